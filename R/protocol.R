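#' Bolus infusion event
#'
#' A rapid, volume-controlled intrathecal infusion of `dV` mL. Pre/post
#' analysis windows (seconds, relative to `t_start`) control how the mean
#' trend peaks are bracketed during analysis.
#'
#' @param t_start infusion start time (s, recording-relative).
#' @param dV infused volume (mL), > 0.
#' @param pre_window,post_window peak-search window lengths (s).
#' @return object of class `bolus_event`.
#' @export
bolus_event <- function(t_start, dV, pre_window = 60, post_window = 60) {
  if (!is.finite(dV) || dV <= 0) stop("bolus volume `dV` must be > 0")
  if (!is.finite(t_start)) stop("`t_start` must be finite")
  structure(list(t_start = t_start, dV = dV,
                 pre_window = pre_window, post_window = post_window),
            class = "bolus_event")
}

#' Constant-pressure infusion step
#'
#' One pressure-controlled step of a constant-pressure infusion (CPI):
#' intrathecal pressure is regulated at `target` mmHg over
#' `[t_start, t_end)`; `q_inf` is the mean infusion rate over the settled
#' part of the step (mL/min), as reported by the infusion apparatus.
#'
#' @param index step number (1..6 in the standard protocol).
#' @param target commanded pressure (mmHg).
#' @param t_start,t_end step interval (s), `t_end > t_start`.
#' @param q_inf mean settled infusion rate (mL/min), `>= 0`; `NA` if not yet
#'   measured.
#' @return object of class `cpi_step`.
#' @export
cpi_step <- function(index, target, t_start, t_end, q_inf = NA_real_) {
  if (t_end <= t_start) stop("cpi step: t_end must exceed t_start")
  if (!is.na(q_inf) && q_inf < 0) stop("cpi step: q_inf must be >= 0")
  structure(list(index = as.integer(index), target = target,
                 t_start = t_start, t_end = t_end, q_inf = q_inf),
            class = "cpi_step")
}

#' Infusion protocol
#'
#' The ordered set of infusion events of one experimental session: bolus
#' infusions and constant-pressure steps. Events must be sorted in time and
#' bolus/CPI intervals must be disjoint. Each bolus is followed by a
#' relaxation period of at most `relaxation_limit` seconds (7 min in the
#' standard protocol) before the next event.
#'
#' @param boluses list of [bolus_event()].
#' @param cpi_steps list of [cpi_step()] (consecutive, non-overlapping,
#'   ordered).
#' @param relaxation_limit maximum bolus relaxation wait (s).
#' @return object of class `infusion_protocol`.
#' @export
infusion_protocol <- function(boluses = list(), cpi_steps = list(),
                              relaxation_limit = 420) {
  stopifnot(is.list(boluses), is.list(cpi_steps))
  if (length(boluses) > 1L) {
    ts <- vapply(boluses, `[[`, numeric(1), "t_start")
    if (is.unsorted(ts, strictly = TRUE))
      stop("bolus events must be strictly ordered in time")
  }
  if (length(cpi_steps) > 1L) {
    for (i in 2:length(cpi_steps)) {
      if (cpi_steps[[i]]$t_start < cpi_steps[[i - 1L]]$t_end)
        stop(sprintf("cpi steps %d and %d overlap or are out of order",
                     i - 1L, i))
    }
  }
  if (length(boluses) && length(cpi_steps)) {
    b_t <- vapply(boluses, `[[`, numeric(1), "t_start")
    for (s in cpi_steps) {
      if (any(b_t >= s$t_start & b_t < s$t_end))
        stop("bolus events must not fall inside cpi steps")
    }
  }
  structure(list(boluses = boluses, cpi_steps = cpi_steps,
                 relaxation_limit = relaxation_limit),
            class = "infusion_protocol")
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat(sprintf("<infusion_protocol> %d bolus event(s), %d cpi step(s)\n",
              length(x$boluses), length(x$cpi_steps)))
  invisible(x)
}

#' Read an infusion protocol from JSON
#'
#' Expected JSON layout:
#' `{"boluses": [{"t_start": ..., "dV_mL": ...}, ...],
#'   "cpi_steps": [{"index": ..., "target_mmHg": ..., "t_start": ...,
#'                  "t_end": ..., "q_inf_mL_min": ...}, ...]}`
#'
#' @param path JSON file path.
#' @return an [infusion_protocol()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  boluses <- lapply(j$boluses, function(b) {
    if (is.null(b$t_start) || is.null(b$dV_mL))
      stop("bolus entries need t_start and dV_mL")
    if (b$dV_mL <= 0) stop("bolus volume must be positive, got ", b$dV_mL)
    bolus_event(t_start = b$t_start, dV = b$dV_mL)
  })
  steps <- lapply(j$cpi_steps, function(s) {
    cpi_step(index = s$index, target = s$target_mmHg,
             t_start = s$t_start, t_end = s$t_end,
             q_inf = if (is.null(s$q_inf_mL_min)) NA_real_ else s$q_inf_mL_min)
  })
  rl <- if (is.null(j$relaxation_limit)) 420 else j$relaxation_limit
  infusion_protocol(boluses, steps, relaxation_limit = rl)
}

#' Write an infusion protocol to JSON
#'
#' @param protocol an [infusion_protocol()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  j <- list(
    boluses = lapply(protocol$boluses, function(b)
      list(t_start = b$t_start, dV_mL = b$dV)),
    cpi_steps = lapply(protocol$cpi_steps, function(s)
      list(index = s$index, target_mmHg = s$target, t_start = s$t_start,
           t_end = s$t_end, q_inf_mL_min = s$q_inf)),
    relaxation_limit = protocol$relaxation_limit)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
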