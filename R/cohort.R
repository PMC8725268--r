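#' Bundled reference cohort tables
#'
#' Per-animal summary values from an acute six-sheep ovine infusion study
#' (identifiers A--F), shipped as plain CSV exactly as published:
#' `baseline` (5-min pre-infusion means and pulse amplitudes per channel),
#' `bolus` (per-channel mean-pressure and pulse-amplitude changes averaged
#' over six 2-mL bolus infusions), `cpi` (per-step cohort means over the
#' four communicating animals during the six 3.75-mmHg pressure steps) and
#' `rout` (per-animal outflow resistance by both methods; `NA` for the two
#' non-communicating animals). Columns ending in `_sd` carry the published
#' per-animal (or per-step) standard deviations.
#'
#' @return named list of data.frames: `baseline`, `bolus`, `cpi`, `rout`.
#' @export
reference_cohort <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "csfinfusion", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(baseline = rd("cohort_baseline.csv"),
       bolus = rd("cohort_bolus_reactions.csv"),
       cpi = rd("cohort_cpi_steps.csv"),
       rout = rd("cohort_rout.csv"))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' reference tables), immune to binary-float representation of decimal
#' ties: `16.575 -> 16.6`, `74.75 -> 74.8`, `51.625 -> 51.6` at one
#' decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  # kill float dust before the floor so decimal ties round up
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

#' Per-animal summary of an infusion test
#'
#' Aggregates the per-event analysis of one animal: per-channel bolus
#' reactions averaged over the available boluses, the per-step CPI table,
#' both outflow-resistance estimates, the 5-min pre-infusion baseline
#' (when the recording is supplied) and the cranio-spinal communication
#' call. Values are stored unrounded; rendering rounds half away from
#' zero.
#'
#' @param id animal label.
#' @param bolus_results list of [analyze_bolus()] results.
#' @param cpi_results an [analyze_cpi()] result or `NULL` (e.g. when the
#'   CPI session could not be completed).
#' @param rout_bolus,rout_cpi `rout_estimate`s or `NULL`.
#' @param rec optional [recording()] for baseline statistics.
#' @param beats optional precomputed beats for baseline amplitudes.
#' @param baseline_window `c(start, end)` of the pre-infusion baseline (s);
#'   5 minutes by convention.
#' @param threshold communication classification threshold.
#' @return object of class `animal_summary`.
#' @export
summarize_animal <- function(id, bolus_results, cpi_results = NULL,
                             rout_bolus = NULL, rout_cpi = NULL, rec = NULL,
                             beats = NULL, baseline_window = c(0, 300),
                             threshold = 0.5) {
  stopifnot(length(bolus_results) >= 1L)
  chans <- bolus_results[[1L]]$per_channel$channel
  d_mean <- sapply(chans, function(ch) mean(vapply(bolus_results, function(r)
    r$per_channel$d_mean[r$per_channel$channel == ch], numeric(1))))
  d_amp <- sapply(chans, function(ch) mean(vapply(bolus_results, function(r)
    r$per_channel$d_amp[r$per_channel$channel == ch], numeric(1))))
  bolus <- data.frame(channel = chans, d_mean = as.numeric(d_mean),
                      d_amp = as.numeric(d_amp))
  comm <- classify_communication(bolus_results, threshold = threshold,
                                 min_events = min(3L, length(bolus_results)))

  cpi_tab <- NULL
  if (!is.null(cpi_results) && length(cpi_results)) {
    cpi_tab <- do.call(rbind, lapply(cpi_results, function(s) {
      wide <- data.frame(step = s$index)
      for (j in seq_len(nrow(s$per_channel))) {
        ch <- tolower(s$per_channel$channel[j])
        wide[[ch]] <- s$per_channel$step_mean[j]
        wide[[paste0(ch, "_amp")]] <- s$per_channel$step_amp[j]
      }
      wide$settled <- s$settled
      wide
    }))
  }

  baseline <- NULL
  if (!is.null(rec)) {
    ii <- rec_window_idx(rec, baseline_window[1L], baseline_window[2L])
    baseline <- data.frame(channel = names(rec$samples),
                           mean = vapply(rec$samples, function(x)
                             mean(x[ii]), numeric(1)),
                           amplitude = NA_real_)
    if (!is.null(beats)) {
      baseline$amplitude <- vapply(names(rec$samples), function(ch)
        tryCatch(amplitude_stat(beats[[ch]], baseline_window),
                 error = function(e) NA_real_), numeric(1))
    }
  }

  structure(list(id = id, baseline = baseline, bolus = bolus,
                 n_boluses = length(bolus_results), cpi = cpi_tab,
                 rout_bolus = if (!is.null(rout_bolus)) rout_bolus$Rout else NA_real_,
                 rout_cpi = if (!is.null(rout_cpi)) rout_cpi$Rout else NA_real_,
                 communicating = comm$communicating,
                 communication_ratio = comm$ratio),
            class = "animal_summary")
}

#' Animal summaries from the bundled reference tables
#'
#' Builds `animal_summary` objects directly from the published per-animal
#' values of [reference_cohort()] (pass-through: the printed per-animal
#' bolus reactions and outflow resistances become the per-animal
#' summaries), classifying communication from the intracranial over
#' intrathecal bolus mean-pressure ratio.
#'
#' @param tables a [reference_cohort()]-shaped list.
#' @param threshold communication classification threshold.
#' @return list of `animal_summary` objects, one per animal.
#' @export
animal_summaries_from_reference <- function(tables = reference_cohort(),
                                            threshold = 0.5) {
  lapply(seq_len(nrow(tables$bolus)), function(i) {
    b <- tables$bolus[i, ]
    comm <- classify_communication(
      data.frame(d_itp = b$d_itp, d_icp = b$d_icp),
      threshold = threshold, min_events = 1L)
    r <- tables$rout[tables$rout$sheep == b$sheep, ]
    bl <- tables$baseline[tables$baseline$sheep == b$sheep, ]
    structure(list(
      id = b$sheep,
      baseline = data.frame(
        channel = c("ICP", "ITP", "ABP", "CVP"),
        mean = c(bl$icp, bl$itp, bl$abp, bl$cvp),
        amplitude = c(bl$icp_amp, bl$itp_amp, bl$abp_amp, bl$cvp_amp)),
      bolus = data.frame(
        channel = c("ICP", "ITP", "ABP", "CVP"),
        d_mean = c(b$d_icp, b$d_itp, b$d_abp, b$d_cvp),
        d_amp = c(b$d_icp_amp, b$d_itp_amp, b$d_abp_amp, b$d_cvp_amp)),
      n_boluses = 6L, cpi = NULL,
      rout_bolus = if (nrow(r)) r$rout_bolus else NA_real_,
      rout_cpi = if (nrow(r)) r$rout_cpi else NA_real_,
      communicating = comm$communicating,
      communication_ratio = comm$ratio),
      class = "animal_summary")
  })
}

#' Cohort summary over animals
#'
#' Mean and sample standard deviation (n - 1 denominator) of each metric
#' over its subset of animals. Following the averaging scheme of the
#' reference study, bolus mean-pressure changes and outflow resistances are
#' averaged over communicating animals only (a muted intracranial response
#' invalidates transmission-dependent metrics), while bolus pulse-amplitude
#' changes are averaged over all animals; the rules are explicit
#' configuration. Metrics with an empty subset are omitted with a warning;
#' a single-animal subset reports no SD.
#'
#' @param animals list of `animal_summary` objects (>= 2).
#' @param subset_rules named list with entries `bolus_mean`, `bolus_amp`,
#'   `rout`, each `"communicating"` or `"all"`.
#' @return object of class `cohort_summary`: data.frame with `metric`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(animals,
                             subset_rules = list(bolus_mean = "communicating",
                                                 bolus_amp = "all",
                                                 rout = "communicating")) {
  if (length(animals) < 2L) stop("need at least 2 animals")
  comm <- vapply(animals, `[[`, logical(1), "communicating")
  pick <- function(rule) if (identical(rule, "communicating")) which(comm)
                         else seq_along(animals)
  rows <- list()
  add <- function(metric, values) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n == 0L) {
      warning("metric omitted (empty subset): ", metric)
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, mean = mean(values),
      sd = if (n >= 2L) stats::sd(values) else NA_real_, n = n)
  }
  get_bolus <- function(an, ch, col) {
    b <- an$bolus
    b[[col]][b$channel == ch]
  }
  for (ch in c("ITP", "ICP", "ABP", "CVP")) {
    sub <- pick(subset_rules$bolus_mean)
    add(paste0("bolus_d_", tolower(ch)),
        vapply(animals[sub], get_bolus, numeric(1), ch, "d_mean"))
    sub <- pick(subset_rules$bolus_amp)
    add(paste0("bolus_d_", tolower(ch), "_amp"),
        vapply(animals[sub], get_bolus, numeric(1), ch, "d_amp"))
  }
  sub <- pick(subset_rules$rout)
  add("rout_bolus", vapply(animals[sub], `[[`, numeric(1), "rout_bolus"))
  add("rout_cpi", vapply(animals[sub], `[[`, numeric(1), "rout_cpi"))
  structure(do.call(rbind, rows), class = c("cohort_summary", "data.frame"))
}

#' Rendered cohort summary
#'
#' @param x a `cohort_summary`.
#' @param digits decimal places (half-away-from-zero rounding).
#' @return data.frame with rounded `mean`/`sd` columns.
#' @export
format_cohort <- function(x, digits = 1) {
  data.frame(metric = x$metric,
             mean = round_half_away(x$mean, digits),
             sd = round_half_away(x$sd, digits),
             n = x$n)
}

#' Pressure rise across the constant-pressure-infusion staircase
#'
#' Absolute and percent rise of each per-step cohort metric between the
#' first and last pressure step (`step6 - step1`;
#' `100 * (step6 - step1)/step1`). Percent rise is `NA` when the first
#' step value is zero.
#'
#' @param table per-step table with a `step` column and metric columns
#'   (columns ending `_sd` and a `settled` column are ignored), e.g. the
#'   `cpi` element of [reference_cohort()] or of an `animal_summary`.
#' @return data.frame with `metric`, `step_first`, `step_last`, `rise`,
#'   `pct_rise`.
#' @export
cpi_rise <- function(table) {
  stopifnot("step" %in% names(table))
  k1 <- which.min(table$step)
  k6 <- which.max(table$step)
  if (k1 == k6) stop("need at least two steps")
  cols <- setdiff(names(table), c("step", "settled"))
  cols <- cols[!grepl("_sd$", cols)]
  out <- do.call(rbind, lapply(cols, function(cn) {
    v1 <- table[[cn]][k1]; v6 <- table[[cn]][k6]
    data.frame(metric = cn, step_first = v1, step_last = v6,
               rise = v6 - v1,
               pct_rise = if (isTRUE(v1 != 0)) 100 * (v6 - v1) / v1
                          else NA_real_)
  }))
  out
}
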