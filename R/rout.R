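#' Pressure-volume index from a bolus infusion
#'
#' Under the exponential craniospinal pressure-volume relation, a rapid
#' volume addition `dV` raises pressure from the resting value `Pr` to the
#' peak `Pp`, and the pressure-volume index follows as
#' `PVI = dV / log10((Pp - P0) / (Pr - P0))` -- the volume that would raise
#' pressure tenfold. `P0` is the reference pressure of the relation, zero
#' by convention.
#'
#' @param dV infused volume (mL), > 0.
#' @param Pp peak post-infusion pressure (mmHg).
#' @param Pr resting pre-infusion pressure (mmHg).
#' @param P0 reference pressure (mmHg).
#' @return PVI in mL.
#' @export
pvi <- function(dV, Pp, Pr, P0 = 0) {
  if (any(dV <= 0)) stop("dV must be > 0")
  if (any(Pr <= P0)) stop("resting pressure must exceed the reference pressure P0")
  if (any(Pp <= Pr)) stop("non-positive pressure rise (Pp <= Pr)")
  dV / log10((Pp - P0) / (Pr - P0))
}

#' Outflow resistance from one bolus relaxation timepoint
#'
#' From the spontaneous post-bolus relaxation of the pressure-volume model,
#' the outflow resistance at relaxation time `t` (minutes after the peak)
#' with relaxation pressure `Pt` is
#' `Rout = t * Pr / (PVI * log10((Pt/Pp) * (Pp - Pr) / (Pt - Pr)))`,
#' in mmHg per mL/min. Vectorised over `t`/`Pt` pairs; inconsistent inputs
#' (relaxation at or below baseline, degenerate logarithm) give `NA` with a
#' warning unless every timepoint is invalid, which is an error.
#'
#' @param t relaxation time after the pressure peak; minutes by default.
#' @param Pr resting pressure (mmHg).
#' @param Pp peak pressure (mmHg).
#' @param Pt relaxation pressure at `t` (mmHg), `Pr < Pt < Pp`.
#' @param PVI pressure-volume index (mL), > 0.
#' @param t_unit `"min"` or `"s"`; seconds are converted to minutes so the
#'   result is always mmHg/mL/min.
#' @return outflow resistance estimate(s), mmHg/mL/min.
#' @export
rout_bolus <- function(t, Pr, Pp, Pt, PVI, t_unit = c("min", "s")) {
  t_unit <- match.arg(t_unit)
  if (t_unit == "s") t <- t / 60
  if (any(PVI <= 0)) stop("PVI must be > 0")
  if (any(t <= 0)) stop("relaxation time must be > 0")
  arg <- (Pt / Pp) * (Pp - Pr) / (Pt - Pr)
  l10 <- rep(NA_real_, length(arg))
  pos <- is.finite(arg) & arg > 0
  l10[pos] <- log10(arg[pos])
  bad <- Pt <= Pr | Pt > Pp | !pos | is.na(l10) | abs(l10) < 1e-12
  if (all(bad)) stop("no valid relaxation timepoint (Pt must satisfy Pr < Pt < Pp)")
  out <- t * Pr / (PVI * l10)
  out[bad] <- NA_real_
  if (any(bad)) warning(sum(bad), " invalid relaxation timepoint(s) dropped")
  out
}

new_rout_estimate <- function(method, Rout, per_timepoint, n_used,
                              PVI = NA_real_, flags = character()) {
  structure(list(method = method, PVI = PVI, Rout = Rout,
                 per_timepoint = per_timepoint, n_used = n_used,
                 flags = flags),
            class = "rout_estimate")
}

#' @export
print.rout_estimate <- function(x, ...) {
  cat(sprintf("<rout_estimate> method = %s: Rout = %.1f mmHg/mL/min (n = %d%s)\n",
              x$method, x$Rout, x$n_used,
              if (!is.na(x$PVI)) sprintf(", PVI = %.2f mL", x$PVI) else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Outflow resistance from a set of bolus infusions
#'
#' For each bolus the pressure-volume index is computed from the pre-bolus
#' and peak pressures of the resistance channel ([pvi()]), the relaxation
#' pressures at 1--4 minutes post peak give per-timepoint resistances
#' ([rout_bolus()]), and the per-bolus resistance is their mean over the
#' valid timepoints. The animal-level estimate is the mean over boluses.
#' Invalid timepoints (relaxation through baseline, truncated recordings)
#' are dropped and flagged rather than aborting the bolus.
#'
#' When boluses repeat faster than the compartment relaxes, later boluses
#' start from a still-elevated pressure. The pressure-volume index is then
#' still exact with the immediate pre-bolus pressure (the volume step acts
#' on the current state), but the relaxation asymptote remains the
#' session's resting baseline: supply it as `Pr_rest` (the 5-min
#' pre-infusion baseline, the defined baseline value for calculation) to
#' keep the relaxation formula consistent. By default the per-bolus `Pr`
#' is used for both, which is the textbook formulation and exact whenever
#' relaxation completes between boluses.
#'
#' @param results list of [analyze_bolus()] results.
#' @param pvi_values optional per-bolus PVI values; by default computed from
#'   each result's `Pr`/`Pp` on `channel`.
#' @param channel pressure channel used (intracranial by convention when
#'   cranio-spinal communication exists; intrathecal as the flagged
#'   fallback otherwise).
#' @param P0 reference pressure (mmHg).
#' @param Pr_rest resting baseline pressure (mmHg) used in the relaxation
#'   formula; default `NULL` uses each bolus's own `Pr`.
#' @return a `rout_estimate` with `method = "bolus"`, per-bolus values in
#'   `per_timepoint`, and the mean PVI.
#' @export
rout_bolus_mean <- function(results, pvi_values = NULL, channel = "ICP",
                            P0 = 0, Pr_rest = NULL) {
  stopifnot(length(results) >= 1L)
  flags <- character()
  per_bolus <- rep(NA_real_, length(results))
  pvis <- rep(NA_real_, length(results))
  for (k in seq_along(results)) {
    r <- results[[k]]
    row <- r$per_channel[r$per_channel$channel == channel, ]
    # prefer the ringing-immune raw peak for pressure-volume arithmetic
    Pp <- if (!is.null(row$Pp_raw) && is.finite(row$Pp_raw)) row$Pp_raw
          else row$Pp
    pv <- if (!is.null(pvi_values)) pvi_values[k]
          else tryCatch(pvi(r$dV, Pp, row$Pr, P0),
                        error = function(e) NA_real_)
    pvis[k] <- pv
    if (!is.finite(pv)) {
      flags <- c(flags, sprintf("bolus %d: PVI not computable", k))
      next
    }
    pt <- r$Pt[channel, ]
    tt <- r$pt_offsets / 60
    ok <- is.finite(pt)
    if (!any(ok)) {
      flags <- c(flags, sprintf("bolus %d: no relaxation timepoints", k))
      next
    }
    pr_relax <- if (is.null(Pr_rest)) row$Pr else Pr_rest
    est <- suppressWarnings(tryCatch(
      rout_bolus(tt[ok], pr_relax, Pp, pt[ok], pv),
      error = function(e) NA_real_))
    if (all(!is.finite(est))) {
      flags <- c(flags, sprintf("bolus %d: no valid timepoint", k))
      next
    }
    if (any(!is.finite(est)))
      flags <- c(flags, sprintf("bolus %d: %d timepoint(s) dropped",
                                k, sum(!is.finite(est))))
    per_bolus[k] <- mean(est, na.rm = TRUE)
  }
  ok <- is.finite(per_bolus)
  if (!any(ok)) stop("no bolus yielded a valid outflow-resistance estimate")
  new_rout_estimate("bolus", Rout = mean(per_bolus[ok]),
                    per_timepoint = per_bolus, n_used = sum(ok),
                    PVI = mean(pvis[is.finite(pvis)]), flags = flags)
}

#' Outflow resistance from constant-pressure-infusion steps
#'
#' Per settled step, `Rout = (Pa - Pb) / q_inf`: the settled step pressure
#' minus the pre-infusion baseline of the resistance channel divided by the
#' infusion rate that maintained the step. Steps that never settled, have
#' no measured rate, or have `q_inf = 0` are excluded and flagged. The
#' animal-level estimate is the mean over the valid steps.
#'
#' @param steps an [analyze_cpi()] result (`cpi_results`).
#' @return a `rout_estimate` with `method = "cpi"` and per-step values in
#'   `per_timepoint`.
#' @export
rout_cpi <- function(steps) {
  stopifnot(inherits(steps, "cpi_results"))
  flags <- character()
  per_step <- rep(NA_real_, length(steps))
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    if (!isTRUE(s$settled)) {
      flags <- c(flags, sprintf("step %d: never settled", s$index))
      next
    }
    if (!is.finite(s$q_inf)) {
      flags <- c(flags, sprintf("step %d: no measured infusion rate", s$index))
      next
    }
    if (s$q_inf <= 0) {
      flags <- c(flags, sprintf("step %d: q_inf = 0%s", s$index,
                                if (s$Pa > s$Pb) " with Pa > Pb" else ""))
      next
    }
    if (s$Pa <= s$Pb) {
      flags <- c(flags, sprintf("step %d: uninformative (Pa <= Pb)", s$index))
      next
    }
    per_step[k] <- (s$Pa - s$Pb) / s$q_inf
  }
  ok <- is.finite(per_step)
  if (!any(ok)) stop("no settled step with a positive infusion rate")
  new_rout_estimate("cpi", Rout = mean(per_step[ok]),
                    per_timepoint = per_step, n_used = sum(ok), flags = flags)
}
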