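#' Mean-trend traces for all channels of a recording
#'
#' Convenience wrapper computing [mean_trend()] once per channel so that
#' multi-event analyses do not refilter the recording per event.
#'
#' @param rec a (preferably preprocessed) [recording()].
#' @param ... passed to [mean_trend()].
#' @return named list of trend traces.
#' @export
compute_trends <- function(rec, ...) {
  lapply(rec$samples, mean_trend, fs = rec$fs, ...)
}

#' Beat series for all channels of a recording
#'
#' @param rec a [recording()].
#' @param f_cardiac_hint optional expected cardiac frequency (Hz).
#' @return named list of `beat_series`.
#' @export
detect_beats_all <- function(rec, f_cardiac_hint = NULL) {
  lapply(rec$samples, detect_beats, fs = rec$fs,
         f_cardiac_hint = f_cardiac_hint)
}

trend_value_at <- function(trend, rec, t) {
  i <- as.integer(round((t - rec$t0) * rec$fs)) + 1L
  i <- min(max(i, 1L), length(trend))
  trend[i]
}

#' Quantify the reaction to one bolus infusion
#'
#' Per channel, the mean-pressure change `d_mean` is the peak of the mean
#' trend in the post-infusion window `[t_start, t_start + post_window)`
#' minus the peak in the pre-infusion window `[t_start - pre_window,
#' t_start - guard_s)` (windows default to 60 s). The pulse-amplitude
#' change `d_amp` is the mean per-beat amplitude over 10 s from the trend
#' peak minus the mean over the 10 s before infusion start. The resting
#' pressure `Pr` is the trend value `guard_s` seconds before infusion --
#' the zero-phase trend filter spreads the infusion front symmetrically in
#' time, so values closer to the start are contaminated by the backward
#' smear (about 12 s for the 0.1 Hz order-4 filter). `Pp` is the
#' post-window trend maximum, and the relaxation pressures `Pt` are read
#' from the trend at 1, 2, 3 and 4 minutes after the trend peak.
#' Relaxation timepoints beyond the recording are returned as `NA` with
#' `truncated = TRUE`.
#'
#' @param rec a preprocessed [recording()].
#' @param ev a [bolus_event()].
#' @param trends optional precomputed [compute_trends()] result.
#' @param beats optional precomputed [detect_beats_all()] result.
#' @param amplitudes compute pulse-amplitude changes (needs beats; set
#'   `FALSE` to skip beat detection when only mean reactions are needed).
#' @param pt_offsets relaxation read-out times (s) after the anchor.
#' @param pt_anchor anchor of the relaxation clock: `"infusion"` (default;
#'   relaxation pressures at exact minutes post bolus infusion) or
#'   `"peak"` (minutes after the trend peak, which lags the infusion by a
#'   few seconds of filter delay).
#' @param guard_s pre-infusion guard interval (s) shielding `Pr` and the
#'   pre-infusion peak from the backward smear of the zero-phase filter.
#' @return object of class `bolus_result`: `per_channel` data.frame
#'   (`channel`, `d_mean`, `d_amp`, `Pr`, `Pp`, `Pp_raw`, `t_peak`), `Pt`
#'   matrix (channels x timepoints), `dV`, `t_start`, `truncated`.
#'   `Pp` is the trend maximum (the quantity entering `d_mean`); `Pp_raw`
#'   is a running-median peak of the raw trace, immune to the ringing
#'   overshoot of the zero-phase filter at the sharp infusion front, and is
#'   the peak used for pressure-volume calculations.
#' @export
analyze_bolus <- function(rec, ev, trends = NULL, beats = NULL,
                          amplitudes = TRUE,
                          pt_offsets = c(60, 120, 180, 240),
                          pt_anchor = c("infusion", "peak"), guard_s = 15) {
  pt_anchor <- match.arg(pt_anchor)
  stopifnot(inherits(rec, "csf_recording"), inherits(ev, "bolus_event"))
  if (is.null(trends)) trends <- compute_trends(rec)
  if (amplitudes && is.null(beats)) beats <- detect_beats_all(rec)
  tmax <- rec$t0 + (rec_n(rec) - 1L) / rec$fs
  if (ev$t_start - ev$pre_window < rec$t0 || ev$t_start + ev$post_window > tmax)
    stop("bolus analysis windows extend beyond the recording")

  chans <- names(rec$samples)
  res <- data.frame(channel = chans, d_mean = NA_real_, d_amp = NA_real_,
                    Pr = NA_real_, Pp = NA_real_, Pp_raw = NA_real_,
                    t_peak = NA_real_)
  Pt <- matrix(NA_real_, nrow = length(chans), ncol = length(pt_offsets),
               dimnames = list(chans, paste0("t", pt_offsets)))
  truncated <- FALSE
  tm <- rec_time(rec)
  for (k in seq_along(chans)) {
    tr <- trends[[chans[k]]]
    pre_i <- rec_window_idx(rec, ev$t_start - ev$pre_window,
                            ev$t_start - guard_s)
    post_i <- rec_window_idx(rec, ev$t_start, ev$t_start + ev$post_window)
    peak_pre <- max(tr[pre_i])
    j <- post_i[which.max(tr[post_i])]
    peak_post <- tr[j]
    t_peak <- tm[j]
    res$d_mean[k] <- peak_post - peak_pre
    res$Pr[k] <- trend_value_at(tr, rec, ev$t_start - guard_s)
    res$Pp[k] <- peak_post
    res$t_peak[k] <- t_peak
    # ringing-immune peak: plain average of the raw trace over one
    # respiratory cycle right after the infusion front (a boxcar cannot
    # overshoot, and full-cycle averaging cancels the pulsatile components)
    raw_i <- rec_window_idx(rec, ev$t_start + 0.5, ev$t_start + 3.8)
    res$Pp_raw[k] <- mean(rec$samples[[chans[k]]][raw_i])
    anchor <- if (pt_anchor == "infusion") ev$t_start else t_peak
    for (q in seq_along(pt_offsets)) {
      t_q <- anchor + pt_offsets[q]
      if (t_q > tmax) truncated <- TRUE
      else Pt[k, q] <- trend_value_at(tr, rec, t_q)
    }
    if (amplitudes) {
      a_pre <- amplitude_stat(beats[[chans[k]]], c(ev$t_start - 10, ev$t_start))
      a_post <- amplitude_stat(beats[[chans[k]]], c(t_peak, t_peak + 10))
      res$d_amp[k] <- a_post - a_pre
    }
  }
  if (truncated)
    warning("relaxation window truncated by end of recording; partial Pt series")
  structure(list(per_channel = res, Pt = Pt, pt_offsets = pt_offsets,
                 dV = ev$dV, t_start = ev$t_start, truncated = truncated),
            class = "bolus_result")
}

#' Quantify the reactions over constant-pressure-infusion steps
#'
#' Per step, statistics are computed over the settled interval
#' `[t_start + settle, t_end)`. A step is flagged unsettled (and later
#' excluded from outflow-resistance estimation) when the intrathecal mean
#' trend still drifts faster than `slope_crit` mmHg/min on average over
#' that interval. `step_mean` is the settled mean of each channel's trend
#' and `step_amp` the mean per-beat amplitude over the settled interval.
#' `Pa` is the settled mean of the resistance channel (`rout_channel`) and
#' `Pb` its pre-infusion baseline: the mean over `baseline_window` seconds
#' before the first step, the same reference for every step.
#'
#' @param rec a preprocessed [recording()] (band-stop applied over the CPI
#'   span).
#' @param steps list of [cpi_step()] (e.g. `protocol$cpi_steps`).
#' @param trends,beats optional precomputed per-channel trends/beats.
#' @param amplitudes compute settled pulse amplitudes.
#' @param settle settling allowance (s).
#' @param slope_crit residual drift threshold (mmHg/min).
#' @param rout_channel channel used for outflow-resistance pressures
#'   (intracranial by convention when cranio-spinal communication exists).
#' @param baseline_window pre-CPI baseline length (s).
#' @return object of class `cpi_results`: list of per-step results
#'   (`index`, `target`, `q_inf`, `per_channel` data.frame, `Pa`, `Pb`,
#'   `settled`) with the shared baseline `Pb` as attribute.
#' @export
analyze_cpi <- function(rec, steps, trends = NULL, beats = NULL,
                        amplitudes = TRUE, settle = 60, slope_crit = 0.5,
                        rout_channel = "ICP", baseline_window = 120) {
  stopifnot(inherits(rec, "csf_recording"), length(steps) >= 1L)
  if (is.null(trends)) trends <- compute_trends(rec)
  if (amplitudes && is.null(beats)) beats <- detect_beats_all(rec)
  chans <- names(rec$samples)
  if (!rout_channel %in% chans) stop("rout_channel not present in recording")

  t_first <- steps[[1L]]$t_start
  base_i <- rec_window_idx(rec, t_first - baseline_window, t_first)
  if (!length(base_i)) stop("no pre-infusion baseline available before the first step")
  Pb <- mean(trends[[rout_channel]][base_i])

  out <- vector("list", length(steps))
  itp_tr <- trends[["ITP"]]
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    ii <- rec_window_idx(rec, s$t_start + settle, s$t_end)
    if (!length(ii)) stop(sprintf("step %d has no settled samples", k))
    drift <- if (!is.null(itp_tr)) {
      span <- (length(ii) - 1L) / rec$fs / 60  # minutes
      abs(itp_tr[ii[length(ii)]] - itp_tr[ii[1L]]) / span
    } else 0
    settled <- drift <= slope_crit
    pc <- data.frame(channel = chans, step_mean = NA_real_,
                     step_amp = NA_real_)
    for (j in seq_along(chans)) {
      pc$step_mean[j] <- mean(trends[[chans[j]]][ii])
      if (amplitudes) {
        w <- c(rec$t0 + (ii[1L] - 1L) / rec$fs, rec$t0 + ii[length(ii)] / rec$fs)
        pc$step_amp[j] <- tryCatch(amplitude_stat(beats[[chans[j]]], w),
                                   error = function(e) NA_real_)
      }
    }
    out[[k]] <- structure(list(index = s$index, target = s$target,
                               q_inf = s$q_inf, per_channel = pc,
                               Pa = pc$step_mean[pc$channel == rout_channel],
                               Pb = Pb, settled = settled),
                          class = "cpi_step_result")
  }
  structure(out, class = "cpi_results", Pb = Pb, rout_channel = rout_channel)
}

#' Classify cranio-spinal communication from bolus reactions
#'
#' For each bolus the transmission ratio is the intracranial over the
#' intrathecal mean-pressure change (clipped at zero; boluses with a
#' non-positive intrathecal change are excluded). The animal communicates
#' when the mean ratio reaches `threshold`: free cranio-spinal fluid
#' communication transmits most of the intrathecal rise to the cranium,
#' while an obstructed spinal canal mutes the intracranial response.
#'
#' @param results list of [analyze_bolus()] results (or a data.frame with
#'   columns `d_itp` and `d_icp`, one row per bolus).
#' @param threshold classification threshold on the mean ratio.
#' @param min_events minimum usable boluses required.
#' @return object of class `communication_call`: `ratio`, `communicating`,
#'   `threshold`, `n_used`.
#' @export
classify_communication <- function(results, threshold = 0.5, min_events = 3) {
  if (is.data.frame(results)) {
    d_itp <- results$d_itp
    d_icp <- results$d_icp
  } else {
    d_itp <- vapply(results, function(r)
      r$per_channel$d_mean[r$per_channel$channel == "ITP"], numeric(1))
    d_icp <- vapply(results, function(r)
      r$per_channel$d_mean[r$per_channel$channel == "ICP"], numeric(1))
  }
  if (length(d_itp) < min_events)
    stop(sprintf("need at least %d bolus results", min_events))
  ok <- d_itp > 0
  if (!any(ok)) stop("no bolus with a positive intrathecal pressure rise")
  ratio <- mean(pmax(0, d_icp[ok] / d_itp[ok]))
  structure(list(ratio = ratio, communicating = ratio >= threshold,
                 threshold = threshold, n_used = sum(ok)),
            class = "communication_call")
}

#' @export
print.communication_call <- function(x, ...) {
  cat(sprintf("<communication_call> ratio = %.3f (threshold %.2f): %s (n = %d)\n",
              x$ratio, x$threshold,
              if (x$communicating) "communicating" else "non-communicating",
              x$n_used))
  invisible(x)
}

#' Coupling between intracranial and intrathecal mean trends
#'
#' Pearson correlation of the intracranial on the intrathecal mean trend
#' over a segment of at least 120 s, quantifying how faithfully the
#' intrathecal pressure tracks the intracranial pressure.
#'
#' @param rec a preprocessed [recording()] containing ICP and ITP.
#' @param segment `c(start, end)` in seconds.
#' @param trends optional precomputed trends.
#' @return correlation coefficient.
#' @export
regression_coupling <- function(rec, segment, trends = NULL) {
  stopifnot(inherits(rec, "csf_recording"))
  if (diff(segment) < 120) stop("segment must be at least 120 s long")
  if (is.null(trends)) trends <- compute_trends(rec)
  ii <- rec_window_idx(rec, segment[1L], segment[2L])
  a <- trends[["ICP"]][ii]
  b <- trends[["ITP"]][ii]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance trend in segment")
  stats::cor(a, b)
}
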