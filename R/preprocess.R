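#' Filter specification
#'
#' Zero-phase Butterworth filter settings used throughout the conditioning
#' chain. The two filters of the standard chain are the 0.1 Hz order-4
#' lowpass that extracts the mean pressure trend (10 s periods, removing
#' cardiac and respiratory waves) and the 0.2--0.5 Hz order-4 band-stop that
#' removes the peristaltic-pump roller oscillation during pressure-regulated
#' infusions. All filters are applied forward--backward, so the effective
#' attenuation is doubled and the passband phase shift is zero.
#'
#' @param kind `"lowpass"` or `"bandstop"`.
#' @param order filter design order (>= 1).
#' @param cutoff cutoff frequency in Hz (lowpass) or `c(low, high)` Hz
#'   (bandstop); must lie strictly inside `(0, fs/2)` at application time.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "bandstop"), order, cutoff) {
  kind <- match.arg(kind)
  if (order < 1) stop("filter order must be >= 1")
  if (kind == "lowpass" && length(cutoff) != 1L)
    stop("lowpass needs a single cutoff frequency")
  if (kind == "bandstop") {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2])
      stop("bandstop needs cutoff = c(low, high) with low < high")
  }
  if (any(cutoff <= 0)) stop("cutoff frequencies must be positive")
  structure(list(kind = kind, order = as.integer(order),
                 cutoff = as.numeric(cutoff), zero_phase = TRUE),
            class = "filter_spec")
}

spec_sos <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoff >= nyq))
    stop("cutoff frequency at or above Nyquist (", nyq, " Hz)")
  w <- spec$cutoff / nyq
  design_butter_sos(spec$order, w,
                    type = switch(spec$kind, lowpass = "low",
                                  bandstop = "stop"))
}

# Settling length (samples) used for padding and the minimum-length check:
# a few periods of the lowest characteristic frequency of the filter.
filter_settle_n <- function(spec, fs) {
  f_low <- min(spec$cutoff)
  as.integer(ceiling(2 * fs / f_low))
}

#' Apply a zero-phase Butterworth filter to a trace
#'
#' Forward--backward application of the filter described by `spec`: unit DC
#' gain for both lowpass and bandstop and no phase shift of passband
#' components. Edges are handled by odd-reflection padding of one settling
#' length combined with step-state initial conditions.
#'
#' @param x numeric pressure trace (mmHg).
#' @param fs sampling rate (Hz).
#' @param spec a [filter_spec()].
#' @return filtered trace, same length as `x`.
#' @export
apply_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  sos <- spec_sos(spec, fs)
  ns <- filter_settle_n(spec, fs)
  if (length(x) <= 3L * ns)
    stop(sprintf(
      "trace too short for this filter: need > %d samples (3 settling lengths), got %d",
      3L * ns, length(x)))
  sos_filtfilt(x, sos, padlen = ns)
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias lowpass (zero-phase Butterworth of order 8 with cutoff
#' `0.4 * fs_out`) followed by keeping every `fs/fs_out`-th sample, as used to
#' reduce 1 kHz acquisitions to the 100 Hz analysis rate. The ratio
#' `fs/fs_out` must be an integer.
#'
#' @param rec a [recording()].
#' @param fs_out target sampling rate (Hz).
#' @return decimated [recording()].
#' @export
decimate_to <- function(rec, fs_out) {
  stopifnot(inherits(rec, "csf_recording"))
  r <- rec$fs / fs_out
  if (abs(r - round(r)) > 1e-9)
    stop(sprintf("fs_out (%g) must divide fs (%g)", fs_out, rec$fs))
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  spec <- filter_spec("lowpass", order = 8, cutoff = 0.4 * fs_out)
  keep <- seq(1L, rec_n(rec), by = r)
  samples <- lapply(rec$samples, function(x)
    apply_filter(x, rec$fs, spec)[keep])
  recording(samples, fs = fs_out, t0 = rec$t0)
}

#' Replace statistical outliers in a pressure trace
#'
#' z-score rejection with critical threshold `sigma_crit` (default 3).
#' Statistics are computed on the input trace over centred sliding windows
#' (default 30 s when `fs` is given, otherwise globally) so that slow
#' infusion transients are not themselves flagged. Rejected samples -- and
#' any non-finite input samples -- are replaced by linear interpolation from
#' the nearest retained neighbours; the output is finite everywhere. Windows
#' with (near-)zero spread reject nothing, so a constant trace passes
#' through unchanged.
#'
#' @param x numeric trace (may contain `NA`/`NaN` missing markers).
#' @param sigma_crit rejection threshold in standard deviations.
#' @param fs sampling rate (Hz); when `NULL`, global statistics are used.
#' @param window_s sliding-window length (s) for local statistics.
#' @return cleaned trace, same length as `x`.
#' @export
reject_outliers <- function(x, sigma_crit = 3, fs = NULL, window_s = 30) {
  n <- length(x)
  if (n < 10L) stop("trace too short for outlier rejection (need >= 10 samples)")
  fin <- is.finite(x)
  if (!any(fin)) stop("trace has no finite samples")
  xf <- x
  xf[!fin] <- mean(x[fin])
  if (is.null(fs) || n <= 3L) {
    mu <- rep(mean(xf), n)
    sdv <- rep(stats::sd(xf), n)
  } else {
    w <- max(3L, min(n, as.integer(round(window_s * fs))))
    cs <- cumsum(c(0, xf))
    cs2 <- cumsum(c(0, xf^2))
    half <- w %/% 2L
    lo <- pmax(0L, seq_len(n) - 1L - half)
    hi <- pmin(n, seq_len(n) + half)
    cnt <- hi - lo
    mu <- (cs[hi + 1L] - cs[lo + 1L]) / cnt
    v <- (cs2[hi + 1L] - cs2[lo + 1L]) / cnt - mu^2
    sdv <- sqrt(pmax(v * cnt / pmax(cnt - 1L, 1L), 0))
  }
  z <- abs(xf - mu) / ifelse(sdv > 1e-12, sdv, Inf)
  bad <- !fin | z > sigma_crit
  if (!any(bad)) return(x)
  if (all(bad)) stop("outlier rejection removed every sample")
  keep_i <- which(!bad)
  out <- x
  out[bad] <- stats::approx(keep_i, x[keep_i], xout = which(bad),
                            method = "linear", rule = 2)$y
  out
}

#' Mean pressure trend of a trace
#'
#' The conditioning used before all mean-reaction measurements: z-score
#' outlier rejection followed by a zero-phase order-4 Butterworth lowpass at
#' 0.1 Hz (10 s periods), which removes cardiac and respiratory waves while
#' retaining the bulk pressure reaction to the infusions.
#'
#' @param x numeric trace (mmHg).
#' @param fs sampling rate (Hz).
#' @param sigma_crit outlier threshold (see [reject_outliers()]).
#' @param cutoff lowpass cutoff (Hz).
#' @param order filter order.
#' @return smoothed mean-trend trace.
#' @export
mean_trend <- function(x, fs, sigma_crit = 3, cutoff = 0.1, order = 4) {
  x <- reject_outliers(x, sigma_crit = sigma_crit, fs = fs)
  apply_filter(x, fs, filter_spec("lowpass", order = order, cutoff = cutoff))
}

#' Condition a recording for analysis
#'
#' Per channel: missing samples and z-score outliers are replaced
#' ([reject_outliers()]); when the protocol contains constant-pressure steps,
#' the 0.2--0.5 Hz order-4 zero-phase band-stop is applied over the CPI span
#' (with 30 s margins) on all channels to remove the roller-pump oscillation,
#' which is present only while the pump regulates pressure.
#'
#' @param rec a [recording()].
#' @param protocol an [infusion_protocol()] or `NULL`; needed to locate the
#'   CPI span.
#' @param sigma_crit outlier threshold.
#' @param bandstop `c(low, high)` stopband in Hz.
#' @return conditioned [recording()].
#' @export
preprocess_recording <- function(rec, protocol = NULL, sigma_crit = 3,
                                 bandstop = c(0.2, 0.5)) {
  stopifnot(inherits(rec, "csf_recording"))
  samples <- lapply(rec$samples, reject_outliers, sigma_crit = sigma_crit,
                    fs = rec$fs)
  if (!is.null(protocol) && length(protocol$cpi_steps)) {
    spec <- filter_spec("bandstop", order = 4, cutoff = bandstop)
    t_a <- protocol$cpi_steps[[1L]]$t_start - 30
    t_b <- protocol$cpi_steps[[length(protocol$cpi_steps)]]$t_end + 30
    idx <- rec_window_idx(rec, t_a, t_b)
    ns <- filter_settle_n(spec, rec$fs)
    if (length(idx) > 3L * ns) {
      sos <- spec_sos(spec, rec$fs)
      samples <- lapply(samples, function(x) {
        x[idx] <- sos_filtfilt(x[idx], sos, padlen = ns)
        x
      })
    }
  }
  out <- recording(samples, fs = rec$fs, t0 = rec$t0)
  attr(out, "preprocessed") <- TRUE
  out
}
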