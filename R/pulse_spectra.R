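#' Detect cardiac beats and per-beat pulse amplitudes
#'
#' Beat anchors are local maxima of the 0.5--5 Hz zero-phase bandpassed
#' trace (so that respiratory excursions and slow infusion drifts do not
#' merge beats); within each inter-anchor interval the systolic pressure is
#' the raw-trace maximum and the diastolic pressure the raw-trace minimum.
#' The pulse amplitude of a beat is systolic minus diastolic (peak-to-peak).
#'
#' @param x numeric pressure trace (mmHg), at least 10 s long.
#' @param fs sampling rate (Hz).
#' @param f_cardiac_hint optional expected cardiac frequency (Hz); sets the
#'   minimum anchor spacing to half a cardiac period and triggers a warning
#'   when the detected median rate deviates from the hint by more than 20%.
#' @return a `beat_series` data.frame with columns `time` (s, anchor time),
#'   `systolic`, `diastolic`, `amplitude` (mmHg).
#' @export
detect_beats <- function(x, fs, f_cardiac_hint = NULL) {
  n <- length(x)
  if (n < 10 * fs) stop("trace must be at least 10 s long for beat detection")
  hi <- min(5, 0.45 * fs)
  sos <- design_butter_sos(2, c(0.5, hi) / (fs / 2), type = "pass")
  bp <- sos_filtfilt(x, sos, padlen = as.integer(4 * fs))
  pk <- which(diff(sign(diff(bp))) < 0) + 1L
  if (!length(pk)) stop("no beats found")
  h <- bp[pk]
  thr <- 0.3 * stats::quantile(h[h > 0], 0.75, names = FALSE, na.rm = TRUE)
  if (!is.finite(thr) || max(h) < 1e-9) stop("no beats found")
  pk <- pk[h > thr]
  if (length(pk) < 2L) stop("no beats found")
  min_d <- if (!is.null(f_cardiac_hint)) round(0.5 * fs / f_cardiac_hint)
           else round(fs / 5)
  # greedy suppression: strongest peaks first; a candidate is dropped when it
  # lies within min_d samples of an already accepted anchor
  ord <- pk[order(bp[pk], decreasing = TRUE)]
  keep <- logical(n)
  taken <- logical(n)
  for (i in ord) {
    if (!taken[i]) {
      keep[i] <- TRUE
      taken[max(1L, i - min_d):min(n, i + min_d)] <- TRUE
    }
  }
  anchors <- which(keep)
  if (length(anchors) < 2L) stop("no beats found")
  # per inter-anchor interval [a_i, a_{i+1}): systolic/diastolic of raw trace
  nb <- length(anchors) - 1L
  grp <- rep.int(seq_len(nb), diff(anchors))
  seg <- x[anchors[1L]:(anchors[nb + 1L] - 1L)]
  sys <- vapply(split(seg, grp), max, numeric(1))
  dia <- vapply(split(seg, grp), min, numeric(1))
  times <- (anchors[seq_len(nb)] - 1L) / fs
  rate <- 1 / stats::median(diff(anchors) / fs)
  if (rate < 0.5 || rate > 4)
    warning(sprintf("implied beat rate %.2f Hz outside the physiologic 0.5-4 Hz range", rate))
  if (!is.null(f_cardiac_hint) && abs(rate - f_cardiac_hint) > 0.2 * f_cardiac_hint)
    warning(sprintf("detected beat rate %.2f Hz deviates > 20%% from hint %.2f Hz",
                    rate, f_cardiac_hint))
  structure(data.frame(time = times, systolic = sys, diastolic = dia,
                       amplitude = sys - dia, row.names = NULL),
            class = c("beat_series", "data.frame"), rate = rate)
}

#' Mean pulse amplitude over a time window
#'
#' Arithmetic mean of per-beat pulse amplitudes with anchor time in the
#' half-open window `[window[1], window[2])`; at least 3 beats are required.
#'
#' @param beats a `beat_series` from [detect_beats()].
#' @param window `c(start, end)` in seconds.
#' @return mean amplitude (mmHg).
#' @export
amplitude_stat <- function(beats, window) {
  stopifnot(inherits(beats, "beat_series"), length(window) == 2L)
  sel <- beats$time >= window[1L] & beats$time < window[2L]
  if (sum(sel) < 3L)
    stop(sprintf("fewer than 3 beats in window [%g, %g)", window[1L], window[2L]))
  mean(beats$amplitude[sel])
}

#' Power spectrum with cardiac/respiratory fundamental identification
#'
#' Averaged modified periodogram (Hann window, linear detrend per segment,
#' 60 s segments with 50% overlap) of a trace segment. The two fundamentals
#' are the two largest spectral peaks below 5 Hz that are not harmonically
#' related to each other (a peak at `f` counts as a harmonic of `f0` when
#' `|f - k*f0| < 1.5` frequency bins for an integer `k`); the lower is
#' labelled respiratory, the higher cardiac. Peaks must exceed 5x the median
#' spectral power in 0.05--5 Hz to count.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param segment optional `c(start, end)` window (s, trace-relative with the
#'   first sample at 0); default is the whole trace. Must be >= 60 s.
#' @return object of class `pressure_spectrum`: list with `freqs` (Hz),
#'   `power`, `df` (bin width, Hz) and `fundamentals`
#'   (`c(respiratory = , cardiac = )`, Hz).
#' @export
pressure_spectrum <- function(x, fs, segment = NULL) {
  if (!is.null(segment)) {
    i0 <- max(1L, as.integer(floor(segment[1L] * fs)) + 1L)
    i1 <- min(length(x), as.integer(ceiling(segment[2L] * fs)))
    x <- x[i0:i1]
  }
  if (length(x) < 60 * fs) stop("spectrum segment must be at least 60 s long")
  nper <- as.integer(round(60 * fs))
  step <- nper %/% 2L
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  nfft <- nper
  pacc <- numeric(nfft %/% 2L + 1L)
  tt <- seq_len(nper)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- stats::residuals(stats::lm.fit(cbind(1, tt), seg))  # linear detrend
    X <- stats::fft(seg * w)
    pacc <- pacc + Mod(X[seq_len(nfft %/% 2L + 1L)])^2
  }
  power <- pacc / length(starts)
  freqs <- (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft
  df <- fs / nfft
  band <- freqs >= 0.05 & freqs <= 5
  medp <- stats::median(power[band])
  is_peak <- c(FALSE, diff(sign(diff(power))) < 0, FALSE)
  cand <- which(is_peak & band & power > 5 * medp)
  if (!length(cand)) stop("no dominant peaks above the prominence threshold")
  cand <- cand[order(power[cand], decreasing = TRUE)]
  f1 <- freqs[cand[1L]]
  harmonic_of <- function(f, f0) {
    k <- round(f / f0)
    k >= 1 && abs(f - k * f0) < 1.5 * df
  }
  f2 <- NA_real_
  for (i in cand[-1L]) {
    f <- freqs[i]
    if (!harmonic_of(f, f1) && !harmonic_of(f1, f)) { f2 <- f; break }
  }
  if (is.na(f2))
    stop("no dominant peaks: fewer than two non-harmonically-related fundamentals")
  fund <- sort(c(f1, f2))
  structure(list(freqs = freqs, power = power, df = df,
                 fundamentals = c(respiratory = fund[1L], cardiac = fund[2L])),
            class = "pressure_spectrum")
}

#' @export
print.pressure_spectrum <- function(x, ...) {
  cat(sprintf("<pressure_spectrum> df = %.4g Hz; respiratory %.3g Hz, cardiac %.3g Hz\n",
              x$df, x$fundamentals[["respiratory"]], x$fundamentals[["cardiac"]]))
  invisible(x)
}

#' Cross-correlation lag between two traces
#'
#' Lag of `b` relative to `a` (positive when `b` is delayed), estimated as
#' the argmax of the normalized cross-correlation within `[-max_lag,
#' max_lag]` with parabolic sub-sample refinement.
#'
#' @param a,b equal-length numeric traces.
#' @param fs sampling rate (Hz).
#' @param max_lag maximum lag magnitude (s), at most 10 s.
#' @return lag in seconds.
#' @export
xcorr_lag <- function(a, b, fs, max_lag = 2) {
  if (length(a) != length(b)) stop("traces must have equal length")
  if (max_lag > 10) stop("max_lag must be <= 10 s")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to cross-correlation")
  n <- length(a)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  m <- as.integer(round(max_lag * fs))
  if (m >= n) stop("max_lag must be shorter than the traces")
  # linear cross-correlation cc[k] = sum_i a0[i] * b0[i + k] via zero-padded
  # circular correlation: positive lags k = 0..m sit at the front of the
  # inverse transform, negative lags at the tail
  L <- stats::nextn(n + m, 2)
  A <- stats::fft(c(a0, numeric(L - n)))
  B <- stats::fft(c(b0, numeric(L - n)))
  cc_full <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / L
  lags <- -m:m
  cc <- c(cc_full[(L - m + 1L):L], cc_full[1L:(m + 1L)])
  k <- which.max(cc)
  # parabolic refinement on the three points around the argmax
  delta <- 0
  if (k > 1L && k < length(cc)) {
    y1 <- cc[k - 1L]; y2 <- cc[k]; y3 <- cc[k + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) delta <- 0.5 * (y1 - y3) / den
  }
  (lags[k] + delta) / fs
}
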