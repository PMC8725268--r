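#' @useDynLib csfinfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Channel labels recognised throughout the package (CSV column order).
REC_CHANNELS <- c("ICP", "ITP", "ABP", "CVP")

#' Multichannel pressure recording
#'
#' A recording is a uniformly sampled set of pressure channels (mmHg) drawn
#' from \{ICP, ITP, ABP, CVP\}: intracranial, intrathecal, arterial and central
#' venous pressure. The time of sample `i` (1-based) is `t0 + (i - 1)/fs`.
#' All analysis windows in the package are half-open `[start, end)` in
#' recording-relative seconds.
#'
#' @param samples named list of equal-length numeric vectors (pressures in
#'   mmHg); names must be a subset of `ICP`, `ITP`, `ABP`, `CVP`. Missing raw
#'   samples may be `NaN`/`NA`; only the preprocessing stage removes them.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds, recording-relative (default 0).
#' @return an object of class `csf_recording`.
#' @export
recording <- function(samples, fs, t0 = 0) {
  if (!is.list(samples) || length(samples) == 0L || is.null(names(samples)))
    stop("`samples` must be a non-empty named list of numeric vectors")
  unknown <- setdiff(names(samples), REC_CHANNELS)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         " (expected ICP, ITP, ABP, CVP)")
  ns <- lengths(samples)
  if (any(ns == 0L)) stop("empty channel(s): ",
                          paste(names(samples)[ns == 0L], collapse = ", "))
  if (length(unique(ns)) != 1L)
    stop("all channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  samples <- lapply(samples, as.numeric)
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "csf_recording")
}

#' @export
print.csf_recording <- function(x, ...) {
  n <- rec_n(x)
  cat(sprintf("<csf_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), n, x$fs, n / x$fs))
  cat("  channels:", paste(names(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `csf_recording`.
#' @return integer sample count.
#' @export
rec_n <- function(rec) length(rec$samples[[1L]])

#' Sample time vector of a recording
#' @param rec a `csf_recording`.
#' @return numeric vector of sample times (s).
#' @export
rec_time <- function(rec) rec$t0 + (seq_len(rec_n(rec)) - 1L) / rec$fs

# Sample indices with time in the half-open window [start, end).
rec_window_idx <- function(rec, start, end) {
  i0 <- ceiling((start - rec$t0) * rec$fs - 1e-9) + 1L
  i1 <- ceiling((end - rec$t0) * rec$fs - 1e-9)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(rec_n(rec), as.integer(i1))
  if (i1 < i0) integer(0) else i0:i1
}

#' Read a multichannel pressure recording
#'
#' CSV layout: a header row with a `time_s` column followed by channel columns
#' named among `ICP`, `ITP`, `ABP`, `CVP`; comma-separated, `.` decimal. The
#' time column must be a uniform grid (relative tolerance 1e-6); the sampling
#' rate is inferred from the median time increment.
#'
#' @param path file path.
#' @param format file format; only `"csv"` is supported.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 recordings are not supported by this build; use format = \"csv\"")
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", "NaN", ""))
  if (!"time_s" %in% names(dt))
    stop("CSV recording must have a 'time_s' column")
  tm <- dt[["time_s"]]
  if (length(tm) < 2L) stop("recording must contain at least 2 samples")
  d <- diff(tm)
  dt_med <- stats::median(d)
  if (dt_med <= 0) {
    i <- which(d <= 0)[1L]
    stop(sprintf("non-uniform time grid: non-increasing time at row %d", i + 1L))
  }
  bad <- which(abs(d - dt_med) > 1e-6 * dt_med)
  if (length(bad))
    stop(sprintf("non-uniform time grid: first offending sample index %d (time %g)",
                 bad[1L] + 1L, tm[bad[1L] + 1L]))
  chans <- setdiff(names(dt), "time_s")
  unknown <- setdiff(chans, REC_CHANNELS)
  if (length(unknown))
    stop("unknown channel label(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  recording(as.list(dt[chans]), fs = 1 / dt_med, t0 = tm[1L])
}

#' Write a multichannel pressure recording
#'
#' Writes full-precision CSV readable by [read_recording()]; round trips
#' preserve pressures to better than 1e-6 mmHg.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("hdf5 recordings are not supported by this build; use format = \"csv\"")
  if (!inherits(rec, "csf_recording")) stop("`rec` must be a csf_recording")
  if (rec_n(rec) == 0L) stop("cannot write an empty recording")
  df <- data.frame(time_s = rec_time(rec), rec$samples, check.names = FALSE)
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = ",", dec = ".")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write recording to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
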