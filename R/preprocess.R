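#' Zero-phase band-pass filter
#'
#' Butterworth IIR band-pass (default order 3, 0.5--40 Hz) applied
#' forward-backward (`signal::filtfilt`) for zero phase distortion, so
#' R-peak timing is preserved. Removes baseline drift (below `low_hz`) and
#' attenuates high-frequency noise and 50/60 Hz powerline interference
#' (above `high_hz`).
#'
#' @param signal an [ecg_signal()]
#' @param low_hz lower cutoff (Hz)
#' @param high_hz upper cutoff (Hz); must be below the Nyquist frequency
#' @param order Butterworth prototype order
#' @return filtered [ecg_signal()], same length and fs
#' @export
bandpass_filter <- function(signal, low_hz = 0.5, high_hz = 40, order = 3L) {
  fs <- signal$fs
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("bandpass_filter: need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop("bandpass_filter: high_hz must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, signal$samples))
  ecg_signal(y, fs = fs, lead = signal$lead, t0 = signal$t0)
}

#' Trim unstable recording edges
#'
#' Long-term wearable recordings are unstable while the recorder is being
#' attached and detached; the first and last `minutes` of data are cut off
#' before analysis. `minutes = 0` is the identity (used for short records).
#'
#' @param signal an [ecg_signal()]
#' @param minutes duration to remove from each end
#' @return interior slice with `t0` advanced accordingly
#' @export
trim_edges <- function(signal, minutes = 2) {
  if (minutes < 0) stop("trim_edges: 'minutes' must be >= 0")
  if (minutes == 0) return(signal)
  k <- as.integer(round(minutes * 60 * signal$fs))
  n <- length(signal$samples)
  if (n <= 2L * k)
    stop("trim_edges: signal shorter than 2 x ", minutes,
         " min; set minutes = 0 for short records")
  ecg_signal(signal$samples[(k + 1L):(n - k)], fs = signal$fs,
             lead = signal$lead, t0 = signal$t0 + minutes * 60)
}

#' Construct a noise mask
#'
#' Per-sample boolean flags marking artifact-contaminated segments that are
#' abandoned by the downstream stages. `segments` is derived from the flags
#' as the maximal runs of `TRUE` (1-based, inclusive sample indices).
#'
#' @param flags logical vector, one entry per sample
#' @return an object of class `noise_mask`
#' @export
noise_mask <- function(flags) {
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("noise_mask: flags must not contain NA")
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  segments <- data.frame(start = starts[keep], end = ends[keep])
  structure(list(flags = flags, segments = segments), class = "noise_mask")
}

#' @export
print.noise_mask <- function(x, ...) {
  cat(sprintf("<noise_mask> %d/%d samples flagged (%.2f%%), %d segments\n",
              sum(x$flags), length(x$flags),
              100 * mean(x$flags), nrow(x$segments)))
  invisible(x)
}

#' Export mask segments as an interval CSV
#'
#' BED-like table with columns `start_sample`, `end_sample` (1-based,
#' inclusive), one row per masked segment.
#'
#' @param mask a [noise_mask()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_mask_csv <- function(mask, path) {
  df <- data.frame(start_sample = mask$segments$start,
                   end_sample = mask$segments$end)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mask artifact-contaminated segments with a dynamic threshold
#'
#' The filtered signal is split into non-overlapping windows (default 2 s).
#' A running median `M` of the window peak-to-peak range over the previous
#' `history` windows (global median for the cold start) sets a dynamic
#' threshold, and a window is flagged when its range exceeds `burst_k * M`
#' (motion/burst artifact), falls below `flat_mv` (flatline / lead-off), or
#' any sample comes within 1% of the recorder full-scale bound (saturation).
#'
#' @param signal a filtered [ecg_signal()]
#' @param window_s window length in seconds
#' @param burst_k burst multiplier on the running median range
#' @param flat_mv flatline peak-to-peak bound (mV)
#' @param full_scale_mv recorder full-scale amplitude bound (mV)
#' @param history number of previous windows in the running median
#' @return a [noise_mask()] of the same length as the signal
#' @export
detect_artifacts <- function(signal, window_s = 2, burst_k = 4,
                             flat_mv = 0.05, full_scale_mv = 5,
                             history = 30L) {
  x <- signal$samples
  n <- length(x)
  w <- max(2L, as.integer(round(window_s * signal$fs)))
  starts <- seq(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  nw <- length(starts)
  rng <- vapply(seq_len(nw), function(i) {
    v <- x[starts[i]:ends[i]]
    max(v) - min(v)
  }, numeric(1L))
  sat <- vapply(seq_len(nw), function(i)
    any(abs(x[starts[i]:ends[i]]) >= 0.99 * full_scale_mv), logical(1L))
  global_med <- median(rng)
  flagged <- logical(nw)
  for (i in seq_len(nw)) {
    m <- if (i > history) median(rng[(i - history):(i - 1L)]) else global_med
    flagged[i] <- rng[i] > burst_k * m || rng[i] < flat_mv || sat[i]
  }
  flags <- logical(n)
  for (i in which(flagged)) flags[starts[i]:ends[i]] <- TRUE
  if (all(flagged) && nw > 0L)
    message("detect_artifacts: every window flagged; record may be unusable")
  noise_mask(flags)
}
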