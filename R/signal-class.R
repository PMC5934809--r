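#' Construct an ECG signal object
#'
#' A uniformly sampled single-lead voltage series. Samples are in millivolts;
#' `fs` is the sampling frequency in Hz; `t0` the start offset in seconds
#' (non-zero after edge trimming). Sample indices are 1-based throughout the
#' package.
#'
#' @param samples numeric vector of voltages (mV), finite, length >= 1
#' @param fs sampling frequency in Hz, > 0
#' @param lead free-text lead label
#' @param t0 start offset in seconds
#' @return an object of class `ecg_signal`
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 150)), fs = 150)
#' sig
#' @export
ecg_signal <- function(samples, fs, lead = "I", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ecg_signal: 'samples' must have length >= 1")
  if (!all(is.finite(samples))) stop("ecg_signal: 'samples' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("ecg_signal: 'fs' must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead = as.character(lead), t0 = as.numeric(t0)),
    class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s), lead %s, t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$lead, x$t0))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param signal an [ecg_signal()]
#' @return duration in seconds
#' @export
signal_duration <- function(signal) length(signal$samples) / signal$fs

#' Construct a beat/event annotation set
#'
#' Beat annotations give the R-peak sample index (1-based), a beat label
#' (`NB`, `APB`, `VPB` or `UNCLASSIFIED`), and a `scored` flag marking
#' whether the beat is an independently scored instance (beats inside
#' bigeminy/trigeminy runs and unscored sinus padding carry `FALSE`).
#' Rhythm events reference beat ordinals (1-based, inclusive).
#'
#' @param beats data.frame with columns `index`, `label`, and optionally
#'   `scored` (defaults to `TRUE`)
#' @param events data.frame with columns `kind` (`BG`/`TG`), `start_beat`,
#'   `end_beat`, or NULL for none
#' @return an object of class `ecg_annotations`
#' @export
annotation_set <- function(beats = NULL, events = NULL) {
  if (is.null(beats)) {
    beats <- data.frame(index = integer(0), label = character(0),
                        scored = logical(0))
  }
  beats <- as.data.frame(beats)
  if (!all(c("index", "label") %in% names(beats)))
    stop("annotation_set: beats need columns 'index' and 'label'")
  if (is.null(beats$scored)) beats$scored <- rep(TRUE, nrow(beats))
  beats$index <- as.integer(beats$index)
  beats$label <- as.character(beats$label)
  beats$scored <- as.logical(beats$scored)
  if (nrow(beats) > 1L && any(diff(beats$index) <= 0L))
    stop("annotation_set: beat indices must be strictly increasing")
  if (is.null(events)) {
    events <- data.frame(kind = character(0), start_beat = integer(0),
                         end_beat = integer(0))
  }
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$kind <- as.character(events$kind)
    events$start_beat <- as.integer(events$start_beat)
    events$end_beat <- as.integer(events$end_beat)
    if (any(events$end_beat < events$start_beat))
      stop("annotation_set: event end_beat before start_beat")
    if (any(events$start_beat < 1L) || any(events$end_beat > nrow(beats)))
      stop("annotation_set: event beat ordinals outside beat list")
    for (k in unique(events$kind)) {
      ev <- events[events$kind == k, , drop = FALSE]
      ev <- ev[order(ev$start_beat), , drop = FALSE]
      if (nrow(ev) > 1L && any(ev$start_beat[-1L] <= ev$end_beat[-nrow(ev)]))
        stop("annotation_set: overlapping events of kind ", k)
    }
  }
  structure(list(beats = beats, events = events), class = "ecg_annotations")
}

#' @export
print.ecg_annotations <- function(x, ...) {
  tab <- table(x$beats$label)
  cat(sprintf("<ecg_annotations> %d beats (%s); %d events\n",
              nrow(x$beats),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              nrow(x$events)))
  invisible(x)
}
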