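#' @name morphology
#' @title Flat grayscale morphology on 1-D signals
#'
#' @description
#' Erosion (running minimum) and dilation (running maximum) with a flat,
#' centered structuring element of odd length `w` samples; windows are
#' truncated at the record boundaries. Two interchangeable backends are
#' provided: `"naive"` (explicit loop, the reference) and `"vectorized"`
#' (shift-and-pmin over the element width); both produce identical output
#' since min/max selection is exact.
#'
#' @param x numeric vector
#' @param w structuring element length (odd, in samples)
#' @param backend `"vectorized"` or `"naive"`
#' @return numeric vector, same length as `x`
NULL

#' @rdname morphology
#' @export
erode <- function(x, w, backend = c("vectorized", "naive")) {
  backend <- match.arg(backend)
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("erode: 'w' must be odd and >= 1")
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  if (backend == "naive") {
    out <- numeric(n)
    for (i in seq_len(n))
      out[i] <- min(x[max(1L, i - h):min(n, i + h)])
    return(out)
  }
  out <- x
  for (k in seq_len(h)) {
    out <- pmin(out,
                c(x[-seq_len(k)], rep(Inf, k)),      # lead by k
                c(rep(Inf, k), x[seq_len(n - k)]))   # lag by k
  }
  out
}

#' @rdname morphology
#' @export
dilate <- function(x, w, backend = c("vectorized", "naive")) {
  -erode(-x, w, backend = match.arg(backend))
}

morph_open <- function(x, w, backend) dilate(erode(x, w, backend), w, backend)
morph_close <- function(x, w, backend) erode(dilate(x, w, backend), w, backend)

#' Morphological R-peak enhancement
#'
#' Nonlinear transform that boosts the R spike relative to P/T waves and
#' residual baseline, so R peaks become unambiguous local maxima. Two
#' stages, both with flat structuring elements whose lengths are given in
#' seconds and converted to the nearest odd sample count:
#' \enumerate{
#'   \item residual baseline removal: subtract the average of
#'     opening-then-closing and closing-then-opening with a `baseline_s`
#'     element (longer than a QRS complex, so the estimate follows the
#'     baseline underneath it);
#'   \item peak enhancement: top-hat (signal minus opening) with a `peak_s`
#'     element shorter than a QRS, which preserves the narrow R spike and
#'     suppresses the wider P and T waves; the absolute value is returned.
#' }
#'
#' @param signal a filtered [ecg_signal()]
#' @param baseline_s baseline structuring element length (s)
#' @param peak_s peak structuring element length (s); must be shorter than
#'   a QRS complex
#' @param backend morphology backend, see [erode()]
#' @return non-negative [ecg_signal()] of the same length; R-peak locations
#'   correspond to local maxima
#' @export
morphological_transform <- function(signal, baseline_s = 0.2, peak_s = 0.06,
                                    backend = c("vectorized", "naive")) {
  backend <- match.arg(backend)
  x <- signal$samples
  wb <- odd_samples(baseline_s, signal$fs)
  wp <- odd_samples(peak_s, signal$fs)
  base <- (morph_open(morph_close(x, wb, backend), wb, backend) +
             morph_close(morph_open(x, wb, backend), wb, backend)) / 2
  det <- x - base
  enh <- abs(det - morph_open(det, wp, backend))
  ecg_signal(enh, fs = signal$fs, lead = signal$lead, t0 = signal$t0)
}
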