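#' Detect R peaks with a dynamic threshold
#'
#' Works on the morphologically enhanced signal. Candidate peaks are local
#' maxima; a candidate is accepted when it exceeds an adaptive threshold
#' (`threshold_frac` times the median of the last `history` accepted peak
#' amplitudes, initialized from the 98th percentile of the first `init_s`
#' seconds), lies outside masked segments, and respects a refractory period.
#' If the gap since the last accepted peak exceeds `searchback_factor` times
#' the running average RR interval, the gap is re-scanned with the threshold
#' halved (search-back), recovering low-amplitude beats.
#'
#' @param enhanced enhanced [ecg_signal()] from [morphological_transform()]
#' @param mask optional [noise_mask()] aligned with the signal; peaks inside
#'   masked segments are abandoned
#' @param threshold_frac fraction of the running median peak amplitude
#' @param refractory_ms minimum distance between accepted peaks (ms)
#' @param searchback_factor multiple of the average RR that triggers
#'   search-back
#' @param init_s seconds used to initialize the threshold
#' @param history number of accepted peak amplitudes in the running median
#' @return integer vector of R-peak sample indices (strictly increasing)
#' @export
detect_r_peaks <- function(enhanced, mask = NULL, threshold_frac = 0.4,
                           refractory_ms = 200, searchback_factor = 1.5,
                           init_s = 10, history = 8L) {
  x <- enhanced$samples
  n <- length(x)
  fs <- enhanced$fs
  if (n < 3L) return(integer(0))
  flags <- if (is.null(mask)) rep(FALSE, n) else mask$flags
  if (length(flags) != n)
    stop("detect_r_peaks: mask length does not match signal")
  refr <- ms_to_samples(refractory_ms, fs)

  # local maxima (first sample of a plateau), positive, unmasked
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > 0 & !flags[cand]]
  if (!length(cand)) return(integer(0))

  init_amp <- as.numeric(quantile(x[seq_len(min(n, round(init_s * fs)))],
                                  0.98, names = FALSE))
  amp_hist <- init_amp
  peaks <- integer(0)
  rr_hist <- numeric(0)

  accept <- function(i) {
    peaks <<- c(peaks, i)
    amp_hist <<- tail(c(amp_hist, x[i]), history)
    np <- length(peaks)
    if (np >= 2L)
      rr_hist <<- tail(c(rr_hist, peaks[np] - peaks[np - 1L]), history)
  }
  search_back <- function(from, to, thr) {
    sel <- cand[cand > from & cand < to & x[cand] >= thr / 2]
    if (length(sel)) {
      best <- sel[which.max(x[sel])]
      if (!length(peaks) || best - tail(peaks, 1L) >= refr) accept(best)
    }
  }

  for (i in cand) {
    thr <- threshold_frac * median(amp_hist)
    last <- if (length(peaks)) tail(peaks, 1L) else NA_integer_
    if (!is.na(last) && length(rr_hist) &&
        (i - last) > searchback_factor * mean(rr_hist)) {
      search_back(last + refr, i - refr + 1L, thr)
      last <- tail(peaks, 1L)
    }
    if (!is.na(last) && i - last < refr) next
    if (x[i] >= thr) accept(i)
  }
  # trailing gap at the end of the record
  if (length(peaks) && length(rr_hist)) {
    last <- tail(peaks, 1L)
    if ((n - last) > searchback_factor * mean(rr_hist))
      search_back(last + refr, n,
                  threshold_frac * median(amp_hist))
  }
  peaks
}

#' Delineate QRS complexes
#'
#' Nominal onset/offset boundaries are placed 50 ms before and 80 ms after
#' each R peak (round-half-up sample conversion), clipped to the record.
#' The QRS width is measured independently of those fixed boundaries: within
#' a `width_search_ms` window around R, the local baseline is estimated as
#' the median of an annulus flanking the complex, and the width is the span
#' between the first and last samples whose baseline-corrected magnitude
#' exceeds `width_frac` of the magnitude at R. A fixed-boundary width would
#' be constant by construction and could not separate narrow from wide
#' (> 120 ms) complexes.
#'
#' @param signal the filtered [ecg_signal()]
#' @param rpeaks integer vector of R-peak indices
#' @param enhanced unused placeholder for the enhanced signal (the width is
#'   measured on the filtered signal); kept so pipeline stages are
#'   interchangeable
#' @param pre_ms nominal onset offset before R (ms)
#' @param post_ms nominal offset after R (ms)
#' @param width_frac threshold fraction of the R magnitude
#' @param width_search_ms half-width of the measurement window (ms)
#' @param annulus_ms two-element range (ms) of the baseline annulus on each
#'   side of R
#' @return data.frame with columns `onset`, `r`, `offset` (sample indices)
#'   and `width_ms`
#' @export
delineate_qrs <- function(signal, rpeaks, enhanced = NULL,
                          pre_ms = 50, post_ms = 80, width_frac = 0.10,
                          width_search_ms = 100, annulus_ms = c(107, 180)) {
  x <- signal$samples
  n <- length(x)
  fs <- signal$fs
  pre <- ms_to_samples(pre_ms, fs)
  post <- ms_to_samples(post_ms, fs)
  h <- ms_to_samples(width_search_ms, fs)
  a1 <- ms_to_samples(annulus_ms[1L], fs)
  a2 <- ms_to_samples(annulus_ms[2L], fs)
  if (!length(rpeaks))
    return(data.frame(onset = integer(0), r = integer(0),
                      offset = integer(0), width_ms = numeric(0)))
  rpeaks <- as.integer(rpeaks)
  if (any(rpeaks < 1L | rpeaks > n))
    stop("delineate_qrs: R peak outside signal")
  clipped <- rpeaks - pre < 1L | rpeaks + post > n
  if (any(clipped))
    message("delineate_qrs: ", sum(clipped),
            " beat(s) at record boundary; boundaries clipped")
  width <- vapply(rpeaks, function(r0) {
    ann <- c(seq(max(1L, r0 - a2), max(1L, r0 - a1)),
             seq(min(n, r0 + a1), min(n, r0 + a2)))
    b <- median(x[ann])
    w <- max(1L, r0 - h):min(n, r0 + h)
    v <- abs(x[w] - b)
    thr <- width_frac * abs(x[r0] - b)
    if (thr <= 0) return(NA_real_)
    above <- which(v > thr)
    if (!length(above)) return(NA_real_)
    (max(above) - min(above)) * 1000 / fs
  }, numeric(1L))
  data.frame(onset = pmax(rpeaks - pre, 1L),
             r = rpeaks,
             offset = pmin(rpeaks + post, n),
             width_ms = width)
}
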