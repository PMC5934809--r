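#' RR-interval series from R peaks
#'
#' @param rpeaks integer vector of R-peak sample indices
#' @param fs sampling frequency (Hz)
#' @return numeric vector of RR intervals in ms, length `length(rpeaks) - 1`
#'   (empty for fewer than two peaks)
#' @export
compute_rr_series <- function(rpeaks, fs) {
  if (length(rpeaks) < 2L) return(numeric(0))
  diff(as.numeric(rpeaks)) * 1000 / fs
}

#' Causal running-average RR interval
#'
#' For the beat owning the `j`-th RR interval, the average of the previous
#' `window` intervals, excluding the current one (cold start: the mean of
#' all intervals seen so far). The default window of 24 intervals averages
#' whole bigeminy couplets and trigeminy triplets exactly (24 is a multiple
#' of both periods), so the running average stays at the underlying sinus
#' cycle length inside ectopic runs instead of oscillating with the run
#' phase.
#'
#' @param rr RR-interval series (ms)
#' @param window averaging window, in intervals
#' @return numeric vector, same length as `rr`; entry 1 is `NA` (no history)
#' @export
running_avg_rr <- function(rr, window = 24L) {
  n <- length(rr)
  if (!n) return(numeric(0))
  out <- rep(NA_real_, n)
  # direct window sums: a cumulative-sum difference would contaminate the
  # average with rounding noise from distant intervals, and the VPB rule
  # compares rr_prev + rr_next against exactly 2x this value
  for (j in 2:max(2L, n)) {
    if (j > n) break
    lo <- max(1L, j - window)
    out[j] <- sum(rr[lo:(j - 1L)]) / (j - lo)
  }
  out
}

#' Assemble per-beat feature records
#'
#' One record per R peak: previous/next RR interval, causal running-average
#' RR, measured QRS width, and whether the beat's nominal QRS span
#' intersects the noise mask (`in_noise` beats are abandoned by
#' classification and template building). The first beat has no `rr_prev`
#' and the last no `rr_next`; these are explicit `NA`s, never silent zeros.
#'
#' @param rpeaks integer vector of R-peak indices
#' @param qrs delineation data.frame from [delineate_qrs()] (same length)
#' @param mask optional [noise_mask()]
#' @param fs sampling frequency (Hz)
#' @param avg_window running-average window, see [running_avg_rr()]
#' @return data.frame of class `beat_features` with columns `beat_index`,
#'   `r`, `rr_prev_ms`, `rr_next_ms`, `avg_rr_ms`, `qrs_width_ms`, `in_noise`
#' @export
assemble_beat_features <- function(rpeaks, qrs, mask = NULL, fs,
                                   avg_window = 24L) {
  nb <- length(rpeaks)
  if (nrow(qrs) != nb)
    stop("assemble_beat_features: rpeaks and qrs lengths differ")
  rr <- compute_rr_series(rpeaks, fs)
  avg <- running_avg_rr(rr, window = avg_window)
  rr_prev <- c(NA_real_, rr)
  rr_next <- c(rr, NA_real_)
  avg_rr <- c(NA_real_, avg)
  in_noise <- rep(FALSE, nb)
  if (!is.null(mask) && nrow(mask$segments)) {
    for (i in seq_len(nb)) {
      s <- qrs$onset[i]; e <- qrs$offset[i]
      in_noise[i] <- any(mask$segments$start <= e & mask$segments$end >= s)
    }
  }
  out <- data.frame(beat_index = seq_len(nb), r = as.integer(rpeaks),
                    rr_prev_ms = rr_prev, rr_next_ms = rr_next,
                    avg_rr_ms = avg_rr, qrs_width_ms = qrs$width_ms,
                    in_noise = in_noise)
  class(out) <- c("beat_features", "data.frame")
  out
}
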