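#' Rule-based beat classification
#'
#' Applies the physician judgment rules relating QRS width, the current RR
#' interval (`rr_prev`), the next RR interval and the causal running-average
#' RR:
#' \describe{
#'   \item{NB}{width < 120 ms and `0.75 * avg < rr_prev < 1.2 * avg`}
#'   \item{APB}{width < 120 ms, `rr_prev < 0.75 * avg` and
#'     `rr_prev + rr_next < 2 * avg` (premature, non-compensatory pause)}
#'   \item{VPB}{width > 120 ms, `rr_prev < 0.75 * avg` and
#'     `rr_prev + rr_next >= 2 * avg` (premature, full compensatory pause)}
#' }
#' All inequalities are strict as printed (a width of exactly 120 ms is
#' neither narrow nor wide), so at most one rule can fire; anything else is
#' `UNCLASSIFIED`. Beats with undefined neighbors (first/last beat, or no
#' average yet) default to `NB` when narrow, else `UNCLASSIFIED`. Beats
#' flagged `in_noise` carry no label (`NA`).
#'
#' @param features a `beat_features` data.frame from
#'   [assemble_beat_features()]
#' @param wide_ms narrow/wide QRS boundary (ms)
#' @param rr_low,rr_high NB band multipliers on the average RR
#' @param pause compensatory-pause multiplier on the average RR
#' @return character vector of labels (`NB`, `APB`, `VPB`, `UNCLASSIFIED`,
#'   or `NA` for in-noise beats)
#' @export
classify_beats <- function(features, wide_ms = 120, rr_low = 0.75,
                           rr_high = 1.2, pause = 2.0) {
  w <- features$qrs_width_ms
  rp <- features$rr_prev_ms
  rn <- features$rr_next_ms
  av <- features$avg_rr_ms
  lab <- rep("UNCLASSIFIED", nrow(features))
  defined <- !is.na(rp) & !is.na(rn) & !is.na(av) & !is.na(w)
  narrow <- !is.na(w) & w < wide_ms
  wide <- !is.na(w) & w > wide_ms
  nb <- defined & narrow & rp > rr_low * av & rp < rr_high * av
  apb <- defined & narrow & rp < rr_low * av & (rp + rn) < pause * av
  vpb <- defined & wide & rp < rr_low * av & (rp + rn) >= pause * av
  lab[nb] <- "NB"
  lab[apb] <- "APB"
  lab[vpb] <- "VPB"
  # undefined-neighbor policy: never APB/VPB without both neighbors
  lab[!defined & narrow] <- "NB"
  lab[features$in_noise] <- NA_character_
  lab
}

#' @rdname classify_beats
#' @param feat a single beat feature record (one-row data.frame or list with
#'   fields `qrs_width_ms`, `rr_prev_ms`, `rr_next_ms`, `avg_rr_ms`)
#' @param ... passed on to [classify_beats()]
#' @export
classify_beat <- function(feat, ...) {
  df <- data.frame(qrs_width_ms = feat$qrs_width_ms,
                   rr_prev_ms = feat$rr_prev_ms,
                   rr_next_ms = feat$rr_next_ms,
                   avg_rr_ms = feat$avg_rr_ms,
                   in_noise = isTRUE(feat$in_noise))
  classify_beats(df, ...)
}

#' Detect bigeminy and trigeminy runs
#'
#' Scans the beat-label sequence for the two alternation patterns: bigeminy
#' (`BG`, a ventricular premature beat alternating with one sinus-conducted
#' beat) and trigeminy (`TG`, two sinus-conducted beats followed by one
#' VPB). A `VPB` label fills the ventricular slot. The sinus slot accepts an
#' `NB` label, or — when `widths` are supplied — a narrow `UNCLASSIFIED`
#' beat: inside a run, the beat after each VPB sits on the compensatory
#' pause, so its RR exceeds the NB band and it cannot be labeled NB even
#' though it is a perfectly conducted sinus beat. Maximal runs are reported;
#' a BG event needs at least `bg_min` VPBs and a TG event at least `tg_min`
#' triplets (clinical convention: a single couplet is not a rhythm).
#' Events never relabel their member beats.
#'
#' @param labels character vector of beat labels (NA allowed; breaks runs)
#' @param widths optional numeric vector of QRS widths (ms), same length
#' @param bg_min minimum VPB count for a bigeminy event
#' @param tg_min minimum triplet count for a trigeminy event
#' @param wide_ms narrow/wide boundary used with `widths`
#' @return data.frame with columns `kind`, `start_beat`, `end_beat`
#'   (1-based, inclusive beat ordinals)
#' @export
detect_rhythm_events <- function(labels, widths = NULL, bg_min = 3L,
                                 tg_min = 2L, wide_ms = 120) {
  n <- length(labels)
  sym <- rep("X", n)
  sym[!is.na(labels) & labels == "VPB"] <- "V"
  is_n <- !is.na(labels) & labels == "NB"
  if (!is.null(widths))
    is_n <- is_n | (!is.na(labels) & labels == "UNCLASSIFIED" &
                      !is.na(widths) & widths < wide_ms)
  sym[is_n] <- "N"

  events <- list()
  # bigeminy: maximal strict alternation starting at a VPB
  i <- 1L
  while (i <= n) {
    if (sym[i] == "V") {
      j <- i
      while (j < n && sym[j + 1L] != "X" && sym[j + 1L] != sym[j]) j <- j + 1L
      nv <- sum(sym[i:j] == "V")
      if (nv >= bg_min) {
        events[[length(events) + 1L]] <-
          data.frame(kind = "BG", start_beat = i, end_beat = j)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  # trigeminy: repeated (N, N, V) triplets, trailing partial Ns included
  i <- 1L
  while (i + 2L <= n) {
    if (sym[i] == "N" && sym[i + 1L] == "N" && sym[i + 2L] == "V") {
      j <- i + 2L
      ntrip <- 1L
      while (j + 3L <= n && sym[j + 1L] == "N" && sym[j + 2L] == "N" &&
               sym[j + 3L] == "V") {
        j <- j + 3L
        ntrip <- ntrip + 1L
      }
      tail_n <- 0L
      while (j < n && tail_n < 2L && sym[j + 1L] == "N") {
        j <- j + 1L
        tail_n <- tail_n + 1L
      }
      if (ntrip >= tg_min) {
        events[[length(events) + 1L]] <-
          data.frame(kind = "TG", start_beat = i, end_beat = j)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(events))
    return(data.frame(kind = character(0), start_beat = integer(0),
                      end_beat = integer(0)))
  out <- do.call(rbind, events)
  out[order(out$start_beat, out$kind), , drop = FALSE]
}

# normalized (Pearson) cross-correlation at zero lag
ncc <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  d <- sqrt(sum(a * a) * sum(b * b))
  if (d == 0) return(0)
  sum(a * b) / d
}

beat_window <- function(x, r0, half) {
  n <- length(x)
  if (r0 - half < 1L || r0 + half > n) return(NULL)
  x[(r0 - half):(r0 + half)]
}

#' Build a normal-beat template
#'
#' Pointwise mean of the waveforms (R +/- `window_ms`) of up to `max_beats`
#' noise-free beats labeled NB, amplitude-normalized to unit peak magnitude.
#' Templates are only built from noise-free signal ("QRS complex templates
#' are generated from noise-free signals"); with no eligible beat the
#' template is unavailable and `NULL` is returned with a warning, in which
#' case the correction step is skipped.
#'
#' @param signal the filtered [ecg_signal()]
#' @param feats `beat_features` data.frame
#' @param labels beat labels from [classify_beats()]
#' @param max_beats maximum number of beats averaged
#' @param window_ms half-window around R (ms)
#' @return an object of class `nb_template` (fields `waveform`, `window_ms`,
#'   `n_beats`), or `NULL` if no eligible beat exists
#' @export
build_template <- function(signal, feats, labels, max_beats = 50L,
                           window_ms = 100) {
  half <- ms_to_samples(window_ms, signal$fs)
  ok <- which(!is.na(labels) & labels == "NB" & !feats$in_noise)
  wins <- list()
  for (i in ok) {
    w <- beat_window(signal$samples, feats$r[i], half)
    if (!is.null(w)) wins[[length(wins) + 1L]] <- w
    if (length(wins) >= max_beats) break
  }
  if (!length(wins)) {
    warning("build_template: no noise-free NB beat; template unavailable")
    return(NULL)
  }
  tmpl <- rowMeans(do.call(cbind, wins))
  tmpl <- tmpl / max(abs(tmpl))
  structure(list(waveform = tmpl, window_ms = window_ms,
                 n_beats = length(wins)),
            class = "nb_template")
}

#' @export
print.nb_template <- function(x, ...) {
  cat(sprintf("<nb_template> %d samples (R +/- %g ms), averaged over %d beats\n",
              length(x$waveform), x$window_ms, x$n_beats))
  invisible(x)
}

#' Reconfirm abnormal beats by template matching
#'
#' A beat labeled abnormal whose normalized cross-correlation with the
#' normal-beat template reaches `corr` has normal morphology and is
#' relabeled NB (demotion only; NB beats are never changed, so the
#' operation is idempotent). By default only `VPB` labels are reconsidered:
#' a ventricular claim asserts abnormal morphology, which the template test
#' can refute, whereas an atrial premature beat conducts through the normal
#' pathway and matches the NB template by nature — reconfirming APBs against
#' it would erase them. Set `classes = c("APB", "VPB")` for the stricter
#' behaviour.
#'
#' @param labels beat labels
#' @param signal the filtered [ecg_signal()]
#' @param feats `beat_features` data.frame
#' @param template an `nb_template` from [build_template()] (NULL skips
#'   correction)
#' @param corr correlation threshold
#' @param classes labels eligible for demotion
#' @return corrected label vector
#' @export
template_correct <- function(labels, signal, feats, template, corr = 0.9,
                             classes = "VPB") {
  if (is.null(template)) {
    warning("template_correct: template unavailable; labels unchanged")
    return(labels)
  }
  half <- (length(template$waveform) - 1L) %/% 2L
  for (i in which(!is.na(labels) & labels %in% classes)) {
    w <- beat_window(signal$samples, feats$r[i], half)
    if (is.null(w)) next
    if (ncc(w, template$waveform) >= corr) labels[i] <- "NB"
  }
  labels
}
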