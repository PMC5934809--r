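#' Match predicted beats against ground truth
#'
#' Greedy nearest-neighbour one-to-one pairing of R-peak indices within a
#' time tolerance (default 75 ms, half the common 150 ms acceptance window).
#' Candidate pairs are assigned in order of increasing time difference (ties
#' broken by truth then prediction order, so matching is deterministic).
#' Unpaired truth beats are detection misses.
#'
#' @param pred,truth [annotation_set()]s (or plain integer index vectors)
#' @param fs sampling frequency (Hz)
#' @param tol_ms matching tolerance (ms)
#' @return list with `pairs` (data.frame `truth_i`, `pred_i`, `dt_ms`),
#'   `unmatched_truth` and `unmatched_pred` (index positions)
#' @export
match_beats <- function(pred, truth, fs, tol_ms = 75) {
  p_idx <- if (inherits(pred, "ecg_annotations")) pred$beats$index else
    as.integer(pred)
  t_idx <- if (inherits(truth, "ecg_annotations")) truth$beats$index else
    as.integer(truth)
  tol <- tol_ms * fs / 1000
  np <- length(p_idx); nt <- length(t_idx)
  if (!np || !nt) {
    return(list(pairs = data.frame(truth_i = integer(0), pred_i = integer(0),
                                   dt_ms = numeric(0)),
                unmatched_truth = seq_len(nt), unmatched_pred = seq_len(np)))
  }
  # candidate pairs: for each truth beat, predictions within tolerance
  cand <- do.call(rbind, lapply(seq_len(nt), function(i) {
    lo <- findInterval(t_idx[i] - tol, p_idx) + 1L
    hi <- findInterval(t_idx[i] + tol, p_idx)
    if (lo > hi) return(NULL)
    data.frame(truth_i = i, pred_i = lo:hi,
               adt = abs(p_idx[lo:hi] - t_idx[i]))
  }))
  pairs <- data.frame(truth_i = integer(0), pred_i = integer(0),
                      dt_ms = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$adt, cand$truth_i, cand$pred_i), , drop = FALSE]
    used_t <- logical(nt); used_p <- logical(np)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$truth_i[k]; j <- cand$pred_i[k]
      if (!used_t[i] && !used_p[j]) {
        used_t[i] <- TRUE; used_p[j] <- TRUE; keep[k] <- TRUE
      }
    }
    m <- cand[keep, , drop = FALSE]
    m <- m[order(m$truth_i), , drop = FALSE]
    pairs <- data.frame(truth_i = m$truth_i, pred_i = m$pred_i,
                        dt_ms = (p_idx[m$pred_i] - t_idx[m$truth_i]) *
                          1000 / fs)
  }
  list(pairs = pairs,
       unmatched_truth = setdiff(seq_len(nt), pairs$truth_i),
       unmatched_pred = setdiff(seq_len(np), pairs$pred_i))
}

#' One-vs-rest confusion counts
#'
#' Counts TPOS/TNEG/FPOS/FNEG for one class over paired (truth, predicted)
#' labels; a missing prediction (`NA`, detection miss) counts as FNEG when
#' the truth is the class, and as a negative prediction otherwise.
#'
#' @param truth_labels,pred_labels character vectors, same length
#' @param class the class to score
#' @return object of class `confusion_counts` (fields `tpos`, `tneg`,
#'   `fpos`, `fneg`, `class_label`)
#' @export
confusion_counts <- function(truth_labels, pred_labels, class) {
  if (length(truth_labels) != length(pred_labels))
    stop("confusion_counts: label vectors differ in length")
  tp <- !is.na(pred_labels) & pred_labels == class
  tt <- truth_labels == class
  structure(list(tpos = sum(tt & tp), fneg = sum(tt & !tp),
                 fpos = sum(!tt & tp), tneg = sum(!tt & !tp),
                 class_label = class),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s: TPOS=%d FNEG=%d FPOS=%d TNEG=%d\n",
              x$class_label, x$tpos, x$fneg, x$fpos, x$tneg))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACCU = (TPOS + TNEG) / (TPOS + FNEG + FPOS + TNEG)`,
#' `SENS = TPOS / (TPOS + FNEG)`, `SPEC = TNEG / (FPOS + TNEG)`.
#' A zero denominator yields an explicit `NA`, never a silent zero.
#'
#' @param counts a [confusion_counts()] object (or list with the four
#'   fields)
#' @return named numeric vector `c(accu, sens, spec)`, fractions in `[0, 1]`
#' @export
perf <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, c(
    accu = safe_div(tpos + tneg, tpos + fneg + fpos + tneg),
    sens = safe_div(tpos, tpos + fneg),
    spec = safe_div(tneg, fpos + tneg)))
}

#' Parallel speedup ratio
#'
#' `SP = Ts / Tp`: execution time on a single processor over execution time
#' of the parallel program. A pure ratio calculator for user-supplied
#' measurements.
#'
#' @param t_s,t_p sequential and parallel execution times (s), > 0
#' @return the speedup ratio
#' @export
speedup <- function(t_s, t_p) {
  if (t_s <= 0 || t_p <= 0) stop("speedup: times must be positive")
  t_s / t_p
}

#' Energy-saving fraction
#'
#' `E_save = (E_s - E_p) / E_s`: the fraction of the sequential program's
#' energy consumption saved by the parallel program.
#'
#' @param e_s,e_p sequential and parallel energy consumption (mWh); `e_s`
#'   must be > 0
#' @return saved fraction
#' @export
energy_saving <- function(e_s, e_p) {
  if (e_s <= 0) stop("energy_saving: e_s must be positive")
  (e_s - e_p) / e_s
}

# sample span [first R, last R] of an event given its beat table
event_span <- function(ev, beats) {
  cbind(start = beats$index[ev$start_beat], end = beats$index[ev$end_beat])
}

#' Score predicted annotations against ground truth
#'
#' Beat- and event-level one-vs-rest scoring over the scored ground-truth
#' instances. A scored truth beat's predicted class is the label of its
#' matched predicted beat ([match_beats()]); a detection miss counts against
#' the truth class. A truth rhythm event (bigeminy couplet / trigeminy
#' triplet) is predicted positive when any predicted event of the same kind
#' overlaps its sample span; scored instances of other kinds covered by such
#' an event count as its false positives. Per class, TPOS + FNEG equals the
#' number of scored truth instances of the class and the four counts sum to
#' the instance universe, so accuracy, sensitivity and specificity are all
#' well-defined.
#'
#' @param pred predicted [annotation_set()]
#' @param truth ground-truth [annotation_set()]
#' @param fs sampling frequency (Hz)
#' @param tol_ms beat-matching tolerance (ms)
#' @param classes classes to report
#' @return data.frame of class `perf_report` (one row per class plus the
#'   four counts and accu/sens/spec as fractions); macro averages are
#'   attached as attribute `"macro"`
#' @export
score_annotations <- function(pred, truth, fs, tol_ms = 75,
                              classes = c("NB", "APB", "VPB", "BG", "TG")) {
  tb <- truth$beats
  pb <- pred$beats
  mb <- match_beats(pred, truth, fs = fs, tol_ms = tol_ms)
  pred_lab_of_truth <- rep(NA_character_, nrow(tb))
  pred_lab_of_truth[mb$pairs$truth_i] <- pb$label[mb$pairs$pred_i]

  beat_classes <- intersect(classes, c("NB", "APB", "VPB"))
  event_classes <- intersect(classes, c("BG", "TG"))

  scored_beat <- which(tb$scored & tb$label %in% beat_classes)
  inst_truth <- tb$label[scored_beat]
  inst_span <- cbind(start = tb$index[scored_beat],
                     end = tb$index[scored_beat])
  inst_pred <- list()
  for (cl in beat_classes)
    inst_pred[[cl]] <- !is.na(pred_lab_of_truth[scored_beat]) &
      pred_lab_of_truth[scored_beat] == cl
  for (cl in event_classes) inst_pred[[cl]] <- rep(FALSE, length(scored_beat))

  te <- truth$events[truth$events$kind %in% event_classes, , drop = FALSE]
  if (nrow(te)) {
    tspan <- event_span(te, tb)
    inst_truth <- c(inst_truth, te$kind)
    inst_span <- rbind(inst_span, tspan)
    for (cl in beat_classes)
      inst_pred[[cl]] <- c(inst_pred[[cl]], rep(FALSE, nrow(te)))
    for (cl in event_classes)
      inst_pred[[cl]] <- c(inst_pred[[cl]], rep(FALSE, nrow(te)))
  }
  for (cl in event_classes) {
    pe <- pred$events[pred$events$kind == cl, , drop = FALSE]
    if (!nrow(pe)) next
    pspan <- event_span(pe, pb)
    covered <- vapply(seq_len(nrow(inst_span)), function(i)
      any(pspan[, "start"] <= inst_span[i, "end"] &
            pspan[, "end"] >= inst_span[i, "start"]), logical(1L))
    inst_pred[[cl]] <- inst_pred[[cl]] | covered
  }

  rows <- lapply(classes, function(cl) {
    tt <- inst_truth == cl
    pp <- inst_pred[[cl]]
    cc <- list(tpos = sum(tt & pp), fneg = sum(tt & !pp),
               fpos = sum(!tt & pp), tneg = sum(!tt & !pp))
    pf <- perf(cc)
    data.frame(class = cl, n = sum(tt), tpos = cc$tpos, fneg = cc$fneg,
               fpos = cc$fpos, tneg = cc$tneg,
               sens = pf["sens"], spec = pf["spec"], accu = pf["accu"],
               row.names = NULL)
  })
  rep_df <- do.call(rbind, rows)
  class(rep_df) <- c("perf_report", "data.frame")
  attr(rep_df, "macro") <- c(sens = mean(rep_df$sens, na.rm = TRUE),
                             spec = mean(rep_df$spec, na.rm = TRUE),
                             accu = mean(rep_df$accu, na.rm = TRUE))
  rep_df
}

#' Pool several per-record confusion tables into one report
#'
#' Sums the per-class TPOS/FNEG/FPOS/TNEG counts of multiple `perf_report`s
#' (e.g. one per record of a fixture set) and recomputes the rates on the
#' pooled counts.
#'
#' @param reports list of `perf_report` data.frames with identical class
#'   rows
#' @return pooled `perf_report`
#' @export
pool_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  out <- reports[[1L]][, c("class", "n", "tpos", "fneg", "fpos", "tneg")]
  for (r in reports[-1L]) {
    stopifnot(identical(r$class, out$class))
    for (col in c("n", "tpos", "fneg", "fpos", "tneg"))
      out[[col]] <- out[[col]] + r[[col]]
  }
  pf <- t(vapply(seq_len(nrow(out)), function(i) perf(out[i, ]),
                 numeric(3L)))
  out$sens <- pf[, "sens"]; out$spec <- pf[, "spec"]; out$accu <- pf[, "accu"]
  class(out) <- c("perf_report", "data.frame")
  attr(out, "macro") <- c(sens = mean(out$sens, na.rm = TRUE),
                          spec = mean(out$spec, na.rm = TRUE),
                          accu = mean(out$accu, na.rm = TRUE))
  out
}

#' @export
print.perf_report <- function(x, ...) {
  cat("Per-class performance (%):\n")
  df <- data.frame(class = x$class, n = x$n,
                   SENS = round(100 * x$sens, 2),
                   SPEC = round(100 * x$spec, 2),
                   ACCU = round(100 * x$accu, 2))
  print.data.frame(df, row.names = FALSE)
  m <- attr(x, "macro")
  if (!is.null(m))
    cat(sprintf("Average: SENS %.2f%%  SPEC %.2f%%  ACCU %.2f%%\n",
                100 * m["sens"], 100 * m["spec"], 100 * m["accu"]))
  invisible(x)
}

#' Write a performance report as CSV (percentages)
#'
#' Columns mirror the usual arrhythmia-evaluation table layout: class,
#' number of scored instances, SENS, SPEC and ACCU in percent.
#'
#' @param report a `perf_report`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_perf_csv <- function(report, path) {
  df <- data.frame(class = report$class, n = report$n,
                   sens_pct = 100 * report$sens,
                   spec_pct = 100 * report$spec,
                   accu_pct = 100 * report$accu)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
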