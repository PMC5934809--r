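#' Pipeline configuration
#'
#' Nested per-stage configuration with validated keys. Any subset can be
#' overridden; unknown keys raise an error. `trim$minutes = NULL` selects
#' automatically: 2 minutes for records longer than 10 minutes (unstable
#' attachment edges), 0 for short records.
#'
#' @param ... named stage overrides, e.g.
#'   `rules = list(wide_ms = 120)`, `backend = "naive"`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    backend = "vectorized",
    trim = list(minutes = NULL),
    filter = list(order = 3L, low_hz = 0.5, high_hz = 40),
    artifact = list(window_s = 2, burst_k = 4, flat_mv = 0.05,
                    full_scale_mv = 5, history = 30L),
    morph = list(baseline_s = 0.2, peak_s = 0.06),
    rdet = list(threshold_frac = 0.4, refractory_ms = 200,
                searchback_factor = 1.5, init_s = 10, history = 8L),
    qrs = list(pre_ms = 50, post_ms = 80, width_frac = 0.10,
               width_search_ms = 100, annulus_ms = c(107, 180)),
    features = list(avg_window = 24L),
    rules = list(wide_ms = 120, rr_low = 0.75, rr_high = 1.2, pause = 2.0),
    tmpl = list(corr = 0.9, max_beats = 50L, window_ms = 100,
                classes = "VPB"),
    events = list(bg_min = 3L, tg_min = 2L),
    metrics = list(tol_ms = 75))
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("pipeline_config: unknown key(s): ",
                        paste(bad, collapse = ", "))
  for (k in names(over)) {
    if (is.list(defaults[[k]]) && is.list(over[[k]])) {
      badk <- setdiff(names(over[[k]]), names(defaults[[k]]))
      if (length(badk)) stop("pipeline_config: unknown key(s) in '", k,
                             "': ", paste(badk, collapse = ", "))
      defaults[[k]][names(over[[k]])] <- over[[k]]
    } else {
      defaults[[k]] <- over[[k]]
    }
  }
  if (!defaults$backend %in% c("vectorized", "naive"))
    stop("pipeline_config: backend must be 'vectorized' or 'naive'")
  structure(defaults, class = "pipeline_config")
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes trim, band-pass filter, morphological R-peak enhancement,
#' artifact masking, dynamic-threshold R detection, QRS delineation,
#' feature assembly, rule classification, rhythm-run detection and
#' normal-template correction, returning predicted annotations, optional
#' scoring against supplied ground truth, and per-stage wall-clock timings.
#' The artifact mask is independent of detection (in a parallel realization
#' the two run concurrently) but is always applied before classification:
#' beats whose QRS span touches a masked segment are abandoned.
#'
#' @param signal an [ecg_signal()]
#' @param config a [pipeline_config()]
#' @param truth optional ground-truth [annotation_set()] for scoring
#' @return list of class `ecg_analysis` with elements `annotations`
#'   ([annotation_set()]; in-noise beats are excluded), `report`
#'   (`perf_report` or NULL), `timings` (data.frame `stage`, `seconds`,
#'   `fraction`), `features`, `labels` and `n_noise_beats`
#' @export
run_pipeline <- function(signal, config = pipeline_config(), truth = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- stage_call(stage, expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  backend <- config$backend

  minutes <- config$trim$minutes
  if (is.null(minutes))
    minutes <- if (signal_duration(signal) > 600) 2 else 0
  sig <- clock("trim", trim_edges(signal, minutes = minutes))
  if (length(sig$samples) < 2L)
    stop("run_pipeline: empty signal after trimming")
  filt <- clock("filter", bandpass_filter(
    sig, low_hz = config$filter$low_hz, high_hz = config$filter$high_hz,
    order = config$filter$order))
  enh <- clock("morphology", morphological_transform(
    filt, baseline_s = config$morph$baseline_s,
    peak_s = config$morph$peak_s, backend = backend))
  mask <- clock("artifact_mask", do.call(detect_artifacts,
                                         c(list(filt), config$artifact)))
  rpeaks <- clock("r_detection", do.call(detect_r_peaks,
                                         c(list(enh, mask), config$rdet)))
  qrs <- clock("qrs_delineation", do.call(delineate_qrs,
                                          c(list(filt, rpeaks, enh),
                                            config$qrs)))
  feats <- clock("features", assemble_beat_features(
    rpeaks, qrs, mask, fs = filt$fs,
    avg_window = config$features$avg_window))
  labels <- clock("classification", do.call(classify_beats,
                                            c(list(feats), config$rules)))
  labels <- clock("template_correction", {
    tmpl <- build_template(filt, feats, labels,
                           max_beats = config$tmpl$max_beats,
                           window_ms = config$tmpl$window_ms)
    if (is.null(tmpl)) labels else
      template_correct(labels, filt, feats, tmpl,
                       corr = config$tmpl$corr,
                       classes = config$tmpl$classes)
  })
  events <- clock("rhythm_events", detect_rhythm_events(
    labels, widths = feats$qrs_width_ms,
    bg_min = config$events$bg_min, tg_min = config$events$tg_min,
    wide_ms = config$rules$wide_ms))

  keep <- which(!is.na(labels))
  remap <- match(seq_along(labels), keep)
  ev_keep <- events
  if (nrow(ev_keep)) {
    # events reference positions among retained (non-noise) beats
    ev_keep$start_beat <- remap[ev_keep$start_beat]
    ev_keep$end_beat <- remap[ev_keep$end_beat]
    ev_keep <- ev_keep[!is.na(ev_keep$start_beat) &
                         !is.na(ev_keep$end_beat), , drop = FALSE]
  }
  ann <- annotation_set(
    beats = data.frame(index = feats$r[keep], label = labels[keep],
                       scored = TRUE),
    events = ev_keep)

  report <- NULL
  if (!is.null(truth))
    report <- clock("scoring", score_annotations(
      ann, truth, fs = filt$fs, tol_ms = config$metrics$tol_ms))

  tdf <- data.frame(stage = names(timings),
                    seconds = as.numeric(unlist(timings)))
  tdf$fraction <- tdf$seconds / max(sum(tdf$seconds), .Machine$double.eps)
  structure(list(annotations = ann, report = report, timings = tdf,
                 features = feats, labels = labels,
                 n_noise_beats = sum(is.na(labels))),
            class = "ecg_analysis")
}

#' @export
print.ecg_analysis <- function(x, ...) {
  print(x$annotations)
  if (x$n_noise_beats)
    cat(sprintf("  (%d beat(s) abandoned inside artifact segments)\n",
                x$n_noise_beats))
  cat(sprintf("total time %.2f s\n", sum(x$timings$seconds)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
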