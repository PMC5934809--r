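feat_row <- function(width, rp, rn, avg, in_noise = FALSE) {
  data.frame(qrs_width_ms = width, rr_prev_ms = rp, rr_next_ms = rn,
             avg_rr_ms = avg, in_noise = in_noise)
}

test_that("judgment rules label the forced examples", {
  expect_equal(classify_beat(feat_row(100, 1000, 1000, 1000)), "NB")
  expect_equal(classify_beat(feat_row(100, 600, 1200, 1000)), "APB")
  expect_equal(classify_beat(feat_row(160, 700, 1400, 1000)), "VPB")
  # exactly 120 ms is neither narrow nor wide
  expect_equal(classify_beat(feat_row(120, 600, 1400, 1000)), "UNCLASSIFIED")
  # compensatory boundary is inclusive for VPB
  expect_equal(classify_beat(feat_row(160, 600, 1400, 1000)), "VPB")
  # in-noise beats carry no label
  expect_true(is.na(classify_beat(feat_row(100, 1000, 1000, 1000, TRUE))))
  # undefined-neighbor policy: narrow -> NB, wide -> UNCLASSIFIED
  expect_equal(classify_beat(feat_row(100, NA, 1000, NA)), "NB")
  expect_equal(classify_beat(feat_row(160, NA, 1000, NA)), "UNCLASSIFIED")
})

test_that("at most one rule fires anywhere on the feature grid", {
  grid <- expand.grid(width = c(60, 100, 119.9, 120, 120.1, 160),
                      rp = seq(400, 1600, by = 100),
                      rn = seq(400, 1600, by = 100),
                      avg = c(800, 1000, 1250))
  # independent statement of the three rules, straight from the rule table
  nb <- grid$width < 120 & 0.75 * grid$avg < grid$rp & grid$rp < 1.2 * grid$avg
  apb <- grid$width < 120 & grid$rp < 0.75 * grid$avg &
    grid$rp + grid$rn < 2 * grid$avg
  vpb <- grid$width > 120 & grid$rp < 0.75 * grid$avg &
    grid$rp + grid$rn >= 2 * grid$avg
  expect_true(all(nb + apb + vpb <= 1L))
  labels <- classify_beats(feat_row(grid$width, grid$rp, grid$rn, grid$avg))
  expected <- rep("UNCLASSIFIED", nrow(grid))
  expected[nb] <- "NB"; expected[apb] <- "APB"; expected[vpb] <- "VPB"
  expect_equal(labels, expected)
})

test_that("alternation runs are detected as specified", {
  ev <- detect_rhythm_events(c("VPB", "NB", "VPB", "NB", "VPB", "NB"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "BG")
  expect_equal(c(ev$start_beat, ev$end_beat), c(1L, 6L))

  ev <- detect_rhythm_events(c("NB", "NB", "VPB", "NB", "NB", "VPB",
                               "NB", "NB"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "TG")
  expect_equal(c(ev$start_beat, ev$end_beat), c(1L, 8L))

  expect_equal(nrow(detect_rhythm_events(rep("NB", 12))), 0L)
  # two VPB-NB couplets are below the run threshold
  expect_equal(nrow(detect_rhythm_events(c("VPB", "NB", "VPB", "NB"))), 0L)
  # a narrow UNCLASSIFIED beat fills the sinus slot only with widths given
  lab <- c("VPB", "UNCLASSIFIED", "VPB", "UNCLASSIFIED", "VPB", "NB")
  expect_equal(nrow(detect_rhythm_events(lab)), 0L)
  wid <- c(140, 50, 140, 50, 140, 50)
  ev <- detect_rhythm_events(lab, widths = wid)
  expect_equal(ev$kind, "BG")
  expect_equal(c(ev$start_beat, ev$end_beat), c(1L, 6L))
})

test_that("run detector matches a regex oracle on all short label strings", {
  # independent oracle: greedy leftmost-longest regular-expression matching
  oracle <- function(sym) {
    s <- paste(sym, collapse = "")
    out <- data.frame(kind = character(0), start_beat = integer(0),
                      end_beat = integer(0))
    for (pat in c(BG = "V(NV){2,}N?", TG = "(NNV){2,}N{0,2}")) {
      m <- gregexpr(pat, s)[[1L]]
      if (m[1L] != -1L)
        out <- rbind(out, data.frame(
          kind = names(which(c(BG = "V(NV){2,}N?",
                               TG = "(NNV){2,}N{0,2}") == pat)),
          start_beat = as.integer(m),
          end_beat = as.integer(m) + attr(m, "match.length") - 1L))
    }
    out <- out[order(out$start_beat, out$kind), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  for (len in 1:9) {
    combos <- expand.grid(rep(list(c("NB", "VPB")), len),
                          stringsAsFactors = FALSE)
    for (row in seq_len(nrow(combos))) {
      labels <- unlist(combos[row, ], use.names = FALSE)
      got <- detect_rhythm_events(labels)
      rownames(got) <- NULL
      want <- oracle(ifelse(labels == "VPB", "V", "N"))
      expect_identical(got, want,
                       label = paste("labels:", paste(labels, collapse = ",")))
    }
  }
})

test_that("normal-beat template averages identical beats to themselves", {
  rec <- generate_record(short_config(all_nb_script(55L), rr_jitter_ms = 0))
  filt <- bandpass_filter(rec$signal)
  r_idx <- rec$annotations$beats$index
  q <- delineate_qrs(filt, r_idx)
  f <- assemble_beat_features(r_idx, q, NULL, 150)
  labels <- classify_beats(f)
  tmpl <- build_template(filt, f, labels)
  expect_s3_class(tmpl, "nb_template")
  expect_length(tmpl$waveform, 2L * 15L + 1L)  # 2 * round(100 * 150/1000) + 1
  # template matches a held-out beat nearly perfectly
  held <- f$r[length(r_idx) - 2L]
  w <- filt$samples[(held - 15L):(held + 15L)]
  expect_gte(ecgflow:::ncc(w, tmpl$waveform), 0.95)
})

test_that("template building requires eligible noise-free NB beats", {
  rec <- generate_record(short_config(all_nb_script(20L), duration_s = 25))
  filt <- bandpass_filter(rec$signal)
  r_idx <- rec$annotations$beats$index
  q <- delineate_qrs(filt, r_idx)
  f <- assemble_beat_features(r_idx, q, NULL, 150)
  labels <- rep("VPB", nrow(f))
  expect_warning(tmpl <- build_template(filt, f, labels), "unavailable")
  expect_null(tmpl)
  expect_warning(out <- template_correct(labels, filt, f, NULL), "unchanged")
  expect_identical(out, labels)
})

test_that("template correction demotes false positives, keeps true VPBs", {
  rec <- generate_record(short_config(mixed_script()))
  filt <- bandpass_filter(rec$signal)
  truth <- rec$annotations$beats
  q <- delineate_qrs(filt, truth$index)
  f <- assemble_beat_features(truth$index, q, NULL, 150)
  labels <- classify_beats(f)
  tmpl <- build_template(filt, f, labels)

  # a true (wide) VPB correlates poorly with the normal template
  vpb_i <- which(truth$label == "VPB")
  w <- filt$samples[(f$r[vpb_i] - 15L):(f$r[vpb_i] + 15L)]
  expect_lt(ecgflow:::ncc(w, tmpl$waveform), 0.9)
  corrected <- template_correct(labels, filt, f, tmpl)
  expect_equal(corrected[vpb_i], "VPB")

  # a normal-morphology beat mislabeled by an RR glitch is demoted
  forced <- labels
  nb_i <- which(truth$label == "NB")[10L]
  forced[nb_i] <- "VPB"
  fixed <- template_correct(forced, filt, f, tmpl)
  expect_equal(fixed[nb_i], "NB")
  # with the strict class set the same applies to a fake APB
  forced[nb_i] <- "APB"
  fixed <- template_correct(forced, filt, f, tmpl,
                            classes = c("APB", "VPB"))
  expect_equal(fixed[nb_i], "NB")

  # idempotence and identity on all-normal records
  once <- template_correct(labels, filt, f, tmpl)
  expect_identical(template_correct(once, filt, f, tmpl), once)
  all_nb <- rep("NB", nrow(f))
  expect_identical(template_correct(all_nb, filt, f, tmpl), all_nb)
})
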