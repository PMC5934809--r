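test_that("band-pass removes DC and attenuates out-of-band components", {
  fs <- 150
  tt <- seq(0, 30, by = 1 / fs)
  mid <- seq(10 * fs, 20 * fs)  # steady-state region, away from edges

  dc <- bandpass_filter(ecg_signal(rep(1, length(tt)), fs))
  expect_lt(max(abs(dc$samples[mid])), 0.01)

  s10 <- bandpass_filter(ecg_signal(sin(2 * pi * 10 * tt), fs))
  amp10 <- max(abs(s10$samples[mid]))
  expect_gt(amp10, 0.9)
  expect_lt(amp10, 1.1)

  s60 <- bandpass_filter(ecg_signal(sin(2 * pi * 60 * tt), fs))
  expect_lte(max(abs(s60$samples[mid])), 0.5)
})

test_that("filtering is idempotent in the passband sense", {
  fs <- 150
  tt <- seq(0, 30, by = 1 / fs)
  mid <- seq(10 * fs, 20 * fs)
  once <- bandpass_filter(ecg_signal(sin(2 * pi * 10 * tt), fs))
  twice <- bandpass_filter(once)
  a1 <- max(abs(once$samples[mid]))
  a2 <- max(abs(twice$samples[mid]))
  expect_lt(abs(a2 - a1), 0.15 * a1)
})

test_that("band-pass validates cutoffs and preserves geometry", {
  sig <- ecg_signal(rnorm(450), fs = 150, lead = "II", t0 = 7)
  out <- bandpass_filter(sig)
  expect_length(out$samples, length(sig$samples))
  expect_equal(out$fs, sig$fs)
  expect_equal(out$t0, sig$t0)
  expect_error(bandpass_filter(sig, high_hz = 75), "Nyquist")
  expect_error(bandpass_filter(sig, low_hz = 0), "low_hz")
})

test_that("edge trimming drops the unstable recording edges", {
  fs <- 150
  sig <- ecg_signal(seq_len(5 * 60 * fs), fs)  # 5 minutes
  out <- trim_edges(sig, minutes = 2)
  expect_length(out$samples, 60 * fs)           # 1 min remainder
  expect_equal(out$t0, 120)
  expect_equal(out$samples[1], 2 * 60 * fs + 1) # interior slice
  expect_identical(trim_edges(sig, minutes = 0), sig)
  short <- ecg_signal(seq_len(3 * 60 * fs), fs)
  expect_error(trim_edges(short, minutes = 2), "shorter")
  # 24 h at 150 Hz -> length 150 * (86400 - 240)
  expect_equal(86400 * fs - 2L * as.integer(round(2 * 60 * fs)),
               fs * (86400 - 240))
})

test_that("clean synthetic records yield an almost empty artifact mask", {
  rec <- generate_record(short_config(all_nb_script(297L), duration_s = 300))
  filt <- bandpass_filter(rec$signal)
  mask <- detect_artifacts(filt)
  expect_length(mask$flags, length(filt$samples))
  expect_lt(mean(mask$flags), 0.01)
})

test_that("injected bursts and flatlines are flagged", {
  noise <- list(burst = data.frame(start_s = 10, dur_s = 2, amp_mv = 4),
                flatline = data.frame(start_s = 29.5, dur_s = 5))
  rec <- generate_record(short_config(all_nb_script(55L), duration_s = 60,
                                      noise = noise))
  filt <- bandpass_filter(rec$signal)
  mask <- detect_artifacts(filt)
  fs <- filt$fs
  burst_i <- (10 * fs + 1):(12 * fs)
  expect_gte(mean(mask$flags[burst_i]), 0.9)
  # flatline interior (away from the filter's edge ringing at the
  # discontinuities) is flagged
  flat_i <- (30 * fs + 1):(34 * fs)
  expect_gte(mean(mask$flags[flat_i]), 0.9)
})

test_that("saturated samples are masked", {
  fs <- 150
  rec <- generate_record(short_config(all_nb_script(25L), duration_s = 30))
  x <- rec$signal$samples
  x[(5 * fs):(6 * fs)] <- 4.999               # near the 5 mV bound
  mask <- detect_artifacts(ecg_signal(x, fs))
  expect_true(all(mask$flags[(5 * fs):(6 * fs)]))
})

test_that("noise mask segments are exactly the maximal flagged runs", {
  flags <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  m <- noise_mask(flags)
  expect_equal(m$segments$start, c(2L, 6L, 8L))
  expect_equal(m$segments$end, c(3L, 6L, 10L))
  rebuilt <- logical(length(flags))
  for (i in seq_len(nrow(m$segments)))
    rebuilt[m$segments$start[i]:m$segments$end[i]] <- TRUE
  expect_identical(rebuilt, flags)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(m, tmp)
  bed <- read.csv(tmp)
  expect_equal(bed$start_sample, c(2L, 6L, 8L))
  expect_equal(bed$end_sample, c(3L, 6L, 10L))
})

test_that("mask of a concatenation covers the masks of its parts", {
  noise <- list(burst = data.frame(start_s = 5, dur_s = 2, amp_mv = 4))
  rec <- generate_record(short_config(all_nb_script(25L), duration_s = 30,
                                      noise = noise))
  a <- bandpass_filter(rec$signal)$samples
  whole <- detect_artifacts(ecg_signal(c(a, a), 150))
  part <- detect_artifacts(ecg_signal(a, 150))
  # flagged samples of the first part stay flagged in the concatenation
  # (up to one window of boundary slack)
  w <- 2 * 150
  core <- which(part$flags)
  core <- core[core <= length(a) - w]
  expect_gte(mean(whole$flags[core]), 0.9)
})
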