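test_that("native CSV signals round-trip exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs=150 lead=II t0=0", "0.0", "0.5", "0.0"), tmp)
  sig <- read_signal(tmp, format = "native_csv")
  expect_s3_class(sig, "ecg_signal")
  expect_length(sig$samples, 3L)
  expect_equal(sig$fs, 150)
  expect_equal(sig$lead, "II")

  x <- ecg_signal(sin(seq(0, 10, length.out = 500)) + 0.123456789,
                  fs = 250, lead = "V5", t0 = 120)
  write_signal(x, tmp, format = "native_csv")
  y <- read_signal(tmp, format = "native_csv")
  expect_equal(y$samples, x$samples, tolerance = 1e-9)
  expect_equal(y$fs, x$fs)
  expect_equal(y$t0, x$t0)
  expect_equal(y$lead, x$lead)
})

test_that("native binary signals round-trip at float32 precision", {
  tmp <- withr::local_tempfile(fileext = ".bin")
  x <- ecg_signal(rnorm(1000), fs = 150, t0 = 2.5)
  write_signal(x, tmp, format = "native_binary")
  y <- read_signal(tmp, format = "native_binary")
  expect_equal(y$samples, x$samples, tolerance = 1e-6)
  expect_equal(y$fs, x$fs, tolerance = 1e-6)
  expect_equal(y$t0, x$t0, tolerance = 1e-6)
})

test_that("signal reader reports I/O and format errors", {
  expect_error(read_signal(file.path(tempdir(), "nope.csv")), "not found")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# lead=II", "0.1"), tmp)   # fs missing
  expect_error(read_signal(tmp), "fs")
  writeLines(c("# fs=abc lead=II", "0.1"), tmp)
  expect_error(read_signal(tmp), "fs")
  writeLines(c("# fs=150 lead=II", "0.1", "zap"), tmp)
  expect_error(read_signal(tmp), "non-numeric")
})

test_that("WFDB format-16 records convert stored integers to mV via gain", {
  d <- withr::local_tempdir()
  # gain 200 adu/mV, baseline 0: stored 200 -> 1.0 mV
  writeLines(c("rec 1 360 4", "rec.dat 16 200 11 0"),
             file.path(d, "rec.hea"))
  con <- file(file.path(d, "rec.dat"), "wb")
  writeBin(c(200L, -100L, 0L, 400L), con, size = 2L, endian = "little")
  close(con)
  sig <- read_signal(file.path(d, "rec.hea"), format = "wfdb")
  expect_equal(sig$samples, c(1.0, -0.5, 0.0, 2.0))
  expect_equal(sig$fs, 360)

  # explicit baseline in parentheses: (adu - baseline) / gain
  writeLines(c("rec2 1 360 2", "rec2.dat 16 100(1024)/mV 11 1024"),
             file.path(d, "rec2.hea"))
  con <- file(file.path(d, "rec2.dat"), "wb")
  writeBin(c(1024L, 1124L), con, size = 2L, endian = "little")
  close(con)
  sig2 <- read_signal(file.path(d, "rec2.hea"), format = "wfdb")
  expect_equal(sig2$samples, c(0.0, 1.0))
})

test_that("WFDB format-212 packing decodes both channels", {
  # hand-packed 12-bit pairs: frames (ch1, ch2) = (100, 300), (-200, 50)
  pack212 <- function(s) {
    s <- ifelse(s < 0L, s + 4096L, s)
    n <- length(s) %/% 2L
    out <- raw(0)
    for (k in seq_len(n)) {
      s1 <- s[2L * k - 1L]; s2 <- s[2L * k]
      out <- c(out, as.raw(c(s1 %% 256L,
                             (s1 %/% 256L) + 16L * (s2 %/% 256L),
                             s2 %% 256L)))
    }
    out
  }
  d <- withr::local_tempdir()
  writeLines(c("r212 2 360 2",
               "r212.dat 212 200 11 0",
               "r212.dat 212 100 11 0"),
             file.path(d, "r212.hea"))
  writeBin(pack212(c(100L, 300L, -200L, 50L)), file.path(d, "r212.dat"))
  ch1 <- read_signal(file.path(d, "r212.hea"), format = "wfdb", channel = 1L)
  ch2 <- read_signal(file.path(d, "r212.hea"), format = "wfdb", channel = 2L)
  expect_equal(ch1$samples, c(100, -200) / 200)
  expect_equal(ch2$samples, c(300, 50) / 100)
})

test_that("annotations round-trip, including empty sets and events", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  empty <- annotation_set()
  write_annotations(empty, tmp, fs = 150, record = "e")
  back <- read_annotations(tmp)
  expect_equal(nrow(back$beats), 0L)
  expect_equal(nrow(back$events), 0L)

  ann <- annotation_set(
    beats = data.frame(index = c(100L, 250L, 400L, 550L, 700L, 850L),
                       label = c("NB", "APB", "VPB", "NB", "VPB", "NB"),
                       scored = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)),
    events = data.frame(kind = "BG", start_beat = 3L, end_beat = 6L))
  write_annotations(ann, tmp, fs = 150, record = "r1")
  back <- read_annotations(tmp)
  expect_equal(back$beats, ann$beats)
  expect_equal(back$events, ann$events)
  expect_equal(attr(back, "fs"), 150)
  expect_equal(attr(back, "record"), "r1")
})

test_that("annotation validation rejects bad input", {
  expect_error(annotation_set(
    beats = data.frame(index = c(10L, 10L), label = c("NB", "NB"))),
    "strictly increasing")
  expect_error(annotation_set(
    beats = data.frame(index = c(10L, 20L, 30L, 40L),
                       label = rep("NB", 4)),
    events = data.frame(kind = c("BG", "BG"), start_beat = c(1L, 2L),
                        end_beat = c(3L, 4L))),
    "overlapping")
  expect_error(annotation_set(
    beats = data.frame(index = 10L, label = "NB"),
    events = data.frame(kind = "TG", start_beat = 1L, end_beat = 5L)),
    "outside")
  expect_error(read_annotations(file.path(tempdir(), "nope.ann")),
               "not found")
})
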