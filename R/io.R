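#' Read an ECG signal from disk
#'
#' Supported dialects:
#' \describe{
#'   \item{`native_csv`}{one mV value per line, header line
#'     `# fs=<Hz> lead=<name> t0=<s>`.}
#'   \item{`native_binary`}{16-byte little-endian header (`"ECGB"`,
#'     float32 fs, float32 t0, int32 n) followed by float32 samples in mV.
#'     The lead label is not stored and defaults to `"I"`.}
#'   \item{`wfdb`}{a WFDB header (`.hea`) plus signal (`.dat`) pair as used
#'     by the MIT-BIH arrhythmia database; signal formats 16 (int16) and
#'     212 (packed 12-bit) are supported, and stored integers are converted
#'     to mV as `(adu - baseline) / gain`. Only one channel is extracted
#'     (`channel`, first by default).}
#' }
#'
#' @param path file path (for `wfdb`, the `.hea` file or record base name)
#' @param format one of `"native_csv"`, `"native_binary"`, `"wfdb"`
#' @param channel channel to extract for multi-signal WFDB records
#' @return an [ecg_signal()]
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, format = c("native_csv", "native_binary", "wfdb"),
                        channel = 1L) {
  format <- match.arg(format)
  switch(format,
         native_csv = read_signal_csv(path),
         native_binary = read_signal_bin(path),
         wfdb = read_signal_wfdb(path, channel = channel))
}

#' Write an ECG signal to disk
#'
#' @param signal an [ecg_signal()]
#' @param path output file path
#' @param format `"native_csv"` or `"native_binary"` (see [read_signal()])
#' @return `path`, invisibly
#' @export
write_signal <- function(signal, path,
                         format = c("native_csv", "native_binary")) {
  format <- match.arg(format)
  if (!inherits(signal, "ecg_signal")) stop("write_signal: not an ecg_signal")
  if (format == "native_csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g lead=%s t0=%.10g",
                       signal$fs, signal$lead, signal$t0), con)
    writeLines(formatC(signal$samples, format = "g", digits = 17), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("ECGB"), con)
    writeBin(as.numeric(signal$fs), con, size = 4L, endian = "little")
    writeBin(as.numeric(signal$t0), con, size = 4L, endian = "little")
    writeBin(length(signal$samples), con, size = 4L, endian = "little")
    writeBin(as.numeric(signal$samples), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("read_signal: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr)) stop("read_signal: malformed header: missing '# fs=...' line")
  h <- hdr[1L]
  get_field <- function(name, required = TRUE) {
    m <- regmatches(h, regexpr(paste0(name, "=[^ ]+"), h))
    if (!length(m)) {
      if (required) stop("read_signal: malformed header: missing field '",
                         name, "'")
      return(NA_character_)
    }
    sub(paste0(name, "="), "", m)
  }
  fs <- suppressWarnings(as.numeric(get_field("fs")))
  if (is.na(fs)) stop("read_signal: malformed header: field 'fs' not numeric")
  lead <- get_field("lead", required = FALSE)
  if (is.na(lead)) lead <- "I"
  t0 <- suppressWarnings(as.numeric(get_field("t0", required = FALSE)))
  if (is.na(t0)) t0 <- 0
  vals <- suppressWarnings(as.numeric(lines[!grepl("^#", lines) &
                                              nzchar(lines)]))
  if (any(is.na(vals))) stop("read_signal: non-numeric sample value")
  ecg_signal(vals, fs = fs, lead = lead, t0 = t0)
}

read_signal_bin <- function(path) {
  if (!file.exists(path)) stop("read_signal: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "ECGB"))
    stop("read_signal: malformed header: bad magic (field 'magic')")
  fs <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  t0 <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(n) || is.na(n) || n < 1L)
    stop("read_signal: malformed header: bad sample count (field 'n')")
  x <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(x) != n) stop("read_signal: truncated sample data")
  ecg_signal(x, fs = fs, t0 = t0)
}

read_signal_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("read_signal: file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rec <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(rec) < 3L)
    stop("read_signal: malformed header: record line needs ",
         "'name nsig fs' (field 'record')")
  nsig <- suppressWarnings(as.integer(rec[2L]))
  fs <- suppressWarnings(as.numeric(rec[3L]))
  if (is.na(nsig) || nsig < 1L)
    stop("read_signal: malformed header: field 'nsig' not a positive integer")
  if (is.na(fs) || fs <= 0)
    stop("read_signal: malformed header: field 'fs' not positive")
  nsamp <- if (length(rec) >= 4L) suppressWarnings(as.integer(rec[4L])) else NA
  if (channel < 1L || channel > nsig)
    stop("read_signal: channel ", channel, " not in record (nsig=", nsig, ")")
  sig_lines <- lines[2L:(1L + nsig)]
  specs <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "[ \t]+")[[1L]]
    if (length(f) < 3L)
      stop("read_signal: malformed header: signal line needs ",
           "'file format gain' (field 'signal')")
    fmt <- suppressWarnings(as.integer(sub("x[0-9]+$", "", f[2L])))
    gain_tok <- f[3L]
    baseline <- NA_real_
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_tok))
      gain_tok <- sub("\\(.*", "", gain_tok)
    }
    gain_tok <- sub("/.*", "", gain_tok)
    gain <- suppressWarnings(as.numeric(gain_tok))
    if (is.na(gain)) stop("read_signal: malformed header: field 'gain'")
    if (gain == 0) gain <- 200  # WFDB convention: 0 means default gain
    adczero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adczero)) 0 else adczero
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline)
  })
  sp <- specs[[channel]]
  if (!all(vapply(specs, function(s) identical(s$file, sp$file), logical(1L))))
    stop("read_signal: multi-file WFDB records are not supported")
  dat <- file.path(dirname(hea), sp$file)
  if (!file.exists(dat)) stop("read_signal: file not found: ", dat)
  raw <- readBin(dat, "raw", file.info(dat)$size)
  fmt <- sp$format
  if (fmt == 16L) {
    v <- readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    mat <- matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)
    adu <- mat[channel, ]
  } else if (fmt == 212L) {
    ntrip <- length(raw) %/% 3L
    b <- as.integer(raw[seq_len(ntrip * 3L)])
    b1 <- b[seq(1L, by = 3L, length.out = ntrip)]
    b2 <- b[seq(2L, by = 3L, length.out = ntrip)]
    b3 <- b[seq(3L, by = 3L, length.out = ntrip)]
    s1 <- b1 + bitwAnd(b2, 15L) * 256L          # low nibble of b2 = high bits
    s2 <- b3 + bitwAnd(b2 %/% 16L, 15L) * 256L  # high nibble of b2
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    mat <- matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)
    adu <- mat[channel, ]
  } else {
    stop("read_signal: unsupported WFDB signal format ", fmt)
  }
  if (!is.na(nsamp) && nsamp > 0L && nsamp <= length(adu))
    adu <- adu[seq_len(nsamp)]
  ecg_signal((adu - sp$baseline) / sp$gain, fs = fs,
             lead = paste0("ch", channel))
}

#' Write beat/event annotations to a CSV file
#'
#' One beat per line `beat,<sample_index>,<label>,<scored>`, one event per
#' line `event,<kind>,<start_beat>,<end_beat>`; a comment header records the
#' sampling frequency, record id and index base. The format is diff-able and
#' round-trips losslessly through [read_annotations()].
#'
#' @param ann an [annotation_set()]
#' @param path output file path
#' @param fs sampling frequency recorded in the header (Hz)
#' @param record record identifier recorded in the header
#' @return `path`, invisibly
#' @export
write_annotations <- function(ann, path, fs = NA, record = "unknown") {
  if (!inherits(ann, "ecg_annotations"))
    stop("write_annotations: not an ecg_annotations object")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# ecgflow-annotations v1",
               sprintf("# fs=%.10g record=%s index_base=1", fs, record)), con)
  if (nrow(ann$beats))
    writeLines(sprintf("beat,%d,%s,%d", ann$beats$index, ann$beats$label,
                       as.integer(ann$beats$scored)), con)
  if (nrow(ann$events))
    writeLines(sprintf("event,%s,%d,%d", ann$events$kind,
                       ann$events$start_beat, ann$events$end_beat), con)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path annotation CSV path
#' @return an [annotation_set()]; the header `fs` and `record` fields are
#'   attached as attributes
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("read_annotations: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  fs <- NA_real_
  record <- NA_character_
  for (h in hdr) {
    m <- regmatches(h, regexpr("fs=[^ ]+", h))
    if (length(m)) fs <- suppressWarnings(as.numeric(sub("fs=", "", m)))
    m <- regmatches(h, regexpr("record=[^ ]+", h))
    if (length(m)) record <- sub("record=", "", m)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  kind1 <- vapply(parts, `[`, character(1L), 1L)
  bad <- !kind1 %in% c("beat", "event")
  if (any(bad))
    stop("read_annotations: malformed line: ", body[which(bad)[1L]])
  bp <- parts[kind1 == "beat"]
  beats <- if (length(bp)) {
    data.frame(index = as.integer(vapply(bp, `[`, character(1L), 2L)),
               label = vapply(bp, `[`, character(1L), 3L),
               scored = vapply(bp, function(p)
                 if (length(p) >= 4L) p[4L] == "1" else TRUE, logical(1L)))
  } else NULL
  ep <- parts[kind1 == "event"]
  events <- if (length(ep)) {
    data.frame(kind = vapply(ep, `[`, character(1L), 2L),
               start_beat = as.integer(vapply(ep, `[`, character(1L), 3L)),
               end_beat = as.integer(vapply(ep, `[`, character(1L), 4L)))
  } else NULL
  ann <- annotation_set(beats, events)
  attr(ann, "fs") <- fs
  attr(ann, "record") <- record
  ann
}
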