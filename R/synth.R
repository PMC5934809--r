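#' Generator configuration
#'
#' Describes a synthetic single-lead recording: sampling frequency, duration,
#' base heart rate, a rhythm script (ordered `(kind, count)` instructions),
#' optional additive noise, and a seed. Beat timing rules:
#' \itemize{
#'   \item sinus (NB) intervals are the base cycle length with Gaussian
#'     jitter (`rr_jitter_ms`, applied only between consecutive plain sinus
#'     beats so ectopic timing is exact);
#'   \item an APB is narrow and premature (`apb_coupling` x base) with a
#'     non-compensatory pause (`apb_next` x base; coupling + pause < 2x);
#'   \item a VPB is wide and premature (`vpb_coupling` x base) with a full,
#'     slightly over-complete compensatory pause (`vpb_pause` x base;
#'     coupling + pause = 2.04x base by default, keeping the compensatory
#'     sum strictly above twice the running-average RR in the presence of
#'     sinus jitter);
#'   \item a `BG` instruction emits that many VPB--NB couplets, a `TG`
#'     instruction that many NB--NB--VPB triplets; run intervals are exact
#'     multiples of 20 ms (3 samples at 150 Hz), so their millisecond values
#'     are floating-point exact.
#' }
#'
#' @param fs sampling frequency (Hz)
#' @param duration_s record duration (s)
#' @param hr_bpm base sinus heart rate (beats/min)
#' @param rhythm_script data.frame with columns `kind`
#'   (`NB`/`APB`/`VPB`/`BG`/`TG`) and `count`
#' @param noise noise specification, see [inject_noise()] (NULL for clean)
#' @param seed RNG seed (record is byte-identical given the seed)
#' @param rr_jitter_ms sinus RR jitter standard deviation (ms)
#' @param apb_coupling,apb_next APB coupling interval and following
#'   interval, as fractions of the base cycle
#' @param vpb_coupling,vpb_pause VPB coupling interval and compensatory
#'   pause, as fractions of the base cycle
#' @param nb_quota number of scored NB instances taken from the final sinus
#'   padding block (NA scores every non-run NB)
#' @return a `generator_config` list
#' @export
generator_config <- function(fs = 150, duration_s = 300, hr_bpm = 60,
                             rhythm_script = data.frame(kind = "NB",
                                                        count = 300L),
                             noise = NULL, seed = 1L, rr_jitter_ms = 10,
                             apb_coupling = 0.6, apb_next = 1.1,
                             vpb_coupling = 0.6, vpb_pause = 1.44,
                             nb_quota = NA_integer_) {
  if (fs <= 0) stop("generator_config: fs must be > 0")
  if (hr_bpm <= 0) stop("generator_config: hr_bpm must be > 0")
  rhythm_script <- as.data.frame(rhythm_script)
  if (!all(rhythm_script$kind %in% c("NB", "APB", "VPB", "BG", "TG")))
    stop("generator_config: script kinds must be NB/APB/VPB/BG/TG")
  structure(list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                 rhythm_script = rhythm_script, noise = noise,
                 seed = as.integer(seed), rr_jitter_ms = rr_jitter_ms,
                 apb_coupling = apb_coupling, apb_next = apb_next,
                 vpb_coupling = vpb_coupling, vpb_pause = vpb_pause,
                 nb_quota = nb_quota),
            class = "generator_config")
}

# Gaussian-bump beat morphologies: amplitude (mV), center offset from R (ms),
# bump sd (ms). The narrow QRS spans 80 ms (Q center - 2 sd to S center +
# 2 sd), the wide ventricular QRS 160 ms.
morphology_nb <- function() rbind(
  P = c(amp = 0.15, mu = -180, sd = 25),
  Q = c(amp = -0.12, mu = -22, sd = 9),
  R = c(amp = 1.00, mu = 0, sd = 11),
  S = c(amp = -0.25, mu = 22, sd = 9),
  T = c(amp = 0.30, mu = 300, sd = 60))

morphology_apb <- function() {
  m <- morphology_nb()
  m["P", ] <- c(0.12, -140, 20)  # earlier, flatter ectopic P wave
  m
}

morphology_vpb <- function() rbind(
  R = c(amp = 1.80, mu = 0, sd = 32),
  S = c(amp = -0.50, mu = 58, sd = 19),
  T = c(amp = -0.35, mu = 320, sd = 70))

beat_morphology <- function(kind) {
  switch(kind, NB = morphology_nb(), APB = morphology_apb(),
         VPB = morphology_vpb(), stop("unknown beat kind ", kind))
}

# expand a rhythm script into per-beat kind / RR (samples) / run membership
expand_script <- function(cfg) {
  fs <- cfg$fs
  base <- as.integer(round(60 / cfg$hr_bpm * fs))
  r3 <- function(x) 3L * as.integer(round(x / 3))  # snap to 20 ms grid
  apb_c <- as.integer(round(cfg$apb_coupling * base))
  apb_n <- as.integer(round(cfg$apb_next * base))
  vpb_c <- r3(cfg$vpb_coupling * base)
  vpb_p <- r3(cfg$vpb_pause * base)
  sd_samp <- cfg$rr_jitter_ms * fs / 1000

  kind <- character(0)
  rr <- integer(0)       # interval to previous beat (samples); rr[1] unused
  run <- integer(0)      # 0 = none, else run id
  run_kind <- character(0)
  ev_start <- integer(0) # event instance start/end (beat ordinals)
  ev_end <- integer(0)
  ev_kind <- character(0)
  block <- integer(0)    # script-row id, for quota selection
  run_id <- 0L
  prev <- "start"        # start / NB / APB / VPB_iso / VPB_run

  push <- function(k, gap, rid) {
    kind <<- c(kind, k)
    rr <<- c(rr, gap)
    run <<- c(run, rid)
    block <<- c(block, srow)
  }
  sinus_gap <- function() {
    if (prev == "NB") {
      j <- as.integer(round(min(3 * sd_samp,
                                max(-3 * sd_samp, rnorm(1L, 0, sd_samp)))))
      base + j
    } else if (prev == "APB") apb_n
    else if (prev %in% c("VPB_iso", "VPB_run")) vpb_p
    else base
  }

  for (srow in seq_len(nrow(cfg$rhythm_script))) {
    k <- cfg$rhythm_script$kind[srow]
    cnt <- cfg$rhythm_script$count[srow]
    if (k == "NB") {
      for (i in seq_len(cnt)) {
        push("NB", sinus_gap(), 0L)
        prev <- "NB"
      }
    } else if (k == "APB") {
      for (i in seq_len(cnt)) {
        push("APB", apb_c, 0L)
        prev <- "APB"
      }
    } else if (k == "VPB") {
      for (i in seq_len(cnt)) {
        push("VPB", vpb_c, 0L)
        prev <- "VPB_iso"
      }
    } else if (k == "BG") {
      run_id <- run_id + 1L
      for (i in seq_len(cnt)) {
        push("VPB", if (prev == "VPB_run") vpb_p else vpb_c, run_id)
        # couplet entry: coupling from the preceding sinus beat
        prev <- "VPB_run"
        push("NB", vpb_p, run_id)
        n_beat <- length(kind)
        ev_kind <- c(ev_kind, "BG")
        ev_start <- c(ev_start, n_beat - 1L)
        ev_end <- c(ev_end, n_beat)
        prev <- "run_NB"  # run ends on the couplet NB; next sinus gap is base
      }
    } else if (k == "TG") {
      run_id <- run_id + 1L
      for (i in seq_len(cnt)) {
        push("NB", if (i == 1L) sinus_gap() else vpb_p, run_id)
        push("NB", base, run_id)
        push("VPB", vpb_c, run_id)
        n_beat <- length(kind)
        ev_kind <- c(ev_kind, "TG")
        ev_start <- c(ev_start, n_beat - 2L)
        ev_end <- c(ev_end, n_beat)
        prev <- "VPB_run"  # run ends on a VPB; next sinus sits on the pause
      }
    }
  }
  list(kind = kind, rr = rr, run = run, block = block,
       events = data.frame(kind = ev_kind, start_beat = ev_start,
                           end_beat = ev_end))
}

#' Generate an annotated synthetic ECG record
#'
#' Renders the configured rhythm script as a sum-of-Gaussians waveform
#' (P, Q, R, S, T bumps per beat) on a timing grid built from the rules in
#' [generator_config()], then applies the configured noise. Ground-truth
#' annotations carry the exact R construction sample of every beat, its
#' label, a `scored` flag, and one event instance per bigeminy couplet /
#' trigeminy triplet. Output is reproducible: the seed fixes the jitter and
#' noise realizations, and neither changes the beat or instance counts.
#'
#' @param config a [generator_config()]
#' @return list with elements `signal` ([ecg_signal()]) and `annotations`
#'   ([annotation_set()])
#' @export
generate_record <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("generate_record: config must be a generator_config")
  with_local_seed(config$seed, {
    fs <- config$fs
    n <- as.integer(round(config$duration_s * fs))
    sc <- expand_script(config)
    t_first <- as.integer(round(0.45 * fs))
    r_idx <- t_first + cumsum(c(0L, sc$rr[-1L]))
    tail_room <- as.integer(round(0.40 * fs))
    if (length(r_idx) && max(r_idx) > n - tail_room)
      stop("generate_record: rhythm script longer than the record duration")

    x <- numeric(n)
    for (b in seq_along(r_idx)) {
      m <- beat_morphology(sc$kind[b])
      for (ci in seq_len(nrow(m))) {
        mu <- r_idx[b] + m[ci, "mu"] * fs / 1000
        sdv <- m[ci, "sd"] * fs / 1000
        lo <- max(1L, as.integer(floor(mu - 5 * sdv)))
        hi <- min(n, as.integer(ceiling(mu + 5 * sdv)))
        if (lo > hi) next
        i <- lo:hi
        x[i] <- x[i] + m[ci, "amp"] * exp(-((i - mu)^2) / (2 * sdv^2))
      }
    }
    sig <- ecg_signal(x, fs = fs, lead = "synthetic")
    if (!is.null(config$noise)) sig <- inject_noise(sig, config$noise)

    scored <- sc$run == 0L & sc$kind %in% c("APB", "VPB")
    nb_plain <- which(sc$kind == "NB" & sc$run == 0L)
    if (is.na(config$nb_quota)) {
      scored[nb_plain] <- TRUE
    } else {
      # scored NB subset: fixed quota from the tail of the final sinus block
      last_block <- max(sc$block[nb_plain])
      pool <- nb_plain[sc$block[nb_plain] == last_block]
      if (length(pool) < config$nb_quota)
        stop("generate_record: final NB block smaller than nb_quota")
      scored[tail(pool, config$nb_quota)] <- TRUE
    }
    ann <- annotation_set(
      beats = data.frame(index = r_idx, label = sc$kind, scored = scored),
      events = sc$events)
    list(signal = sig, annotations = ann)
  })
}

#' Inject synthetic noise into a signal
#'
#' Additive 0.3 Hz baseline-wander and 50 Hz powerline sinusoids, uniform
#' random bursts over given spans, and zeroed flatline spans. A zero/empty
#' specification is the identity.
#'
#' @param signal an [ecg_signal()]
#' @param noise list with optional fields `baseline_mv`, `powerline_mv`
#'   (amplitudes, mV), `burst` (data.frame `start_s`, `dur_s`, `amp_mv`) and
#'   `flatline` (data.frame `start_s`, `dur_s`)
#' @return the contaminated [ecg_signal()]
#' @export
inject_noise <- function(signal, noise) {
  x <- signal$samples
  n <- length(x)
  fs <- signal$fs
  tt <- (seq_len(n) - 1L) / fs
  span_idx <- function(start_s, dur_s, what) {
    i1 <- as.integer(floor(start_s * fs)) + 1L
    i2 <- as.integer(ceiling((start_s + dur_s) * fs))
    if (i1 < 1L || i2 > n) stop("inject_noise: ", what, " outside record")
    i1:i2
  }
  burst_flags <- logical(n)
  flat_flags <- logical(n)
  bl <- if (is.null(noise$baseline_mv)) 0 else noise$baseline_mv
  pl <- if (is.null(noise$powerline_mv)) 0 else noise$powerline_mv
  if (bl != 0) x <- x + bl * sin(2 * pi * 0.3 * tt)
  if (pl != 0) x <- x + pl * sin(2 * pi * 50 * tt)
  if (!is.null(noise$burst) && nrow(noise$burst)) {
    for (k in seq_len(nrow(noise$burst))) {
      i <- span_idx(noise$burst$start_s[k], noise$burst$dur_s[k], "burst")
      a <- noise$burst$amp_mv[k]
      x[i] <- x[i] + runif(length(i), -a, a)
      burst_flags[i] <- TRUE
    }
  }
  if (!is.null(noise$flatline) && nrow(noise$flatline)) {
    for (k in seq_len(nrow(noise$flatline))) {
      i <- span_idx(noise$flatline$start_s[k], noise$flatline$dur_s[k],
                    "flatline")
      flat_flags[i] <- TRUE
      x[i] <- 0
    }
  }
  if (any(burst_flags & flat_flags))
    stop("inject_noise: overlapping flatline and burst spans")
  ecg_signal(x, fs = fs, lead = signal$lead, t0 = signal$t0)
}

# per-record rhythm script reproducing the bedside-simulator session layout
# at 60 beats/min in 5 min: a sinus warm-up, six isolated APBs and six
# isolated VPBs each followed by sinus recovery, one 15-couplet bigeminy
# run, one 10-triplet trigeminy run, and sinus padding. Each run is
# preceded by a sinus spacer spanning a full RR-averaging window so the
# running average has settled back to the sinus cycle length when the run
# starts (a stray post-extrasystolic pause inside the window would bias it).
paper_record_script <- function() {
  rows <- list(data.frame(kind = "NB", count = 10L))
  for (i in 1:6) rows <- c(rows, list(data.frame(kind = "APB", count = 1L),
                                      data.frame(kind = "NB", count = 7L)))
  for (i in 1:6) rows <- c(rows, list(data.frame(kind = "VPB", count = 1L),
                                      data.frame(kind = "NB", count = 7L)))
  rows <- c(rows, list(data.frame(kind = "NB", count = 24L),
                       data.frame(kind = "BG", count = 15L),
                       data.frame(kind = "NB", count = 24L),
                       data.frame(kind = "TG", count = 10L),
                       data.frame(kind = "NB", count = 84L)))
  do.call(rbind, rows)
}

#' Generate the 40-record evaluation fixture set
#'
#' Emulates a 40-recording bedside patient-simulator session: 40 clean
#' 5-minute records at 150 Hz and 60 beats/min whose summed ground-truth
#' instance counts are exactly 3120 scored NB beats, 240 APB beats, 240 VPB
#' beats, 600 bigeminy couplets and 400 trigeminy triplets (4600 scored
#' instances). Each record also contains unscored sinus padding and the
#' sinus-conducted beats inside runs; instance semantics: one BG instance is
#' one VPB--NB couplet, one TG instance one NB--NB--VPB triplet, and the
#' scored NB subset is a fixed per-record quota of 78 padding sinus beats.
#'
#' @param profile fixture profile (only `"paper_synthetic"`)
#' @param seed base seed; record `k` uses `seed + 1000 * k`. Seeds change
#'   only the sinus jitter realization, never the instance counts.
#' @return list of 40 `list(signal, annotations)` records
#' @export
generate_fixture_set <- function(profile = "paper_synthetic", seed = 1L) {
  profile <- match.arg(profile)
  lapply(seq_len(40L), function(k) {
    cfg <- generator_config(fs = 150, duration_s = 300, hr_bpm = 60,
                            rhythm_script = paper_record_script(),
                            seed = seed + 1000L * k, nb_quota = 78L)
    generate_record(cfg)
  })
}

#' Ground-truth instance counts of a record set
#'
#' @param records list of records from [generate_record()] /
#'   [generate_fixture_set()]
#' @return named integer vector with components NB, APB, VPB (scored beats)
#'   and BG, TG (event instances)
#' @export
fixture_counts <- function(records) {
  if (!is.null(records$annotations)) records <- list(records)
  counts <- c(NB = 0L, APB = 0L, VPB = 0L, BG = 0L, TG = 0L)
  for (rec in records) {
    b <- rec$annotations$beats
    e <- rec$annotations$events
    for (lab in c("NB", "APB", "VPB"))
      counts[lab] <- counts[lab] + sum(b$scored & b$label == lab)
    for (k in c("BG", "TG"))
      counts[k] <- counts[k] + sum(e$kind == k)
  }
  counts
}
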