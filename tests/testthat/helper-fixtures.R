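# short synthetic records used across tests (built in code, no stored data)

short_config <- function(script, duration_s = 60, seed = 42L, ...) {
  generator_config(fs = 150, duration_s = duration_s, hr_bpm = 60,
                   rhythm_script = script, seed = seed, ...)
}

all_nb_script <- function(n = 55L) data.frame(kind = "NB", count = n)

# a 60 s record with isolated ectopy: sinus, one APB, one VPB, sinus
mixed_script <- function() {
  rbind(data.frame(kind = "NB", count = 20L),
        data.frame(kind = "APB", count = 1L),
        data.frame(kind = "NB", count = 10L),
        data.frame(kind = "VPB", count = 1L),
        data.frame(kind = "NB", count = 20L))
}

run_record <- function(rec, ...) {
  run_pipeline(rec$signal, pipeline_config(...), truth = rec$annotations)
}

# filtered + enhanced helper
prep <- function(sig, backend = "vectorized") {
  filt <- bandpass_filter(sig)
  list(filt = filt,
       enh = morphological_transform(filt, backend = backend))
}

# run an expression while discarding stderr chatter (CLI usage messages)
capture_usage <- function(expr) {
  val <- NULL
  utils::capture.output(val <- expr, type = "message")
  val
}
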