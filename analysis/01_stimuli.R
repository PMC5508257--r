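#!/usr/bin/env Rscript
# Tone-pip stimulus ensemble: the 2 x 3 design (REG/RAND x alphabet size
# 5/10/15), 104 sequences per cell, drawn from a 20-step log-spaced pool
# between 222 and 2000 Hz. Writes per-sequence metadata, the set manifest,
# regularity-discovery latencies, and (optionally, WRITE_WAV=1) example
# 16-bit 44.1 kHz waveforms.
suppressMessages(library(gaintrack))

SEED <- as.integer(Sys.getenv("SEED", "1"))
out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pool <- build_frequency_pool(222, 2000, 20)
cat(sprintf("Frequency pool: %d steps, %.0f-%.0f Hz, ratio %.4f\n",
            pool$n_steps, pool$f_min, pool$f_max,
            pool$freqs_hz[2] / pool$freqs_hz[1]))

set <- generate_stimulus_set(104, seed = SEED)
meta <- set$meta
meta$alphabet <- vapply(set$sequences, function(s) paste(round(s$alphabet, 1), collapse = ";"), "")
meta$tones <- vapply(set$sequences, function(s) paste(round(s$tone_freqs, 1), collapse = ";"), "")
write.csv(meta, file.path(out, "sequences.csv"), row.names = FALSE)
cat(sprintf("Wrote %d sequences (%d per condition cell)\n",
            nrow(meta), set$n_per_condition))

lat <- do.call(rbind, lapply(c(5, 10, 15), function(r) {
  data.frame(r = r,
             one_cycle_ms = discovery_latency(r, "one_cycle"),
             cycle_plus_four_ms = discovery_latency(r, "cycle_plus_four"))
}))
write.csv(lat, file.path(out, "discovery_latencies.csv"), row.names = FALSE)
cat("Discovery latencies (ms):\n"); print(lat)

manifest <- list(seed = SEED, n_per_condition = set$n_per_condition,
                 n_sequences = nrow(meta),
                 pool = list(f_min = pool$f_min, f_max = pool$f_max,
                             n_steps = pool$n_steps),
                 isi_range_ms = set$inter_sequence_interval_range,
                 tone_ms = 50, ramp_ms = 5, duration_ms = 3000,
                 wav = list(bits = 16, rate = 44100))
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)

if (Sys.getenv("WRITE_WAV", "0") == "1") {
  for (cell in c("REG5", "RAND15")) {
    s <- set$sequences[[which(paste0(meta$condition, meta$r) == cell)[1]]]
    write_wav(render_waveform(s, 44100), file.path(out, paste0(cell, ".wav")))
  }
  cat("Example WAV files written\n")
}
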