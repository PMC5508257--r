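#' Log-spaced tone frequency pool
#'
#' The stimulus alphabet is drawn from a fixed pool of pip frequencies placed
#' in equal steps on a logarithmic scale (a geometric progression), endpoints
#' included.
#'
#' @param f_min lowest frequency (Hz), must be positive
#' @param f_max highest frequency (Hz), `> f_min`
#' @param n number of pool frequencies (>= 2)
#' @return an object of class `frequency_pool` with fields `freqs_hz`,
#'   `f_min`, `f_max`, `n_steps`
#' @export
#' @examples
#' pool <- build_frequency_pool(222, 2000, 20)
#' length(pool$freqs_hz)
build_frequency_pool <- function(f_min = 222, f_max = 2000, n = 20) {
  if (!is.numeric(f_min) || f_min <= 0 || !is.numeric(f_max) || f_max <= f_min) {
    stop("invalid-argument: need 0 < f_min < f_max")
  }
  if (n < 2) stop("invalid-argument: n must be >= 2")
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n))
  structure(list(freqs_hz = freqs, f_min = f_min, f_max = f_max, n_steps = as.integer(n)),
            class = "frequency_pool")
}

#' Generate one tone-pip sequence
#'
#' A sequence of 60 abutting 50 ms tone pips spanning 3000 ms. An alphabet of
#' `r` frequencies is drawn from the pool randomly with replacement
#' (duplicates retained). Under the REG condition the alphabet is tiled
#' periodically (cycle starting at tone 0); under RAND each tone is an
#' independent uniform draw over the alphabet slots. REG and RAND sequences
#' built with the same seed share the same alphabet (frequency matching).
#'
#' @param condition `"REG"` or `"RAND"`
#' @param r alphabet size; 5, 10 or 15 in the standard design (other values
#'   allowed with a warning)
#' @param pool a [build_frequency_pool()] object
#' @param seed integer seed; fixes both the alphabet draw and the RAND order
#' @param tone_duration pip duration in ms
#' @param total_duration sequence duration in ms
#' @param ramp raised-cosine gate duration in ms (kept as metadata here;
#'   applied by [render_waveform()])
#' @return an object of class `tone_pip_sequence`
#' @export
generate_sequence <- function(condition = c("REG", "RAND"), r, pool, seed,
                              tone_duration = 50, total_duration = 3000, ramp = 5) {
  condition <- match.arg(condition)
  stopifnot(inherits(pool, "frequency_pool"))
  n_tones <- as.integer(round(total_duration / tone_duration))
  if (r > n_tones) stop("invalid-argument: alphabet size exceeds the number of tones")
  if (!r %in% c(5L, 10L, 15L)) warning("alphabet size outside the standard design {5, 10, 15}")
  alphabet <- with_seed(derive_seed(seed, 0L),
                        sample(pool$freqs_hz, r, replace = TRUE))
  tone_freqs <- if (condition == "REG") {
    rep_len(alphabet, n_tones)
  } else {
    with_seed(derive_seed(seed, 1L),
              alphabet[sample.int(r, n_tones, replace = TRUE)])
  }
  structure(list(condition = condition, r = as.integer(r), alphabet = alphabet,
                 tone_freqs = tone_freqs, tone_duration = tone_duration,
                 ramp = ramp, total_duration = total_duration),
            class = "tone_pip_sequence")
}

#' Render a tone-pip sequence as an audio waveform
#'
#' Abutting sinusoidal pips, each gated on and off with raised-cosine ramps,
#' peak amplitude normalised to `level` full scale.
#'
#' @param seq a [generate_sequence()] object
#' @param sample_rate sampling rate in Hz; must be at least twice the highest
#'   pip frequency
#' @param level peak amplitude as a fraction of full scale
#' @return numeric vector of samples in `[-level, level]`
#' @export
render_waveform <- function(seq, sample_rate = 44100, level = 0.9) {
  stopifnot(inherits(seq, "tone_pip_sequence"))
  if (sample_rate < 2 * max(seq$tone_freqs)) {
    stop("invalid-argument: sample_rate below the Nyquist limit of the highest pip")
  }
  n_pip <- as.integer(round(sample_rate * seq$tone_duration / 1000))
  n_ramp <- as.integer(round(sample_rate * seq$ramp / 1000))
  t <- (seq_len(n_pip) - 1) / sample_rate
  gate <- rep(1, n_pip)
  if (n_ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    gate[seq_len(n_ramp)] <- up
    gate[n_pip - n_ramp + seq_len(n_ramp)] <- rev(up)
  }
  wave <- unlist(lapply(seq$tone_freqs, function(f) sin(2 * pi * f * t) * gate),
                 use.names = FALSE)
  wave * (level / max(abs(wave)))
}

#' Regularity-discovery latency
#'
#' Time from sequence onset by which a regular cycle can in principle be
#' detected: one full cycle of `r` pips (`one_cycle`), or the ideal-observer
#' bound of a cycle plus four further tones (`cycle_plus_four`).
#'
#' @param r alphabet size (cycle length), `>= 1`
#' @param rule `"one_cycle"` or `"cycle_plus_four"`
#' @param tone_duration pip duration in ms
#' @return latency in ms
#' @export
#' @examples
#' discovery_latency(15, "one_cycle")   # 750 ms
#' discovery_latency(5, "cycle_plus_four")
discovery_latency <- function(r, rule = c("one_cycle", "cycle_plus_four"),
                              tone_duration = 50) {
  rule <- match.arg(rule)
  stopifnot(r >= 1)
  switch(rule,
         one_cycle = r * tone_duration,
         cycle_plus_four = (r + 4) * tone_duration)
}

#' Generate a full stimulus set
#'
#' The 2 x 3 factorial design (REG/RAND by alphabet size 5/10/15) with
#' `n_per_condition` sequences per cell, a randomised presentation order, and
#' random inter-sequence intervals in `[700, 2000]` ms.
#'
#' @param n_per_condition sequences per condition cell
#' @param seed master seed; per-sequence sub-seeds are derived by counter
#' @param pool frequency pool (default: the standard 222-2000 Hz, 20-step pool)
#' @return an object of class `stimulus_set` with fields `sequences` (in
#'   presentation order), `meta` (one row per sequence), `n_per_condition`,
#'   `inter_sequence_interval_range`
#' @export
generate_stimulus_set <- function(n_per_condition = 104, seed = 1,
                                  pool = build_frequency_pool()) {
  stopifnot(n_per_condition >= 1)
  cells <- expand.grid(condition = c("REG", "RAND"), r = c(5L, 10L, 15L),
                       stringsAsFactors = FALSE)
  seqs <- list()
  meta <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(n_per_condition)) {
      k <- k + 1L
      # REG and RAND with the same (r, j) share a sub-seed, hence an alphabet
      sub <- derive_seed(seed, cells$r[i] * 100000L + j)
      seqs[[k]] <- generate_sequence(cells$condition[i], cells$r[i], pool, sub)
      meta[[k]] <- data.frame(idx = k, condition = cells$condition[i],
                              r = cells$r[i], seed = sub)
    }
  }
  meta <- do.call(rbind, meta)
  ord <- with_seed(derive_seed(seed, 999999L), sample.int(k))
  isi <- with_seed(derive_seed(seed, 999998L), stats::runif(k, 700, 2000))
  meta <- meta[ord, , drop = FALSE]
  meta$presentation <- seq_len(k)
  meta$isi_ms <- isi
  structure(list(sequences = seqs[ord], meta = meta,
                 n_per_condition = as.integer(n_per_condition),
                 inter_sequence_interval_range = c(700, 2000)),
            class = "stimulus_set")
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit little-endian PCM).
#'
#' @param wave numeric samples in `[-1, 1]`
#' @param path output file path
#' @param sample_rate sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(wave * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                  # block align
  writeBin(16L, con, size = 2, endian = "little")                 # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
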