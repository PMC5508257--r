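test_that("frequency pool is a geometric progression with the stated endpoints", {
  pool <- build_frequency_pool(222, 2000, 20)
  expect_length(pool$freqs_hz, 20)
  expect_equal(pool$freqs_hz[1], 222)
  expect_equal(pool$freqs_hz[20], 2000)
  ratios <- pool$freqs_hz[-1] / pool$freqs_hz[-20]
  expect_lt(max(ratios) - min(ratios), 1e-9)
  expect_equal(ratios[1], (2000 / 222)^(1 / 19), tolerance = 1e-12)
  expect_equal(round(ratios[1], 4), 1.1227)
  expect_error(build_frequency_pool(-1, 100, 5), "invalid-argument")
  expect_error(build_frequency_pool(100, 50, 5), "invalid-argument")
})

test_that("REG sequences tile the alphabet periodically from tone 0", {
  pool <- build_frequency_pool()
  for (r in c(5L, 10L, 15L)) {
    s <- generate_sequence("REG", r, pool, seed = 42 + r)
    expect_length(s$tone_freqs, 60)
    expect_length(s$alphabet, r)
    expect_true(all(s$tone_freqs %in% s$alphabet))
    expect_identical(s$tone_freqs[seq_len(60 - r)], s$tone_freqs[seq_len(60 - r) + r])
    expect_identical(s$tone_freqs[seq_len(r)], s$alphabet)
  }
})

test_that("RAND sequences stay within the alphabet but are almost never periodic", {
  pool <- build_frequency_pool()
  periodic <- 0L
  for (seed in 1:200) {
    s <- generate_sequence("RAND", 15, pool, seed = seed)
    expect_true(all(s$tone_freqs %in% s$alphabet))
    if (identical(s$tone_freqs[1:45], s$tone_freqs[16:60])) periodic <- periodic + 1L
  }
  expect_lte(periodic, 1L)
})

test_that("REG and RAND with the same seed share an alphabet; seeds reproduce exactly", {
  pool <- build_frequency_pool()
  a <- generate_sequence("REG", 10, pool, seed = 7)
  b <- generate_sequence("RAND", 10, pool, seed = 7)
  expect_identical(a$alphabet, b$alphabet)
  expect_identical(generate_sequence("RAND", 10, pool, seed = 7)$tone_freqs,
                   b$tone_freqs)
  expect_warning(generate_sequence("REG", 7, pool, seed = 1), "standard design")
  expect_error(generate_sequence("REG", 61, pool, seed = 1), "invalid-argument")
})

test_that("rendered waveforms have the right length, onset and per-pip spectra", {
  pool <- build_frequency_pool()
  s <- generate_sequence("REG", 5, pool, seed = 3)
  w <- render_waveform(s, 44100)
  expect_length(w, 132300)
  expect_equal(w[1], 0)
  expect_equal(max(abs(w)), 0.9, tolerance = 1e-9)
  # spectral peak of an isolated pip sits at that pip's frequency
  n_pip <- 2205
  pip <- w[(2 * n_pip + 1):(3 * n_pip)]
  spec <- Mod(stats::fft(pip))[1:(n_pip %/% 2)]
  f_peak <- (which.max(spec) - 1) * 44100 / n_pip
  expect_lt(abs(f_peak - s$tone_freqs[3]), 44100 / n_pip)
  expect_error(render_waveform(s, 1000), "invalid-argument")
})

test_that("discovery latency follows the one-cycle and cycle-plus-four rules", {
  expect_equal(discovery_latency(15, "one_cycle"), 750)
  expect_equal(discovery_latency(5, "one_cycle"), 250)
  expect_equal(discovery_latency(5, "cycle_plus_four"), 450)
  expect_equal(discovery_latency(10, "cycle_plus_four"), 700)
})

test_that("stimulus sets have balanced cells, full randomization and bounded intervals", {
  ss <- generate_stimulus_set(4, seed = 9)
  expect_length(ss$sequences, 24)
  tab <- table(ss$meta$condition, ss$meta$r)
  expect_true(all(tab == 4))
  expect_true(all(ss$meta$isi_ms >= 700 & ss$meta$isi_ms <= 2000))
  ss2 <- generate_stimulus_set(4, seed = 9)
  expect_identical(lapply(ss$sequences, `[[`, "tone_freqs"),
                   lapply(ss2$sequences, `[[`, "tone_freqs"))
  # frequency matching: REG and RAND cells with the same r share alphabets
  reg5 <- Filter(function(s) s$condition == "REG" && s$r == 5, ss$sequences)
  rnd5 <- Filter(function(s) s$condition == "RAND" && s$r == 5, ss$sequences)
  alpha_sort <- function(xs) lapply(xs, function(s) sort(s$alphabet))
  expect_setequal(vapply(alpha_sort(reg5), paste, "", collapse = ","),
                  vapply(alpha_sort(rnd5), paste, "", collapse = ","))
})

test_that("WAV files round-trip their PCM payload", {
  w <- sin(2 * pi * 440 * (0:999) / 44100) * 0.5
  f <- tempfile(fileext = ".wav")
  write_wav(w, f, 44100)
  con <- file(f, "rb")
  hdr <- readBin(con, "raw", 44)
  pcm <- readBin(con, "integer", 1000, size = 2, endian = "little")
  close(con)
  expect_identical(rawToChar(hdr[1:4]), "RIFF")
  expect_identical(rawToChar(hdr[9:12]), "WAVE")
  expect_equal(pcm, as.integer(round(w * 32767)))
})
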