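make_trials <- function(n_time, n_trials, f, fs, amp = 1, seed = 1) {
  set.seed(seed)
  t <- seq_len(n_time) / fs
  sapply(seq_len(n_trials), function(i) {
    amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(n_time, sd = 0.5)
  })
}

test_that("evoked subtraction zeroes the mean and identical trials entirely", {
  x <- matrix(rnorm(100), 100, 1)[, c(1, 1, 1)]
  expect_equal(subtract_evoked(x), matrix(0, 100, 3), ignore_attr = TRUE)
  y <- matrix(rnorm(500), 100, 5)
  expect_equal(rowMeans(subtract_evoked(y)), rep(0, 100))
  expect_warning(out <- subtract_evoked(y[, 1, drop = FALSE]), "single trial")
  expect_equal(out, y[, 1, drop = FALSE])
})

test_that("induced power at an evoked transient is reduced by evoked subtraction", {
  set.seed(11)
  fs <- 600; n <- fs * 2
  evoked <- c(rep(0, 500), sin(2 * pi * 30 * seq_len(200) / fs) * 3, rep(0, n - 700))
  trials <- make_trials(n, 20, 45, fs) + evoked
  p_with <- mean(tf_decompose(trials[, 1], fs, times = 1.0, freqs = 30)$power)
  induced <- subtract_evoked(trials)
  p_without <- mean(tf_decompose(induced[, 1], fs, times = 1.0, freqs = 30)$power)
  expect_lt(p_without, p_with)
})

test_that("tf decomposition shows a ridge at the driving frequency and scales quadratically", {
  fs <- 600
  t <- seq_len(fs * 3) / fs
  x <- sin(2 * pi * 40 * t)
  m <- tf_decompose(x, fs)
  ridge <- m$freqs[apply(m$power, 1, which.max)]
  expect_true(all(ridge == 40))
  m2 <- tf_decompose(3 * x, fs)
  expect_equal(m2$power, 9 * m$power, tolerance = 1e-9)
  expect_error(tf_decompose(x, fs, freqs = 400), "Nyquist")
  expect_error(tf_decompose(x[1:100], fs), "shorter")
})

test_that("white-noise expected power is flat across frequencies", {
  set.seed(12)
  fs <- 600
  acc <- 0
  for (i in 1:60) {
    acc <- acc + colMeans(tf_decompose(rnorm(fs * 2), fs)$power)
  }
  acc <- acc / 60
  expect_lt((max(acc) - min(acc)) / mean(acc), 0.35)
})

test_that("log rescaling is exact for known ratios and scale-invariant", {
  fs <- 600
  x <- c(rnorm(fs) * 1, rnorm(fs * 2) * sqrt(2))   # post power = 2x baseline
  m <- tf_decompose(x, fs, times = seq(0.3, 2.7, by = 0.05))
  r <- log_rescale(m, baseline = c(0.3, 0.7))
  r10 <- log_rescale({m10 <- m; m10$power <- m$power * 10; m10}, baseline = c(0.3, 0.7))
  expect_equal(r$power, r10$power, tolerance = 1e-9)
  # stationary portion rescales to ~0
  base_rows <- r$times <= 0.7
  expect_lt(max(abs(rowMeans(r$power[base_rows, , drop = FALSE]))), 0.8)
  expect_error(log_rescale(m, baseline = c(10, 11)), "invalid-argument")
})

test_that("robust averaging equals the mean for homogeneous trials and resists outliers", {
  set.seed(13)
  fs <- 600
  maps <- lapply(1:6, function(i) tf_decompose(rnorm(fs * 2), fs))
  # symmetric trial-to-trial variation: robust mean ~ arithmetic mean
  # (raw single-taper power is chi-squared skewed, where the two means
  # legitimately differ; symmetry is the right regime for this identity)
  sym <- lapply(1:8, function(i) {
    m <- maps[[1]]
    m$power <- 1 + matrix(rnorm(length(m$power), 0, 0.1), nrow(m$power))
    m
  })
  ra_sym <- robust_average(sym)
  am_sym <- Reduce(`+`, lapply(sym, `[[`, "power")) / 8
  # agreement to well within the trial noise SD (0.1); occasional bins clip
  # one tail draw, so the bulk deviation is the sharper statistic
  expect_lt(max(abs(ra_sym$power - am_sym)), 0.1)
  expect_lt(mean(abs(ra_sym$power - am_sym)), 0.01)
  hom <- lapply(1:4, function(i) maps[[1]])
  expect_equal(robust_average(hom)$power, maps[[1]]$power, tolerance = 1e-6)
  out <- maps
  out[[6]]$power <- out[[6]]$power * 100
  ra_out <- robust_average(out)
  clean <- Reduce(`+`, lapply(maps[1:5], `[[`, "power")) / 5
  naive <- Reduce(`+`, lapply(out, `[[`, "power")) / 6
  expect_lt(mean(abs(ra_out$power - clean)), mean(abs(naive - clean)))
  expect_equal(robust_average(out[c(2, 1, 3, 4, 5, 6)])$power, ra_out$power)
})

test_that("factorial contrasts vanish on identical cells and detect an injected interaction", {
  set.seed(14)
  fs <- 600
  cells <- c("REG5", "REG10", "REG15", "RAND5", "RAND10", "RAND15")
  base_map <- function(gamma_amp, seed) {
    set.seed(seed)
    t <- seq_len(fs * 3) / fs
    x <- rnorm(fs * 3) + gamma_amp * sin(2 * pi * 80 * t)
    tf_decompose(x, fs)
  }
  # identical cells: all contrasts zero
  subj <- stats::setNames(lapply(1:6, function(i) base_map(0, 99)), cells)
  fc0 <- factorial_contrasts(list(subj, subj))
  expect_equal(max(abs(fc0$regularity$mean)), 0)
  expect_equal(max(abs(fc0$interaction$mean)), 0)
  # gamma increase only in REG5 drives a positive interaction at 80 Hz
  subjects <- lapply(1:4, function(s) {
    maps <- stats::setNames(lapply(seq_along(cells), function(i) {
      base_map(if (cells[i] == "REG5") 1.5 else 0, s * 10 + i)
    }), cells)
    maps
  })
  fc <- factorial_contrasts(subjects)
  k80 <- which(fc$freqs == 80)
  expect_gt(mean(fc$interaction$mean[, k80]), 0)
  expect_gt(mean(fc$interaction$t[, k80]), 2)
  # swapping REG/RAND labels negates the regularity contrast
  swapped <- lapply(subjects, function(s) {
    stats::setNames(s[c("RAND5", "RAND10", "RAND15", "REG5", "REG10", "REG15")], cells)
  })
  fcs <- factorial_contrasts(swapped)
  expect_equal(fcs$regularity$mean, -fc$regularity$mean, tolerance = 1e-9)
  expect_error(factorial_contrasts(list(subj[-1])), "invalid-argument")
})

test_that("time-averaged contrasts equal contrasts of time averages (linearity)", {
  set.seed(15)
  fs <- 600
  cells <- c("REG5", "REG10", "REG15", "RAND5", "RAND10", "RAND15")
  subj <- stats::setNames(lapply(1:6, function(i) tf_decompose(rnorm(fs * 3), fs)), cells)
  fc <- factorial_contrasts(list(subj), time_window = c(0.75, 3))
  sel <- subj[[1]]$times >= 0.75 & subj[[1]]$times <= 3
  avg_then_contrast <- (colMeans(subj$REG5$power[sel, ]) + colMeans(subj$REG10$power[sel, ]) +
                          colMeans(subj$REG15$power[sel, ]) - colMeans(subj$RAND5$power[sel, ]) -
                          colMeans(subj$RAND10$power[sel, ]) - colMeans(subj$RAND15$power[sel, ])) / 3
  expect_equal(colMeans(fc$regularity$mean), avg_then_contrast, tolerance = 1e-10)
})
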