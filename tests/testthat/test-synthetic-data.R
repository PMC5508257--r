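test_that("default scenarios encode the stated timing and design structure", {
  sc <- build_default_scenario(seed = 3)
  expect_equal(nrow(sc$conditions), 6)
  expect_equal(sort(sc$conditions$reg), c(0, 0, 0, 1, 1, 1))
  expect_equal(sc$n_trials, 104)
  t <- seq(0, 3000, by = 10)
  peak_of <- function(nm) t[which.max(abs(sc$schedules[[nm]](t)))]
  # AC gain schedules peak later than IFG's, per factor
  expect_gt(peak_of("B_reg_Gsp_AC"), peak_of("B_reg_Gsp_IFG"))
  expect_gt(peak_of("B_alp_Gsp_AC"), peak_of("B_alp_Gsp_IFG"))
  expect_equal(peak_of("B_reg_Gsp_IFG"), 1050)
  expect_equal(peak_of("B_alp_Gsp_IFG"), 1550)
  # schedules are zero before stimulus onset
  for (f in sc$schedules) expect_equal(f(c(-500, -1)), c(0, 0))
  # identical seeds give identical scenarios
  sc2 <- build_default_scenario(seed = 3)
  expect_identical(scenario_trajectories(sc), scenario_trajectories(sc2))
})

test_that("truth tables round-trip losslessly through JSON", {
  sc <- build_default_scenario(seed = 7, n_trials = 4)
  truth <- list(network = sc$network,
                trajectories = scenario_trajectories(sc),
                window_centers = window_grid()$centers,
                mixture = sc$mixture,
                coding = list(regularity = c(0.5, -0.5)),
                conditions = sc$conditions, n_trials = 4L,
                rms_noise_sd = sc$rms_noise_sd, seed = 7L)
  f <- tempfile(fileext = ".json")
  write_truth(truth, f)
  back <- read_truth(f)
  expect_equal(back$network, truth$network)
  expect_equal(unname(back$trajectories), unname(truth$trajectories))
  expect_equal(back$mixture, truth$mixture)
  expect_equal(back$rms_noise_sd, truth$rms_noise_sd)
})

test_that("generated datasets are reproducible and carry the declared shapes", {
  sc <- build_default_scenario(seed = 9, n_trials = 3)
  g <- window_grid(500, 250, 300, 0, 1000)
  ds <- tryCatch(generate_dataset(sc, grid = g), error = function(e) e)
  expect_false(inherits(ds, "error"))
  expect_length(ds$ts, 6)
  expect_equal(dim(ds$ts$REG5$y)[1], 2)
  expect_equal(dim(ds$ts$REG5$y)[3], 3)
  expect_length(ds$features, g$n_windows)
  expect_length(ds$features[[1]], 6)
  expect_length(ds$rms, 6)
  expect_equal(length(ds$rms$REG5), 1800)
  ds2 <- generate_dataset(sc, grid = g)
  expect_identical(ds$ts$RAND10$y, ds2$ts$RAND10$y)
  expect_identical(ds$rms$REG15, ds2$rms$REG15)
})

test_that("regular small-alphabet sequences induce more AC gamma power than random ones", {
  sc <- build_default_scenario(seed = 13, n_trials = 14)
  ds <- generate_dataset(sc, windowed = FALSE)
  band <- ds$whole_csd$REG5$freqs >= 60
  g_reg <- sum(Re(ds$whole_csd$REG5$csd[1, 1, band]))
  g_rand <- sum(Re(ds$whole_csd$RAND5$csd[1, 1, band]))
  expect_gt(g_reg, g_rand)
})

test_that("with no scheduled modulation the conditions are statistically exchangeable", {
  sc <- build_default_scenario(seed = 17, n_trials = 20, sets = character(0))
  ds <- generate_dataset(sc, windowed = FALSE)
  # per-trial AC band power, REG5 vs RAND5: no detectable difference
  bp <- function(cell) {
    y <- ds$ts[[cell]]$y
    apply(y[1, , ], 2, stats::var)
  }
  p <- stats::wilcox.test(bp("REG5"), bp("RAND5"))$p.value
  expect_gt(p, 0.01)
})

test_that("sensor RMS contrasts recover the constructed mixture signals", {
  sc <- build_default_scenario(seed = 19, n_trials = 2)
  ds <- generate_dataset(sc, windowed = FALSE)
  eff <- effect_timecourses(ds$rms, fs = ds$fs)
  # rebuild the noiseless mixture target for the regularity contrast
  truth_traj <- scenario_trajectories(sc)
  X <- prepare_predictors(truth_traj, window_grid()$centers,
                          out_times = seq(0, 3000 - 1000 / ds$fs, by = 1000 / ds$fs),
                          target_rate = ds$fs, standardize = FALSE)
  Xs <- scale(X)
  w <- sc$mixture$regularity
  target <- drop(Xs[, names(w), drop = FALSE] %*% w)
  mid <- 300:1500
  expect_gt(cor(eff$regularity$values[mid], target[mid]), 0.9)
})
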