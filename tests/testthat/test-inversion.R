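test_that("gaussian densities validate their invariants and KL is zero on identity", {
  q <- gaussian_density(c(a = 1, b = -1), diag(c(0.5, 2)))
  expect_equal(gd_kl(q, q), 0, tolerance = 1e-10)
  expect_error(gaussian_density(c(1, 2), diag(2)), "unique names")
  expect_error(gaussian_density(c(a = 1, b = 2), matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  sub <- gd_subset(q, "b")
  expect_equal(sub$mean, c(b = -1))
  expect_equal(drop(sub$cov), 2)
})

test_that("model space holds the five stated modulation patterns", {
  space <- enumerate_model_space()
  expect_length(space, 5)
  sets <- lapply(space, `[[`, "modulated_sets")
  expect_equal(sum(vapply(sets, function(s) "extrinsic" %in% s, logical(1))), 3)
  expect_equal(sum(vapply(sets, function(s) "SP_gain" %in% s, logical(1))), 2)
  expect_equal(sum(vapply(sets, function(s) "II_gain" %in% s, logical(1))), 2)
  keys <- vapply(sets, paste, "", collapse = "+")
  expect_equal(anyDuplicated(keys), 0L)
  expect_length(model_b_params(space[[5]]), 8)
  expect_length(model_b_params(space[[2]]), 4)
})

test_that("free energy has zero complexity at the prior and penalizes worse fits", {
  net <- cmc_network()
  S <- expected_welch_csd(net)
  prior <- dcm_priors(c("G_sp_AC", "in_amp"))
  f_prior <- csd_free_energy(prior, prior, list(S))
  expect_true(is.finite(f_prior))
  # a sharp posterior at the generating values, at fixed precision, beats
  # the same posterior displaced from them (lost accuracy + complexity),
  # and doubling the displacement (hence the residuals) drops F further
  q0 <- gaussian_density(prior$mean, diag(1e-6, 2))
  f0 <- csd_free_energy(q0, prior, list(S))
  lam <- attr(f0, "lambda")
  q_off <- gaussian_density(prior$mean + c(0.2, 0), diag(1e-6, 2))
  f_off <- csd_free_energy(q_off, prior, list(S), lambda = lam)
  expect_lt(as.numeric(f_off), as.numeric(f0))
  q_off2 <- gaussian_density(prior$mean + c(0.4, 0), diag(1e-6, 2))
  f_off2 <- csd_free_energy(q_off2, prior, list(S), lambda = lam)
  expect_lt(as.numeric(f_off2), as.numeric(f_off))
})

test_that("noiseless self-generated data are recovered with an ascending free energy", {
  truth <- cmc_default_params()
  truth["G_sp_AC"] <- -1.2
  truth["in_amp"] <- 0.2
  S <- expected_welch_csd(cmc_network(truth))
  prior <- dcm_priors(c("G_sp_AC", "in_amp", "obs_AC"))
  res <- invert_csd(list(S), prior)
  expect_true(res$converged)
  expect_true(all(diff(res$free_energy_trace) >= 0))
  for (nm in prior$parameter_names) {
    sd_nm <- sqrt(diag(res$posterior$cov))[nm]
    expect_lt(abs(res$posterior$mean[nm] - truth[nm]), 2 * sd_nm + 1e-3)
  }
})

test_that("an essentially infinitely precise prior pins the posterior", {
  net <- cmc_network()
  S <- predict_csd(net)
  prior <- gaussian_density(c(G_sp_AC = -1.39, in_amp = 0), diag(c(1e-10, 1e-10)))
  res <- invert_csd(list(S), prior, maxit = 8)
  expect_lt(max(abs(res$posterior$mean - prior$mean)), 1e-4)
})

test_that("model reduction is exact on conjugate linear-Gaussian problems", {
  set.seed(8)
  d <- 5; n <- 40
  A <- matrix(rnorm(n * d), n, d)
  beta <- c(1, -0.5, 0, 0.3, 0)
  yv <- drop(A %*% beta) + rnorm(n, sd = 0.5)
  Piy <- diag(n) / 0.25
  nm <- paste0("p", 1:d)
  conj <- function(m0, S0) {
    P <- solve(S0) + t(A) %*% Piy %*% A
    S <- solve(P)
    m <- drop(S %*% (solve(S0) %*% m0 + t(A) %*% Piy %*% yv))
    logev <- -0.5 * (drop(t(yv) %*% Piy %*% yv) + drop(t(m0) %*% solve(S0) %*% m0) -
                       drop(t(m) %*% P %*% m)) -
      0.5 * (determinant(S0)$modulus + n * log(0.25)) +
      0.5 * determinant(S)$modulus - n / 2 * log(2 * pi)
    list(m = m, S = S, logev = drop(logev))
  }
  mu0 <- stats::setNames(rep(0, d), nm)
  S0 <- diag(0.5, d)
  full <- conj(mu0, S0)
  fp <- gaussian_density(mu0, S0)
  fq <- gaussian_density(stats::setNames(full$m, nm), full$S)

  # identity reduction: nothing changes
  same <- bayesian_model_reduction(fp, fq, fp)
  expect_equal(same$delta_f, 0, tolerance = 1e-9)
  expect_equal(same$posterior$mean, fq$mean, tolerance = 1e-9)

  # pinning reductions match direct conjugate inversion
  for (pin in list(1L, c(3L, 5L))) {
    S0r <- S0; diag(S0r)[pin] <- 1e-8
    red <- conj(mu0, S0r)
    bmr <- bayesian_model_reduction(fp, fq, gaussian_density(mu0, S0r))
    expect_lt(abs(bmr$delta_f - (red$logev - full$logev)), 1e-6)
    expect_lt(max(abs(bmr$posterior$mean - red$m)), 1e-6)
    expect_lt(max(abs(bmr$posterior$cov - red$S)), 1e-6)
  }

  # a hard pin holds the posterior at the pinned value
  S0p <- S0; S0p[2, 2] <- 1e-12
  pinned <- bayesian_model_reduction(fp, fq, gaussian_density(mu0, S0p))
  expect_lt(abs(pinned$posterior$mean[2]), 1e-5)
})

test_that("model averaging moment-matches Gaussian mixtures", {
  g1 <- gaussian_density(c(a = 1), matrix(1))
  g2 <- gaussian_density(c(a = -1), matrix(1))
  eq <- bayesian_model_average(list(g1, g2), c(3, 3))
  expect_equal(unname(eq$mean), 0)
  expect_equal(drop(eq$cov), 2)
  one <- bayesian_model_average(list(g1), 0)
  expect_equal(one$mean, g1$mean)
  same <- bayesian_model_average(list(g1, g1), c(0, -5))
  expect_equal(same$mean, g1$mean)
  expect_equal(same$cov, g1$cov)
  # dominant evidence collapses onto the winning model
  dom <- bayesian_model_average(list(g1, g2), c(100, 0))
  expect_equal(unname(dom$mean), 1, tolerance = 1e-6)
})

test_that("reduced priors pin exactly the modulators outside the model", {
  full <- dcm_priors()
  m2 <- enumerate_model_space()[[2]]   # II gain only
  rp <- reduced_prior_for(full, m2)
  free_b <- model_b_params(m2)
  pinned <- setdiff(grep("^B_", rp$parameter_names, value = TRUE), free_b)
  expect_true(all(diag(rp$cov)[pinned] == 1e-8))
  expect_true(all(diag(rp$cov)[free_b] == 1 / 8))
  expect_true(all(rp$mean[pinned] == 0))
})
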