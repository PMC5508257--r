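#' Sliding-window grid
#'
#' @param width window width (ms)
#' @param step window step (ms)
#' @param smoothing_fwhm full width at half maximum (ms) of the Gaussian
#'   kernel applied across window index to the spectral features
#' @param t_start,t_end data extent (ms)
#' @return object of class `window_grid` with window `starts`, `centers`
#'   (ms) and counts
#' @export
window_grid <- function(width = 500, step = 100, smoothing_fwhm = 300,
                        t_start = 0, t_end = 3000) {
  stopifnot(width > 0, step > 0, t_end - t_start >= width)
  starts <- seq(t_start, t_end - width, by = step)
  structure(list(width = width, step = step, smoothing_fwhm = smoothing_fwhm,
                 starts = starts, centers = starts + width / 2,
                 n_windows = length(starts)),
            class = "window_grid")
}

#' Windowed cross-spectral features
#'
#' One CSD per window per condition from trial data, with Gaussian temporal
#' smoothing (FWHM `grid$smoothing_fwhm`) applied across the window index to
#' every spectral entry. Smoothing is a convex combination of Hermitian PSD
#' matrices, so the invariant is preserved.
#'
#' @param ts list (one element per condition) of channels x time x trials
#'   arrays, time starting at `t_start` of the grid
#' @param grid a [window_grid()]
#' @param fs sampling rate (Hz)
#' @param freqs frequency grid (Hz)
#' @return list over windows, each a list over conditions of [csd_object()]s
#' @export
windowed_features <- function(ts, grid, fs = 600, freqs = seq(8, 128, by = 2)) {
  stopifnot(inherits(grid, "window_grid"))
  n_w <- grid$n_windows
  wlen <- as.integer(round(grid$width / 1000 * fs))
  raw <- vector("list", n_w)
  for (w in seq_len(n_w)) {
    i0 <- as.integer(round((grid$starts[w] - grid$starts[1]) / 1000 * fs)) + 1L
    if (i0 + wlen - 1L > dim(ts[[1]])[2]) stop("invalid-argument: window beyond data extent")
    raw[[w]] <- lapply(ts, function(y) {
      estimate_csd(y[, i0:(i0 + wlen - 1L), , drop = FALSE], fs = fs,
                   window = grid$width / 1000, step = grid$width / 1000,
                   freqs = freqs)
    })
  }
  sd_w <- fwhm_to_sd(grid$smoothing_fwhm) / grid$step
  if (sd_w <= 1e-9) return(raw)
  half <- max(1L, ceiling(4 * sd_w))
  out <- vector("list", n_w)
  for (w in seq_len(n_w)) {
    lo <- max(1L, w - half); hi <- min(n_w, w + half)
    kw <- stats::dnorm(lo:hi - w, sd = sd_w)
    kw <- kw / sum(kw)
    out[[w]] <- lapply(seq_along(ts), function(cc) {
      acc <- raw[[lo]][[cc]]$csd * kw[1]
      if (hi > lo) for (j in 2:length(kw)) {
        acc <- acc + raw[[lo + j - 1L]][[cc]]$csd * kw[j]
      }
      csd_object(freqs, acc, raw[[1]][[cc]]$channel_labels)
    })
  }
  out
}

#' Sliding-window Bayesian belief updating
#'
#' For each window j the previous window's posterior becomes the prior, with
#' a constant covariance inflation `sigma_const / j` added to keep the scheme
#' adaptive (windows are indexed from 1, so the first window is inflated by
#' the full `sigma_const`). Parameters outside the model's modulated sets are
#' held constant at their whole-window estimates.
#'
#' @param features output of [windowed_features()]
#' @param design data.frame (`reg`, `alp`), one row per condition
#' @param init_prior [gaussian_density()] over the model's modulator
#'   parameters (typically the whole-window model average restricted to them)
#' @param model a `model_spec`; its modulators must match `init_prior`
#' @param sigma_const covariance-inflation matrix (or vector of diagonal
#'   entries); default: diagonal at 1/8 of the modulators' model prior
#'   variances (so `1/64` with the default priors), which keeps the chain
#'   adaptive even when the whole-window posterior is sharp
#' @param fixed full parameter vector of constants (whole-window estimates)
#' @param constants base constants
#' @param baseline_free names of window-wise baseline nuisance parameters
#'   estimated alongside the modulators (pathway-common extrinsic scalings
#'   and observation gains); they absorb condition-independent drifts of the
#'   windowed spectral features so that condition contrasts are not forced
#'   onto the modulators. Set to `character(0)` to disable.
#' @param ... passed to [invert_csd()]
#' @return a `posterior_trajectory`: per-window posteriors and free energies
#' @export
update_sequence <- function(features, design, init_prior, model,
                            sigma_const = NULL,
                            fixed = cmc_default_params(),
                            constants = cmc_constants(),
                            baseline_free = c("A_asc", "A_desc", "obs_AC", "obs_IFG"),
                            ...) {
  b_names <- model_b_params(model)
  stopifnot(all(b_names %in% init_prior$parameter_names))
  init_prior <- gd_subset(init_prior, b_names)
  baseline_free <- setdiff(baseline_free, b_names)
  if (length(baseline_free)) {
    base_mu <- fixed[baseline_free]
    base_var <- diag(dcm_priors(cmc_param_names())$cov)[baseline_free]
    mu <- c(init_prior$mean, base_mu)
    S <- diag(c(rep(0, length(b_names)), base_var), length(mu))
    S[seq_along(b_names), seq_along(b_names)] <- init_prior$cov
    init_prior <- gaussian_density(mu, S)
  }
  free_names <- init_prior$parameter_names
  if (is.null(sigma_const)) {
    sigma_const <- diag(diag(dcm_priors(cmc_param_names())$cov)[free_names] / 8,
                        length(free_names))
  }
  if (is.null(dim(sigma_const))) sigma_const <- diag(rep_len(sigma_const, length(free_names)),
                                                     length(free_names))
  posteriors <- vector("list", length(features))
  fes <- rep(NA_real_, length(features))
  prior_j <- init_prior
  n_done <- 0L
  failure <- NULL
  for (j in seq_along(features)) {
    prior_j <- gaussian_density(prior_j$mean, prior_j$cov + sigma_const / j)
    res <- tryCatch(
      invert_csd(features[[j]], prior_j, design, fixed = fixed,
                 constants = constants, ...),
      error = function(err) err)
    if (inherits(res, "error")) {
      failure <- list(window = j, message = conditionMessage(res))
      break
    }
    posteriors[[j]] <- res$posterior
    fes[j] <- res$free_energy
    prior_j <- res$posterior
    n_done <- j
  }
  structure(list(posteriors = posteriors[seq_len(n_done)],
                 free_energies = fes[seq_len(n_done)],
                 sigma_const = sigma_const, model = model,
                 parameter_names = free_names, modulators = b_names,
                 failure = failure),
            class = "posterior_trajectory")
}

#' Extract modulatory predictor trajectories
#'
#' The eight predictors (2 experimental factors x 4 modulatory parameters:
#' SP gain in AC and IFG, ascending and descending extrinsic pathways) as
#' per-window posterior means with 95% credible intervals.
#'
#' @param traj a `posterior_trajectory` from [update_sequence()]
#' @param centers optional window centers (ms) to attach as times
#' @return list with `mean`, `sd`, `lower`, `upper` (windows x 8 matrices)
#'   and `times`
#' @export
extract_trajectories <- function(traj, centers = NULL) {
  stopifnot(inherits(traj, "posterior_trajectory"))
  nm <- traj$modulators %||% traj$parameter_names
  expected <- model_b_params(c("extrinsic", "SP_gain"))
  if (!all(expected %in% nm)) {
    stop("invalid-argument: trajectory model does not carry the 4 modulatory parameters per factor")
  }
  nm <- expected
  n_w <- length(traj$posteriors)
  m <- t(vapply(traj$posteriors, function(p) p$mean[nm], numeric(length(nm))))
  s <- t(vapply(traj$posteriors, function(p) sqrt(diag(p$cov)[nm]), numeric(length(nm))))
  colnames(m) <- colnames(s) <- nm
  list(mean = m, sd = s,
       lower = m - 1.959964 * s, upper = m + 1.959964 * s,
       times = centers %||% seq_len(n_w))
}
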