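#' Across-channel root-mean-square time course
#'
#' @param sensor_data channels x time matrix
#' @return numeric vector: per time point, the RMS over channels
#' @export
rms_timecourse <- function(sensor_data) {
  if (is.null(dim(sensor_data))) sensor_data <- matrix(sensor_data, nrow = 1)
  sqrt(colMeans(sensor_data^2))
}

#' Sensor-level effect time courses
#'
#' Zero-phase low-pass filtering of the six per-condition RMS series followed
#' by the three design contrasts: regularity (mean REG - mean RAND), linear
#' alphabet-size trend (pooled over regularity), and the interaction
#' (REG5 - REG15) - (RAND5 - RAND15).
#'
#' @param rms named list of six numeric series (`REG5`, `REG10`, `REG15`,
#'   `RAND5`, `RAND10`, `RAND15`), equal length, sampled at `fs`
#' @param fs sampling rate (Hz)
#' @param lowpass_hz low-pass corner (Hz)
#' @return list of three `effect_timecourse` objects (fields `times`,
#'   `values`, `contrast_id`)
#' @export
effect_timecourses <- function(rms, fs = 600, lowpass_hz = 8) {
  cells <- c("REG5", "REG10", "REG15", "RAND5", "RAND10", "RAND15")
  if (!all(cells %in% names(rms))) stop("invalid-argument: missing condition")
  bf <- signal::butter(4, lowpass_hz / (fs / 2))
  lp <- lapply(rms[cells], function(x) as.numeric(signal::filtfilt(bf, x)))
  weights <- list(
    regularity  = c(1, 1, 1, -1, -1, -1) / 3,
    alphabet    = c(-1, 0, 1, -1, 0, 1) / 2,
    interaction = c(1, 0, -1, -1, 0, 1)
  )
  times <- seq_along(lp[[1]]) / fs
  lapply(names(weights), function(nm) {
    v <- Reduce(`+`, Map(`*`, lp, weights[[nm]]))
    structure(list(times = times, values = v, contrast_id = nm, fs = fs),
              class = "effect_timecourse")
  }) |> stats::setNames(names(weights))
}

#' Prepare the model-based predictor matrix
#'
#' Nearest-neighbour upsampling of the eight modulator trajectories from the
#' window grid to the sensor sampling rate, Gaussian smoothing (SD
#' `smooth_sd` ms), and column standardization for the elastic-net penalty.
#'
#' @param trajectories windows x 8 matrix of modulator means (columns named),
#'   or the output of [extract_trajectories()]
#' @param window_times window centres (ms)
#' @param out_times output times (ms) at the target rate
#' @param target_rate output sampling rate (Hz)
#' @param smooth_sd Gaussian kernel SD (ms)
#' @param standardize centre and scale columns to unit variance
#' @return matrix (length(out_times) x 8) with attribute `"scaling"`
#' @export
prepare_predictors <- function(trajectories, window_times = NULL,
                               out_times = NULL, target_rate = 600,
                               smooth_sd = 150, standardize = TRUE) {
  if (is.list(trajectories) && !is.null(trajectories$mean)) {
    if (is.null(window_times)) window_times <- trajectories$times
    trajectories <- trajectories$mean
  }
  stopifnot(is.matrix(trajectories), ncol(trajectories) == 8)
  if (is.null(window_times)) stop("invalid-argument: window_times required")
  if (is.null(out_times)) {
    out_times <- seq(min(window_times), max(window_times), by = 1000 / target_rate)
  }
  idx <- vapply(out_times, function(t) which.min(abs(window_times - t)), integer(1))
  X <- trajectories[idx, , drop = FALSE]
  sd_samp <- smooth_sd / 1000 * target_rate
  X <- apply(X, 2, gauss_smooth, sd = sd_samp)
  colnames(X) <- colnames(trajectories)
  scaling <- list(center = colMeans(X), scale = apply(X, 2, stats::sd))
  if (standardize) {
    keep <- scaling$scale > 1e-12
    if (!all(keep)) warning("zero-variance predictor column(s) dropped: ",
                            paste(colnames(X)[!keep], collapse = ", "))
    X <- scale(X[, keep, drop = FALSE])
  }
  attr(X, "scaling") <- scaling
  attr(X, "times") <- out_times
  X
}

#' Elastic-net linking of predictors to sensor-level effects
#'
#' Multi-response elastic net (mixing parameter `alpha_mix`) over a
#' regularization path with cross-validation on contiguous time blocks
#' (respecting autocorrelation). Reports the minimum-MSE and one-standard-
#' error models, per-response coefficients, the predictor entry order along
#' the path, and the percentage of MSE explained.
#'
#' @param X predictor matrix (time x predictors), e.g. [prepare_predictors()]
#' @param Y response matrix (time x responses) or list of
#'   `effect_timecourse`s; responses are centred, not scaled
#' @param alpha_mix elastic-net mixing parameter
#' @param nfolds cross-validation folds (contiguous blocks)
#' @return list: `alpha`, `lambda_min`, `lambda_1se`, `pct_mse_explained`
#'   (at the minimum-MSE model), `pct_mse_explained_1se`, `coef_min`,
#'   `coef_1se` (predictors x responses), `support_min`, `support_1se`,
#'   `entry_order`, `cvfit`
#' @export
elastic_net_link <- function(X, Y, alpha_mix = 0.95, nfolds = 10) {
  if (is.list(Y) && !is.matrix(Y)) {
    Y <- vapply(Y, function(e) e$values, numeric(length(Y[[1]]$values)))
  }
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  keep <- apply(X, 2, stats::sd) > 1e-12
  if (!all(keep)) {
    warning("zero-variance predictor column(s) dropped: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (all(abs(Yc) < 1e-14)) {
    p <- ncol(X); r <- ncol(Y)
    zero <- matrix(0, p, r, dimnames = list(colnames(X), colnames(Y)))
    return(list(alpha = alpha_mix, lambda_min = Inf, lambda_1se = Inf,
                pct_mse_explained = 0, pct_mse_explained_1se = 0,
                coef_min = zero, coef_1se = zero,
                support_min = character(0), support_1se = character(0),
                entry_order = character(0), cvfit = NULL))
  }
  foldid <- as.integer(cut(seq_len(nrow(X)), breaks = nfolds, labels = FALSE))
  cv <- glmnet::cv.glmnet(X, Yc, family = "mgaussian", alpha = alpha_mix,
                          foldid = foldid, standardize = FALSE)
  fit <- cv$glmnet.fit
  coef_at <- function(s) {
    cf <- glmnet::coef.glmnet(fit, s = s)
    out <- vapply(cf, function(ci) as.numeric(ci)[-1], numeric(ncol(X)))
    rownames(out) <- colnames(X)
    colnames(out) <- colnames(Y) %||% paste0("resp", seq_len(ncol(Y)))
    out
  }
  dev_at <- function(s) {
    k <- which.min(abs(fit$lambda - s))
    100 * fit$dev.ratio[k]
  }
  beta_path <- Reduce(`+`, lapply(fit$beta, function(b) abs(as.matrix(b))))
  first_idx <- apply(beta_path > 0, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  entry <- names(sort(first_idx[!is.na(first_idx)]))
  cmin <- coef_at(cv$lambda.min)
  c1se <- coef_at(cv$lambda.1se)
  list(alpha = alpha_mix,
       lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       pct_mse_explained = dev_at(cv$lambda.min),
       pct_mse_explained_1se = dev_at(cv$lambda.1se),
       coef_min = cmin, coef_1se = c1se,
       support_min = rownames(cmin)[rowSums(abs(cmin)) > 0],
       support_1se = rownames(c1se)[rowSums(abs(c1se)) > 0],
       entry_order = entry, cvfit = cv)
}
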