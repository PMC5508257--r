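#' Gaussian density over named log-parameters
#'
#' Priors and posteriors share this shape: a mean vector with unique names and
#' a symmetric positive-semidefinite covariance aligned with it.
#'
#' @param mean named numeric vector
#' @param cov covariance matrix, or a vector of variances (diagonal)
#' @return object of class `gaussian_density`
#' @export
gaussian_density <- function(mean, cov) {
  if (is.null(names(mean)) || anyDuplicated(names(mean))) {
    stop("invalid-argument: mean must have unique names")
  }
  d <- length(mean)
  if (is.null(dim(cov))) {
    stopifnot(length(cov) %in% c(1L, d))
    cov <- diag(rep_len(cov, d), d)
  }
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(sum(abs(ev)), 1)) {
    stop("invalid-argument: covariance is not positive semidefinite")
  }
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = cov, parameter_names = names(mean)),
            class = "gaussian_density")
}

#' Restrict a Gaussian density to a subset of parameters
#' @param q a [gaussian_density()]
#' @param keep character vector of parameter names to keep
#' @return marginal `gaussian_density`
#' @export
gd_subset <- function(q, keep) {
  stopifnot(all(keep %in% q$parameter_names))
  gaussian_density(q$mean[keep], q$cov[keep, keep, drop = FALSE])
}

# log-determinant via eigenvalues with a floor for numerically zero modes
logdet_psd <- function(S, floor = 1e-14) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(log(pmax(ev, floor * max(ev, floor))))
}

# precision (pseudo-)inverse of a PSD matrix
prec_of <- function(S, floor = 1e-14) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor * max(e$values, floor))
  e$vectors %*% (t(e$vectors) / v)
}

#' Kullback-Leibler divergence between two Gaussian densities
#' @param q,p [gaussian_density()] objects on the same parameter space
#' @return KL(q || p) in nats
#' @export
gd_kl <- function(q, p) {
  stopifnot(identical(q$parameter_names, p$parameter_names))
  d <- length(q$mean)
  Pp <- prec_of(p$cov)
  dm <- q$mean - p$mean
  0.5 * (sum(diag(Pp %*% q$cov)) + drop(t(dm) %*% Pp %*% dm) - d +
           logdet_psd(p$cov) - logdet_psd(q$cov))
}
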