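#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' A counter-based scheme so that any single sequence, trial or replicate is
#' reproducible in isolation: the sub-seed depends only on the master seed and
#' the counter, never on how many draws preceded it.
#'
#' @param seed master seed (integer)
#' @param counter non-negative integer identifying the stream
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter), counter >= 0)
  # splitmix-style integer hash, kept in double arithmetic below 2^31
  x <- (as.double(seed) %% 2147483647) * 2654435.0 + as.double(counter) * 40503.0 + 12345.0
  x <- x %% 2147483647
  y <- (x * 48271.0) %% 2147483647
  as.integer(floor(y))
}

#' Evaluate a function with a temporary RNG seed
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian smoothing of a series along its index
#'
#' Kernel smoothing with reflection at the edges; used for smoothing windowed
#' spectral features across window index and parameter trajectories over time.
#'
#' @param x numeric vector (or matrix smoothed column-wise)
#' @param sd kernel standard deviation in index units; `sd <= 0` returns `x`
#' @return smoothed object of the same shape
#' @export
gauss_smooth <- function(x, sd) {
  if (is.matrix(x)) return(apply(x, 2, gauss_smooth, sd = sd))
  n <- length(x)
  if (sd <= 0 || n < 2) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  # reflect the series at both ends so the kernel never runs off the data
  xp <- c(rev(x[seq_len(min(half, n))]), x, rev(x[seq.int(n - min(half, n) + 1L, n)]))
  pad <- min(half, n)
  out <- stats::filter(xp, k, sides = 2)
  out <- as.numeric(out)[pad + seq_len(n)]
  # filter() leaves NA where the kernel exceeded even the padded ends
  if (anyNA(out)) {
    idx <- which(is.na(out))
    for (i in idx) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- stats::dnorm(seq(lo, hi) - i, sd = sd)
      out[i] <- sum(w * x[lo:hi]) / sum(w)
    }
  }
  out
}

#' Convert a full width at half maximum to a Gaussian standard deviation
#' @param fwhm full width at half maximum
#' @return standard deviation of the equivalent Gaussian kernel
#' @export
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
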