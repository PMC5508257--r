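#' Subtract the average evoked response from each trial
#'
#' @param trials time x trials matrix (aligned)
#' @return induced trials, same shape; the across-trial mean of the output is
#'   the zero vector
#' @export
subtract_evoked <- function(trials) {
  stopifnot(is.matrix(trials))
  if (ncol(trials) < 2) {
    warning("single trial: evoked subtraction skipped")
    return(trials)
  }
  trials - rowMeans(trials)
}

#' Hanning-tapered time-frequency decomposition
#'
#' Sliding-window Fourier power of one trial: a fixed-length Hanning-tapered
#' window centred on each time point of the output grid, power read at the
#' FFT bins nearest the frequency grid. Window positions are clipped at the
#' data edges.
#'
#' @param x numeric time series (one trial, one channel)
#' @param fs sampling rate (Hz)
#' @param times output time centres (s, relative to the start of `x`)
#' @param freqs frequency grid (Hz), default 8-128 Hz in 2 Hz steps
#' @param window window length (s)
#' @return object of class `tf_map`: `times` (s), `freqs`, `power`
#'   (times x freqs)
#' @export
tf_decompose <- function(x, fs, times = NULL, freqs = seq(8, 128, by = 2),
                         window = 0.5) {
  n <- length(x)
  wlen <- as.integer(round(window * fs))
  if (wlen > n) stop("invalid-argument: trial shorter than the analysis window")
  if (max(freqs) > fs / 2) stop("invalid-argument: frequency grid exceeds Nyquist")
  if (is.null(times)) times <- seq(window / 2, n / fs - window / 2, by = 0.05)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  U <- sum(h^2)
  fbins <- (seq_len(wlen) - 1) * fs / wlen
  kidx <- vapply(freqs, function(f) which.min(abs(fbins - f)), integer(1))
  P <- matrix(0, length(times), length(freqs))
  for (i in seq_along(times)) {
    c0 <- as.integer(round(times[i] * fs))
    i0 <- min(max(1L, c0 - wlen %/% 2L), n - wlen + 1L)
    seg <- x[i0:(i0 + wlen - 1L)]
    X <- stats::fft((seg - mean(seg)) * h)
    P[i, ] <- (2 / (fs * U)) * Mod(X[kidx])^2
  }
  structure(list(times = times, freqs = freqs, power = P,
                 n_trials_effective = 1), class = "tf_map")
}

#' Log-baseline rescaling of a time-frequency map
#'
#' Per frequency: `log(power) - log(mean baseline power)`. Invariant to
#' global amplitude scaling.
#'
#' @param map a `tf_map` (raw power)
#' @param baseline two-element vector (s) delimiting the baseline interval,
#'   which must lie within the map's time extent
#' @return `tf_map` with log-rescaled values
#' @export
log_rescale <- function(map, baseline) {
  stopifnot(inherits(map, "tf_map"), length(baseline) == 2)
  sel <- map$times >= baseline[1] & map$times <= baseline[2]
  if (!any(sel)) stop("invalid-argument: baseline outside map extent")
  base <- colMeans(map$power[sel, , drop = FALSE])
  if (any(base <= 0)) stop("zero baseline power")
  map$power <- log(map$power) - rep(log(base), each = nrow(map$power))
  map
}

#' Robust (iteratively reweighted) average of time-frequency maps
#'
#' Bisquare weights on residuals standardized per time-frequency bin,
#' iterated until the weights change by less than `tol` or `maxit` rounds,
#' down-weighting trials with outlying power.
#'
#' @param maps list of `tf_map`s on identical grids
#' @param k bisquare tuning constant (in robust-SD units)
#' @param maxit maximum reweighting iterations
#' @param tol convergence threshold on the maximum weight change
#' @return `tf_map` holding the robust average; `n_trials_effective` is the
#'   average total weight per bin
#' @export
robust_average <- function(maps, k = 4.685, maxit = 8, tol = 1e-4) {
  stopifnot(length(maps) >= 2)
  A <- vapply(maps, function(m) m$power, maps[[1]]$power)  # time x freq x trial
  n <- dim(A)[3]
  W <- array(1, dim(A))
  mu <- apply(A, c(1, 2), mean)
  for (it in seq_len(maxit)) {
    R <- sweep(A, c(1, 2), mu)
    s <- apply(abs(R), c(1, 2), stats::median) / 0.6745
    s[s < 1e-12] <- 1e-12
    U <- sweep(R, c(1, 2), s, "/") / k
    Wn <- (1 - U^2)^2
    Wn[abs(U) >= 1] <- 0
    delta <- max(abs(Wn - W))
    W <- Wn
    sw <- apply(W, c(1, 2), sum)
    sw[sw < 1e-12] <- 1e-12
    mu <- apply(W * A, c(1, 2), sum) / sw
    if (delta < tol) break
  }
  out <- maps[[1]]
  out$power <- mu
  out$n_trials_effective <- mean(apply(W, c(1, 2), sum))
  out
}

#' Factorial contrasts of condition time-frequency maps
#'
#' Within-subject 2 x 3 design (regularity by alphabet size). Returns the
#' main effect of regularity (REG - RAND), the linear alphabet-size trend
#' (pooled over regularity), and the interaction
#' (REG5 - REG15) - (RAND5 - RAND15), per subject and as across-subject
#' t-statistic maps.
#'
#' @param cond_maps list over subjects; each element a named list of six
#'   `tf_map`s (`REG5`, `REG10`, `REG15`, `RAND5`, `RAND10`, `RAND15`)
#' @param time_window analysis window (s) to which the returned summary t
#'   maps are restricted; `NULL` keeps the full extent
#' @return list with per-contrast lists: `maps` (per subject), `mean`, `t`
#'   (across subjects), plus `times`, `freqs`
#' @export
factorial_contrasts <- function(cond_maps, time_window = c(0.75, 3)) {
  cells <- c("REG5", "REG10", "REG15", "RAND5", "RAND10", "RAND15")
  for (s in cond_maps) {
    if (!all(cells %in% names(s))) stop("invalid-argument: missing condition cell")
  }
  tmpl <- cond_maps[[1]][["REG5"]]
  sel <- if (is.null(time_window)) rep(TRUE, length(tmpl$times)) else
    tmpl$times >= time_window[1] & tmpl$times <= time_window[2]
  contrast_of <- function(s, w) {
    Reduce(`+`, Map(function(cell, wi) wi * s[[cell]]$power, cells, w))
  }
  weights <- list(
    regularity  = c(1, 1, 1, -1, -1, -1) / 3,
    alphabet    = c(-1, 0, 1, -1, 0, 1) / 2,
    interaction = c(1, 0, -1, -1, 0, 1)
  )
  out <- lapply(weights, function(w) {
    per <- lapply(cond_maps, contrast_of, w = w)
    A <- vapply(per, function(m) m[sel, , drop = FALSE],
                per[[1]][sel, , drop = FALSE])
    n <- dim(A)[3]
    mu <- apply(A, c(1, 2), mean)
    if (n > 1) {
      se <- apply(A, c(1, 2), stats::sd) / sqrt(n)
      tmap <- mu / pmax(se, 1e-12)
    } else tmap <- mu * NA
    list(maps = per, mean = mu, t = tmap)
  })
  c(out, list(times = tmpl$times[sel], freqs = tmpl$freqs))
}
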