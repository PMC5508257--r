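#' Cross-spectral density container
#'
#' @param freqs frequency grid (Hz)
#' @param csd complex array, channels x channels x frequency; each slice is
#'   hermitized on construction
#' @param channel_labels channel names
#' @return object of class `csd`
#' @export
csd_object <- function(freqs, csd, channel_labels = dimnames(csd)[[1]]) {
  stopifnot(length(dim(csd)) == 3, dim(csd)[1] == dim(csd)[2],
            dim(csd)[3] == length(freqs))
  for (k in seq_along(freqs)) {
    csd[, , k] <- (csd[, , k] + Conj(t(csd[, , k]))) / 2
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(csd)[1]))
  structure(list(freqs = freqs, csd = csd, channel_labels = channel_labels),
            class = "csd")
}

#' Check the Hermitian positive-semidefinite invariant of a CSD
#' @param x a `csd` object
#' @param tol eigenvalue tolerance relative to the trace
#' @return TRUE invisibly; errors otherwise
#' @export
validate_csd <- function(x, tol = 1e-10) {
  stopifnot(inherits(x, "csd"))
  for (k in seq_along(x$freqs)) {
    S <- x$csd[, , k]
    if (max(Mod(S - Conj(t(S)))) > tol * max(1, Mod(sum(diag(S))))) {
      stop("csd slice not Hermitian at ", x$freqs[k], " Hz")
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(1, sum(abs(ev)))) {
      stop("csd slice not PSD at ", x$freqs[k], " Hz")
    }
  }
  invisible(TRUE)
}

#' Endogenous input (innovation) spectrum
#'
#' Power-law plus white-floor spectral density of the stochastic drive
#' entering the spiny stellate populations:
#' `S_u(f) = amplitude^2 * (f^-exponent + white_floor)`.
#'
#' @param amplitude drive amplitude (per input channel; scalar recycled)
#' @param exponent power-law slope
#' @param white_floor flat component relative to amplitude^2
#' @return object of class `innovation_spectrum` (callable density via
#'   [innovation_density()])
#' @export
innovation_spectrum <- function(amplitude = 1, exponent = 1, white_floor = 0.25) {
  stopifnot(amplitude > 0, white_floor >= 0)
  structure(list(amplitude = rep_len(amplitude, 2), exponent = exponent,
                 white_floor = white_floor),
            class = "innovation_spectrum")
}

#' Evaluate an innovation spectrum on a frequency grid
#' @param inn an [innovation_spectrum()]
#' @param freqs frequencies (Hz); clamped below 1 Hz to keep the density finite
#' @return matrix (2 input channels x frequency) of spectral densities
#' @export
innovation_density <- function(inn, freqs) {
  f <- pmax(freqs, 1)
  outer(inn$amplitude^2, f^(-inn$exponent) + inn$white_floor)
}

#' Innovation spectrum implied by a network's input parameters
#' @param net a `cmc_network`
#' @return an [innovation_spectrum()]
#' @export
net_innovations <- function(net) {
  cst <- net$constants
  ratio <- cst$input_amp_ratio %||% c(1, 1)
  innovation_spectrum(amplitude = cst$input_amp_base * exp(net$params[["in_amp"]]) * ratio,
                      exponent = cst$input_exponent_base + net$params[["in_exp"]],
                      white_floor = cst$input_white_floor)
}

#' Channel-noise spectral density of a network's observation model
#' @param net a `cmc_network`
#' @param freqs frequencies (Hz)
#' @return matrix (2 channels x frequency), white plus 1/f components
#' @export
channel_noise_density <- function(net, freqs) {
  cst <- net$constants
  w <- cst$noise_white_base * exp(net$params[["noise_white"]])
  p <- cst$noise_pink_base * exp(net$params[["noise_pink"]])
  f <- pmax(freqs, 1)
  matrix(rep(w + p / f, each = 2), nrow = 2)
}

#' Linearize a network around its fixed point
#'
#' Returns the state-space model used by the spectral forward prediction:
#' the analytic Jacobian at the fixed point, the input map (endogenous drive
#' enters the SS current equations scaled by the SS rate constant), and the
#' output map (per-source observed channel reads the SP membrane potential
#' through a log observation gain).
#'
#' @param net a `cmc_network`
#' @param u constant drive for the fixed point (default zero)
#' @return object of class `state_space_model` with `jacobian`, `input_map`,
#'   `output_map`, `x0`, `stable` (all eigenvalue real parts negative)
#' @export
linearize <- function(net, u = c(0, 0)) {
  x0 <- fixed_point(net, u)
  J <- state_jacobian(net, x0)
  si <- state_index(net)
  kap <- net$constants$kappa_hz
  L <- matrix(0, 16, 2)
  L[si$I[1], 1] <- kap[["SS"]]
  L[si$I[5], 2] <- kap[["SS"]]
  C <- matrix(0, 2, 16)
  C[1, si$V[2]] <- exp(net$params[["obs_AC"]])
  C[2, si$V[6]] <- exp(net$params[["obs_IFG"]])
  ev <- eigen(J, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  if (!stable) warning("linearized network is unstable (non-negative eigenvalue)")
  structure(list(jacobian = J, input_map = L, output_map = C, x0 = x0,
                 eigenvalues = ev, stable = stable),
            class = "state_space_model")
}

#' Analytic cross-spectral density prediction
#'
#' For each frequency the transfer function
#' `T(w) = C (i w Id - J)^-1 L` maps the innovation spectrum to the observed
#' cross-spectral density, to which the channel-noise spectrum is added:
#' `S(w) = T diag(S_u) T* + diag(N)`. Hermitian and positive semidefinite by
#' construction.
#'
#' @param net a `cmc_network`
#' @param innovations an [innovation_spectrum()]; defaults to the network's own
#' @param freqs frequency grid in Hz (default 8-128 Hz in 2 Hz steps)
#' @param ssm optional precomputed [linearize()] result
#' @param channel_noise logical; include the channel-noise spectrum
#' @return a [csd_object()]
#' @export
predict_csd <- function(net, innovations = net_innovations(net),
                        freqs = seq(8, 128, by = 2), ssm = NULL,
                        channel_noise = TRUE) {
  if (is.null(ssm)) ssm <- linearize(net)
  Su <- innovation_density(innovations, freqs)
  Nf <- if (channel_noise) channel_noise_density(net, freqs) else matrix(0, 2, length(freqs))
  J <- ssm$jacobian
  L <- ssm$input_map
  C <- ssm$output_map
  Id <- diag(nrow(J))
  out <- array(0i, dim = c(2, 2, length(freqs)))
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k]
    Tk <- C %*% solve(1i * w * Id - J, L)
    S <- Tk %*% (Su[, k] * Conj(t(Tk)))
    S <- S + diag(Nf[, k])
    out[, , k] <- S
  }
  dimnames(out) <- list(c("AC", "IFG"), c("AC", "IFG"), NULL)
  csd_object(freqs, out, c("AC", "IFG"))
}

# FFT-shaped Gaussian noise with one-sided PSD S(f); returns n samples at fs.
# Used for both the endogenous drive and the observation channel noise.
shaped_noise <- function(n, fs, density_fn) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  H <- sqrt(density_fn(pmax(f, fs / n)) * fs / 2)
  Re(stats::fft(W * H, inverse = TRUE)) / n
}

#' Stochastic simulation of the network dynamics
#'
#' Heun (trapezoidal predictor-corrector) integration of the nonlinear
#' dynamics driven by colored noise shaped to the innovation spectrum.
#' Observed channels are read through the output map, decimated to `fs_out`
#' after zero-phase anti-alias filtering, and overlaid with channel noise.
#' Serves as the independent oracle for [predict_csd()].
#'
#' @param net a `cmc_network`
#' @param innovations an [innovation_spectrum()]
#' @param duration simulated time (s)
#' @param dt integration step (s); checked against the fastest eigenvalue
#' @param seed integer seed
#' @param n_trials number of independent trials simulated jointly
#' @param fs_out output sampling rate (Hz); must divide `1/dt`
#' @param channel_noise logical; add observation noise
#' @param x0 initial state (default: fixed point)
#' @return list with `y` (channels x time x trials), `fs`, `times`
#' @export
simulate_timeseries <- function(net, innovations = net_innovations(net),
                                duration = 3, dt = 1 / 2400, seed = 1,
                                n_trials = 1, fs_out = 600,
                                channel_noise = TRUE, x0 = NULL) {
  ssm <- linearize(net)
  lam_max <- max(abs(ssm$eigenvalues))
  if (dt * lam_max > 1) stop("invalid-argument: dt too large for stable integration")
  fs_in <- round(1 / dt)
  dec <- fs_in / fs_out
  if (abs(dec - round(dec)) > 1e-9) stop("invalid-argument: fs_out must divide 1/dt")
  dec <- as.integer(round(dec))
  n_steps <- as.integer(round(duration * fs_in))
  M <- coupling_matrix(net)
  si <- state_index(net)
  kapv <- rep(net$constants$kappa_hz, 2)
  if (is.null(x0)) x0 <- fixed_point(net)
  x <- matrix(x0, nrow = 16, ncol = n_trials)

  inn_fun <- function(f) innovation_density(innovations, f)[1, ]
  u <- array(0, dim = c(2, n_steps + 1, n_trials))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      for (s in 1:2) {
        amp_s <- innovations$amplitude[s] / innovations$amplitude[1]
        u[s, , tr] <- amp_s * shaped_noise(n_steps + 1, fs_in, inn_fun)
      }
    }
  })

  y_full <- array(0, dim = c(2, n_steps, n_trials))
  C <- ssm$output_map
  for (t in seq_len(n_steps)) {
    ut <- matrix(u[, t, ], nrow = 2)
    ut1 <- matrix(u[, t + 1, ], nrow = 2)
    f1 <- state_derivative(x, net, ut, M)
    xp <- x + dt * f1
    f2 <- state_derivative(xp, net, ut1, M)
    x <- x + dt * (f1 + f2) / 2
    if (!all(is.finite(x)) || max(abs(x)) > 1e6) {
      stop("numerical-failure: state divergence during simulation")
    }
    y_full[, t, ] <- C %*% x
  }

  # zero-phase anti-alias filtering, then decimation to fs_out
  if (dec > 1L) {
    bf <- signal::butter(6, 0.8 / dec)
    n_out <- floor(n_steps / dec)
    y <- array(0, dim = c(2, n_out, n_trials))
    for (tr in seq_len(n_trials)) {
      for (ch in 1:2) {
        yf <- signal::filtfilt(bf, y_full[ch, , tr])
        y[ch, , tr] <- yf[seq.int(dec, n_steps, by = dec)][seq_len(n_out)]
      }
    }
  } else {
    y <- y_full
  }
  if (channel_noise) {
    noise_fun <- function(f) channel_noise_density(net, f)[1, ]
    with_seed(derive_seed(seed, 7L), {
      for (tr in seq_len(n_trials)) {
        for (ch in 1:2) {
          y[ch, , tr] <- y[ch, , tr] + shaped_noise(dim(y)[2], fs_out, noise_fun)
        }
      }
    })
  }
  list(y = y, fs = fs_out, times = seq_len(dim(y)[2]) / fs_out)
}

#' Welch cross-spectral density estimate
#'
#' Hanning-tapered, segment-averaged cross-periodograms (averaged over
#' segments and trials), one-sided density normalization, evaluated at the
#' FFT bins nearest the requested grid.
#'
#' @param y channels x time matrix, or channels x time x trials array
#' @param fs sampling rate (Hz)
#' @param window segment length (s)
#' @param step hop between segment starts (s)
#' @param freqs requested frequency grid (Hz)
#' @param demean subtract each segment's mean before tapering
#' @return a [csd_object()]
#' @export
estimate_csd <- function(y, fs, window = 0.5, step = 0.1,
                         freqs = seq(8, 128, by = 2), demean = TRUE) {
  if (length(dim(y)) == 2) dim(y) <- c(dim(y), 1)
  n_ch <- dim(y)[1]; n_t <- dim(y)[2]; n_tr <- dim(y)[3]
  n_seg <- as.integer(round(window * fs))
  if (n_seg > n_t) stop("invalid-argument: window longer than the data")
  if (max(freqs) > fs / 2) stop("invalid-argument: frequency grid exceeds Nyquist")
  hop <- max(1L, as.integer(round(step * fs)))
  starts <- seq.int(1L, n_t - n_seg + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_seg) - 1) / (n_seg - 1))
  U <- sum(h^2)
  fbins <- (seq_len(n_seg) - 1) * fs / n_seg
  kidx <- vapply(freqs, function(f) which.min(abs(fbins - f)), integer(1))
  acc <- array(0i, dim = c(n_ch, n_ch, length(freqs)))
  count <- 0L
  for (tr in seq_len(n_tr)) {
    for (s0 in starts) {
      seg <- y[, s0:(s0 + n_seg - 1L), tr, drop = FALSE]
      dim(seg) <- c(n_ch, n_seg)
      if (demean) seg <- seg - rowMeans(seg)
      X <- t(stats::mvfft(t(seg * rep(h, each = n_ch))))
      Xk <- X[, kidx, drop = FALSE]
      for (k in seq_along(freqs)) {
        acc[, , k] <- acc[, , k] + Xk[, k] %o% Conj(Xk[, k])
      }
      count <- count + 1L
    }
  }
  acc <- acc * (2 / (fs * U * count))
  dimnames(acc) <- list(NULL, NULL, NULL)
  csd_object(freqs, acc)
}
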