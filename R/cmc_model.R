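#' Base constants of the canonical microcircuit
#'
#' Fixed (non-estimated) quantities of the neural mass model: per-population
#' synaptic rate constants, base intrinsic and extrinsic coupling weights,
#' sigmoid shape, and the base scales of the endogenous input, observation and
#' channel-noise models. Free parameters are log-deviations around these
#' bases, so a parameter value of 0 means "base value". The constants are
#' shipped as a versioned JSON file under `extdata`.
#'
#' @param path optional path to an alternative constants file
#' @return a named list of constants
#' @export
cmc_constants <- local({
  cache <- NULL
  function(path = NULL) {
    if (is.null(path)) {
      if (!is.null(cache)) return(cache)
      path <- system.file("extdata", "cmc_base_constants.json", package = "gaintrack")
    }
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    out$kappa_hz <- as.numeric(out$kappa_hz)
    names(out$kappa_hz) <- out$populations
    if (is.null(sys.call(-1))) cache <<- out
    cache <<- out
    out
  }
})

#' Population labels of a canonical-microcircuit source
#' @return character vector `c("SS", "SP", "II", "DP")`
#' @export
cmc_populations <- function() c("SS", "SP", "II", "DP")

#' Names of the full free-parameter vector of the two-source network
#'
#' Extrinsic log-scalings (`A_*`), intrinsic self-inhibition gains (`G_*`),
#' condition modulators (`B_<factor>_<target>` with factors `reg`, `alp`),
#' endogenous input parameters, observation gains and channel-noise levels.
#'
#' @return character vector of parameter names
#' @export
cmc_param_names <- function() {
  b_targets <- c("Gsp_AC", "Gsp_IFG", "Gii_AC", "Gii_IFG", "asc", "desc")
  c("A_asc_ss", "A_asc_dp", "A_desc_sp", "A_desc_ii", "A_asc", "A_desc",
    "G_sp_AC", "G_ii_AC", "G_sp_IFG", "G_ii_IFG",
    paste0("B_reg_", b_targets), paste0("B_alp_", b_targets),
    "in_amp", "in_exp", "obs_AC", "obs_IFG", "noise_white", "noise_pink")
}

#' Default parameter values (prior means)
#'
#' Zeros everywhere except the intrinsic gains, whose prior means place the
#' superficial-pyramidal and inhibitory-interneuron self-inhibition at the
#' operating point that reproduces the empirical band placement (log-scalings
#' -1.39 and -2.02 of the base weights).
#'
#' @return named numeric vector over [cmc_param_names()]
#' @export
cmc_default_params <- function() {
  p <- stats::setNames(numeric(length(cmc_param_names())), cmc_param_names())
  p[c("G_sp_AC", "G_sp_IFG")] <- -1.39
  p[c("G_ii_AC", "G_ii_IFG")] <- -2.02
  p
}

#' Construct a two-source canonical-microcircuit network
#'
#' Sources are AC (auditory cortex, lower) and IFG (inferior frontal gyrus,
#' higher). Ascending connections run SP(AC) to SS/DP(IFG); descending
#' connections run DP(IFG) to SP/II(AC) and are inhibitory.
#'
#' @param params named numeric vector of log-deviation parameters; missing
#'   names are filled from [cmc_default_params()]
#' @param constants base constants, see [cmc_constants()]
#' @return an object of class `cmc_network`
#' @export
cmc_network <- function(params = cmc_default_params(), constants = cmc_constants()) {
  full <- cmc_default_params()
  if (!all(names(params) %in% names(full))) {
    stop("invalid-argument: unknown parameter name(s): ",
         paste(setdiff(names(params), names(full)), collapse = ", "))
  }
  full[names(params)] <- params
  structure(list(params = full, constants = constants,
                 sources = c("AC", "IFG"), n_states = 16L),
            class = "cmc_network")
}

#' Apply condition modulators to a network
#'
#' Each modulated quantity (intrinsic gain or extrinsic pathway) is scaled
#' multiplicatively by `exp(sum_f B_f * level_f)`; equivalently the modulator
#' values are folded additively into the corresponding log-parameters. The
#' returned network has its `B_*` entries zeroed.
#'
#' @param net a [cmc_network()]
#' @param levels named numeric vector `c(reg = ..., alp = ...)`; regularity is
#'   coded RAND = 0 / REG = 1, alphabet size as 0, 1, 2 for r = 5, 10, 15
#' @return modulated `cmc_network`
#' @export
apply_modulation <- function(net, levels) {
  stopifnot(inherits(net, "cmc_network"))
  factors <- c("reg", "alp")
  if (is.null(names(levels))) names(levels) <- factors[seq_along(levels)]
  if (!all(names(levels) %in% factors)) stop("invalid-argument: unknown factor")
  p <- net$params
  for (f in names(levels)) {
    lv <- levels[[f]]
    p["G_sp_AC"]  <- p["G_sp_AC"]  + p[paste0("B_", f, "_Gsp_AC")]  * lv
    p["G_sp_IFG"] <- p["G_sp_IFG"] + p[paste0("B_", f, "_Gsp_IFG")] * lv
    p["G_ii_AC"]  <- p["G_ii_AC"]  + p[paste0("B_", f, "_Gii_AC")]  * lv
    p["G_ii_IFG"] <- p["G_ii_IFG"] + p[paste0("B_", f, "_Gii_IFG")] * lv
    p["A_asc_ss"] <- p["A_asc_ss"] + p[paste0("B_", f, "_asc")] * lv
    p["A_asc_dp"] <- p["A_asc_dp"] + p[paste0("B_", f, "_asc")] * lv
    p["A_desc_sp"] <- p["A_desc_sp"] + p[paste0("B_", f, "_desc")] * lv
    p["A_desc_ii"] <- p["A_desc_ii"] + p[paste0("B_", f, "_desc")] * lv
  }
  p[grepl("^B_", names(p))] <- 0
  net$params <- p
  net
}

#' Signed population-coupling matrix of a network
#'
#' Maps the firing-rate vector (8 populations, source-major SS/SP/II/DP order)
#' to presynaptic drives. Inhibitory interneuron efferents, self-inhibitions
#' and descending extrinsic connections carry negative sign; the sign pattern
#' lives here, not in the (positive) weights.
#'
#' @param net a `cmc_network`
#' @return 8 x 8 numeric matrix
#' @export
coupling_matrix <- function(net) {
  cst <- net$constants
  p <- net$params
  g <- cst$g_base
  M <- matrix(0, 8, 8)
  idx <- function(s, m) 4L * (s - 1L) + m   # m: 1 SS, 2 SP, 3 II, 4 DP
  gain <- list(AC = c(sp = unname(exp(p["G_sp_AC"])), ii = unname(exp(p["G_ii_AC"]))),
               IFG = c(sp = unname(exp(p["G_sp_IFG"])), ii = unname(exp(p["G_ii_IFG"]))))
  for (s in 1:2) {
    gn <- gain[[s]]
    M[idx(s, 1), idx(s, 1)] <- -g[["ss_self"]]
    M[idx(s, 1), idx(s, 2)] <- -g[["sp_to_ss"]]
    M[idx(s, 1), idx(s, 3)] <- -g[["ii_to_ss"]]
    M[idx(s, 2), idx(s, 1)] <-  g[["ss_to_sp"]]
    M[idx(s, 2), idx(s, 2)] <- -g[["sp_self"]] * gn[["sp"]]
    M[idx(s, 3), idx(s, 1)] <-  g[["ss_to_ii"]]
    M[idx(s, 3), idx(s, 3)] <- -g[["ii_self"]] * gn[["ii"]]
    M[idx(s, 3), idx(s, 4)] <-  g[["dp_to_ii"]]
    M[idx(s, 4), idx(s, 2)] <-  g[["sp_to_dp"]]
    M[idx(s, 4), idx(s, 3)] <- -g[["ii_to_dp"]]
    M[idx(s, 4), idx(s, 4)] <- -g[["dp_self"]]
  }
  # A_asc / A_desc are pathway-common log-scalings on top of the per-target ones
  a <- cst$a_base
  M[idx(2, 1), idx(1, 2)] <- M[idx(2, 1), idx(1, 2)] + a[["asc_ss"]] * exp(p["A_asc_ss"] + p["A_asc"])
  M[idx(2, 4), idx(1, 2)] <- M[idx(2, 4), idx(1, 2)] + a[["asc_dp"]] * exp(p["A_asc_dp"] + p["A_asc"])
  M[idx(1, 2), idx(2, 4)] <- M[idx(1, 2), idx(2, 4)] - a[["desc_sp"]] * exp(p["A_desc_sp"] + p["A_desc"])
  M[idx(1, 3), idx(2, 4)] <- M[idx(1, 3), idx(2, 4)] - a[["desc_ii"]] * exp(p["A_desc_ii"] + p["A_desc"])
  M
}

#' Firing-rate sigmoid
#'
#' Centered logistic transform of the membrane-potential deviation from the
#' fixed point: `sigma(0) = 0`, saturating at `+/- rmax/2`, slope
#' `rho * rmax / 4` at the origin.
#'
#' @param v membrane potential deviation (any numeric shape)
#' @param constants base constants providing `sigmoid_rho`, `sigmoid_rmax`
#' @return firing rate, same shape as `v`
#' @export
cmc_sigmoid <- function(v, constants = cmc_constants()) {
  constants$sigmoid_rmax * (1 / (1 + exp(-constants$sigmoid_rho * v)) - 0.5)
}

#' Derivative of the firing-rate sigmoid
#' @inheritParams cmc_sigmoid
#' @return slope of the sigmoid at `v`
#' @export
cmc_sigmoid_deriv <- function(v, constants = cmc_constants()) {
  s <- 1 / (1 + exp(-constants$sigmoid_rho * v))
  constants$sigmoid_rmax * constants$sigmoid_rho * s * (1 - s)
}

#' State ordering helper
#'
#' States are ordered source-major, with the four membrane potentials (SS, SP,
#' II, DP) followed by the four synaptic currents per source.
#'
#' @param net a `cmc_network`
#' @return list with integer index vectors `V` and `I` (length 8 each)
#' @export
state_index <- function(net) {
  list(V = c(1:4, 9:12), I = c(5:8, 13:16))
}

#' Time derivative of the network state
#'
#' Second-order synaptic dynamics per population: `dV/dt = I` and
#' `dI/dt = kappa * U - 2 kappa I - kappa^2 V`, where the presynaptic drive
#' `U` is the signed coupling-weighted sum of presynaptic firing rates plus
#' endogenous input into the spiny stellate populations.
#'
#' @param x state vector (length 16) or 16 x n matrix of states
#' @param net a `cmc_network`
#' @param u exogenous drive, length-2 vector (per source, into SS) or 2 x n
#' @param M optional precomputed [coupling_matrix()]
#' @return derivative, same shape as `x`
#' @export
state_derivative <- function(x, net, u = c(0, 0), M = coupling_matrix(net)) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (nrow(x) != net$n_states) stop("invalid-argument: state dimension mismatch")
  if (is.null(dim(u))) u <- matrix(u, nrow = 2, ncol = ncol(x))
  si <- state_index(net)
  V <- x[si$V, , drop = FALSE]
  I <- x[si$I, , drop = FALSE]
  kap <- rep(net$constants$kappa_hz, 2)
  U <- M %*% cmc_sigmoid(V, net$constants)
  U[c(1, 5), ] <- U[c(1, 5), ] + u          # endogenous input into SS of each source
  dI <- kap * U - 2 * kap * I - kap^2 * V
  dx <- x
  dx[si$V, ] <- I
  dx[si$I, ] <- dI
  if (vec) dx <- drop(dx)
  dx
}

#' Analytic Jacobian of the state derivative
#'
#' @param net a `cmc_network`
#' @param x state at which to linearize (default: origin)
#' @return 16 x 16 numeric matrix
#' @export
state_jacobian <- function(net, x = numeric(16)) {
  si <- state_index(net)
  M <- coupling_matrix(net)
  kap <- rep(net$constants$kappa_hz, 2)
  sd_ <- cmc_sigmoid_deriv(x[si$V], net$constants)
  J <- matrix(0, 16, 16)
  J[cbind(si$V, si$I)] <- 1
  J[si$I, si$V] <- kap * M %*% diag(sd_, 8) - diag(kap^2, 8)
  J[cbind(si$I, si$I)] <- -2 * kap
  J
}

#' Fixed point of the deterministic dynamics
#'
#' Newton iteration on `state_derivative(x) = 0` starting from the origin.
#' With the centered sigmoid and zero drive the origin is an exact root; a
#' constant bias drive moves the root and the iteration follows it.
#'
#' @param net a `cmc_network`
#' @param u constant drive (length 2)
#' @param tol residual norm tolerance
#' @param maxit maximum Newton iterations
#' @return state vector at the fixed point
#' @export
fixed_point <- function(net, u = c(0, 0), tol = 1e-9, maxit = 100) {
  x <- numeric(net$n_states)
  for (i in seq_len(maxit)) {
    fx <- state_derivative(x, net, u)
    if (sqrt(sum(fx^2)) < tol) return(x)
    J <- state_jacobian(net, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) stop("numerical-failure: singular Jacobian in fixed-point search")
    x <- x - step
  }
  fx <- state_derivative(x, net, u)
  if (sqrt(sum(fx^2)) < tol) return(x)
  stop(sprintf("numerical-failure: fixed point not found in %d iterations (residual %.3e)",
               maxit, sqrt(sum(fx^2))))
}
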