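#' Build the default ground-truth scenario
#'
#' A two-source AC-IFG network at the optimized whole-window operating point,
#' with smooth Gaussian-bump schedules of the condition modulators: extrinsic
#' effects early in the sequence, frontal (IFG) superficial-pyramidal
#' disinhibition by regularity peaking ~1050 ms and by alphabet size
#' ~1550 ms, auditory-cortex disinhibition peaking ~1850/1950 ms. Sensor-level
#' effect time courses are a sparse linear mixture of the scheduled
#' modulators plus pink noise.
#'
#' @param seed master seed
#' @param n_trials trials per condition cell
#' @param sets modulated sets receiving non-zero schedules (default: the
#'   winning model's, extrinsic + SP gain)
#' @param rms_noise_sd sensor pink-noise level as a fraction of the effect
#'   signal SD
#' @return object of class `scenario`
#' @export
build_default_scenario <- function(seed = 1, n_trials = 104,
                                   sets = c("extrinsic", "SP_gain"),
                                   rms_noise_sd = 0.35) {
  truth <- cmc_default_params()
  truth[c("A_asc_ss", "A_asc_dp", "A_desc_sp", "A_desc_ii")] <-
    c(-1.0919, -0.0901, -0.0877, -0.3759)
  truth[c("G_sp_AC", "G_ii_AC", "G_sp_IFG", "G_ii_IFG")] <-
    c(-1.3455, 0.2480, -1.1852, -2.2009)
  bump <- function(amp, peak, sd) {
    force(amp); force(peak); force(sd)
    function(t_ms) ifelse(t_ms < 0, 0, amp * exp(-0.5 * ((t_ms - peak) / sd)^2))
  }
  zero <- function(t_ms) rep(0, length(t_ms))
  schedules <- list(
    B_reg_Gsp_IFG = bump(-0.40, 1050, 300),
    B_alp_Gsp_IFG = bump(-0.15, 1550, 300),
    B_reg_Gsp_AC  = bump(-0.40, 1850, 300),
    B_alp_Gsp_AC  = bump(-0.15, 1950, 300),
    B_reg_asc     = bump(-0.30,  350, 150),
    B_reg_desc    = bump(+0.30,  550, 180),
    B_alp_asc     = bump(-0.15,  700, 200),
    B_alp_desc    = bump(+0.15,  850, 220)
  )
  if (!"extrinsic" %in% sets) {
    schedules[c("B_reg_asc", "B_reg_desc", "B_alp_asc", "B_alp_desc")] <-
      list(zero, zero, zero, zero)
  }
  if (!"SP_gain" %in% sets) {
    schedules[c("B_reg_Gsp_AC", "B_reg_Gsp_IFG", "B_alp_Gsp_AC", "B_alp_Gsp_IFG")] <-
      list(zero, zero, zero, zero)
  }
  # sparse mixture defining the sensor-level effect time courses. The support
  # holds one member per temporal cluster of the schedules: with the
  # paper-anchored peak times, same-epoch schedules are near-collinear after
  # standardization (|r| up to 0.98), so a support containing two members of
  # one cluster is not identifiable by any sparse regression.
  mixture <- list(
    regularity  = c(B_reg_Gsp_AC = 1.0, B_reg_Gsp_IFG = 0.8),
    alphabet    = c(B_alp_Gsp_IFG = 0.8),
    interaction = c(B_reg_asc = 0.7)
  )
  conditions <- data.frame(
    cell = c("REG5", "REG10", "REG15", "RAND5", "RAND10", "RAND15"),
    reg = c(1, 1, 1, 0, 0, 0),
    alp = c(0, 1, 2, 0, 1, 2),
    stringsAsFactors = FALSE)
  structure(list(network = truth, schedules = schedules, mixture = mixture,
                 conditions = conditions, n_trials = n_trials,
                 rms_noise_sd = rms_noise_sd, seed = seed),
            class = "scenario")
}

# simulate one condition cell with piecewise-frozen scheduled parameters
simulate_condition <- function(sc, levels, n_trials, seed,
                               t_pre = 700, t_post = 3000,
                               fs_in = 2400, fs_out = 600,
                               constants = cmc_constants(),
                               freeze_ms = 100) {
  n_steps <- as.integer(round((t_pre + t_post) / 1000 * fs_in))
  seg_len <- as.integer(round(freeze_ms / 1000 * fs_in))
  seg_starts <- seq(1L, n_steps, by = seg_len)
  dt <- 1 / fs_in

  net0 <- cmc_network(sc$network, constants)
  inn <- net_innovations(net0)
  inn_fun <- function(f) innovation_density(inn, f)[1, ]
  si <- state_index(net0)
  kapv <- rep(constants$kappa_hz, 2)

  u <- array(0, dim = c(2, n_steps + 1, n_trials))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) for (s in 1:2) {
      amp_s <- inn$amplitude[s] / inn$amplitude[1]
      u[s, , tr] <- amp_s * shaped_noise(n_steps + 1, fs_in, inn_fun)
    }
  })

  x <- matrix(0, 16, n_trials)
  y_full <- array(0, dim = c(2, n_steps, n_trials))
  C <- matrix(0, 2, 16)
  C[1, si$V[2]] <- exp(sc$network[["obs_AC"]])
  C[2, si$V[6]] <- exp(sc$network[["obs_IFG"]])

  for (s0 in seg_starts) {
    s1 <- min(s0 + seg_len - 1L, n_steps)
    t_mid <- ((s0 + s1) / 2) / fs_in * 1000 - t_pre   # ms relative to onset
    p <- sc$network
    for (nm in names(sc$schedules)) p[nm] <- sc$schedules[[nm]](t_mid)
    net <- apply_modulation(cmc_network(p, constants), levels)
    M <- coupling_matrix(net)
    ev <- eigen(state_jacobian(net), only.values = TRUE)$values
    if (max(Re(ev)) >= 0) {
      stop(sprintf("instability under scheduled parameters in segment starting %.0f ms",
                   s0 / fs_in * 1000 - t_pre))
    }
    for (t in s0:s1) {
      ut <- matrix(u[, t, ], nrow = 2)
      ut1 <- matrix(u[, t + 1, ], nrow = 2)
      f1 <- state_derivative(x, net, ut, M)
      f2 <- state_derivative(x + dt * f1, net, ut1, M)
      x <- x + dt * (f1 + f2) / 2
      y_full[, t, ] <- C %*% x
    }
  }

  dec <- as.integer(round(fs_in / fs_out))
  bf <- signal::butter(6, 0.8 / dec)
  n_out <- floor(n_steps / dec)
  y <- array(0, dim = c(2, n_out, n_trials))
  for (tr in seq_len(n_trials)) for (ch in 1:2) {
    yf <- signal::filtfilt(bf, y_full[ch, , tr])
    y[ch, , tr] <- yf[seq.int(dec, n_steps, by = dec)][seq_len(n_out)]
  }
  noise_fun <- function(f) channel_noise_density(net0, f)[1, ]
  with_seed(derive_seed(seed, 7L), {
    for (tr in seq_len(n_trials)) for (ch in 1:2) {
      y[ch, , tr] <- y[ch, , tr] + shaped_noise(n_out, fs_out, noise_fun)
    }
  })
  list(y = y, fs = fs_out, t0 = -t_pre,
       times = seq_len(n_out) / fs_out * 1000 - t_pre)
}

#' True modulator trajectories of a scenario on a window grid
#' @param sc a `scenario`
#' @param grid a [window_grid()]
#' @return windows x 8 matrix of scheduled modulator values
#' @export
scenario_trajectories <- function(sc, grid = window_grid()) {
  vapply(names(sc$schedules), function(nm) sc$schedules[[nm]](grid$centers),
         numeric(grid$n_windows))
}

#' Generate a complete synthetic dataset from a scenario
#'
#' Simulates the time-varying-parameter network dynamics per condition
#' (parameters frozen per 100 ms, matching the belief-updating step), builds
#' whole-epoch and windowed cross-spectral features, constructs sensor-level
#' RMS series whose design contrasts equal the scenario's sparse mixture of
#' true modulator schedules plus pink noise, and records every generated
#' parameter in a truth table.
#'
#' @param sc a [build_default_scenario()] object
#' @param n_trials trials per condition (default: the scenario's)
#' @param grid [window_grid()] for the windowed features
#' @param constants base constants
#' @param windowed compute windowed features (set `FALSE` to skip)
#' @return list: `ts` (per-condition trial arrays), `whole_csd`, `features`
#'   (per window per condition), `rms` (six series at 600 Hz), `truth`
#' @export
generate_dataset <- function(sc, n_trials = sc$n_trials, grid = window_grid(),
                             constants = cmc_constants(), windowed = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  conds <- sc$conditions
  ts <- vector("list", nrow(conds))
  names(ts) <- conds$cell
  for (i in seq_len(nrow(conds))) {
    ts[[i]] <- simulate_condition(sc, c(reg = conds$reg[i], alp = conds$alp[i]),
                                  n_trials, derive_seed(sc$seed, 100L + i),
                                  constants = constants)
  }
  fs <- ts[[1]]$fs
  onset_idx <- which(ts[[1]]$times >= 0)[1]
  post <- lapply(ts, function(d) d$y[, onset_idx:(onset_idx + 3 * fs - 1), , drop = FALSE])
  whole_csd <- lapply(post, estimate_csd, fs = fs)
  features <- if (windowed) windowed_features(post, grid, fs = fs) else NULL

  rms <- scenario_rms(sc, fs = fs, grid = grid)
  truth <- list(network = sc$network,
                trajectories = scenario_trajectories(sc, grid),
                window_centers = grid$centers,
                mixture = sc$mixture,
                coding = attr(rms, "coding"),
                conditions = conds,
                n_trials = n_trials,
                rms_noise_sd = sc$rms_noise_sd,
                seed = sc$seed)
  list(ts = ts, whole_csd = whole_csd, features = features, rms = rms,
       design = conds[, c("reg", "alp")], truth = truth, fs = fs)
}

#' Construct the sensor-level RMS series of a scenario
#'
#' Per-condition across-channel RMS time courses at the sensor rate, built
#' so that the three design contrasts equal the scenario's sparse mixture of
#' the true (standardized, smoothed, upsampled) modulator schedules, plus
#' pink noise at `sc$rms_noise_sd` times the mean effect-signal SD.
#'
#' @param sc a [build_default_scenario()] object
#' @param fs sensor sampling rate (Hz)
#' @param grid [window_grid()] on which the schedules are sampled
#' @param seed noise seed (default: the scenario's)
#' @return named list of six series; attributes `"coding"` (contrast coding
#'   per condition) and `"effects"` (the noiseless effect signals)
#' @export
scenario_rms <- function(sc, fs = 600, grid = window_grid(), seed = sc$seed) {
  conds <- sc$conditions
  truth_traj <- scenario_trajectories(sc, grid)
  out_times <- seq(0, 3000 - 1000 / fs, by = 1000 / fs)
  Xtrue <- prepare_predictors(truth_traj, window_times = grid$centers,
                              out_times = out_times, target_rate = fs,
                              standardize = FALSE)
  Xs <- scale(Xtrue)
  Xs[, apply(Xtrue, 2, stats::sd) < 1e-12] <- 0
  effects <- lapply(sc$mixture, function(w) {
    drop(Xs[, names(w), drop = FALSE] %*% w)
  })
  coding <- list(
    regularity  = c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5),
    alphabet    = c(-0.25, 0, 0.25, -0.25, 0, 0.25),
    interaction = c(0.25, 0, -0.25, -0.25, 0, 0.25)
  )
  sig_sd <- mean(vapply(effects, stats::sd, numeric(1)))
  pink <- function(f) (sc$rms_noise_sd * sig_sd)^2 * 2 * (pmax(f, 1))^(-1) / log(300)
  rms <- vector("list", nrow(conds))
  names(rms) <- conds$cell
  for (i in seq_len(nrow(conds))) {
    base <- 1 +
      coding$regularity[i] * effects$regularity +
      coding$alphabet[i] * effects$alphabet +
      coding$interaction[i] * effects$interaction
    noise <- with_seed(derive_seed(seed, 200L + i),
                       shaped_noise(length(out_times), fs, pink))
    rms[[i]] <- base + noise
  }
  attr(rms, "coding") <- coding
  attr(rms, "effects") <- effects
  rms
}

#' Write and read scenario truth tables
#'
#' Full-precision JSON round trip of everything needed to reconstruct the
#' ground truth of a generated dataset.
#'
#' @param truth the `truth` element of [generate_dataset()] output
#' @param path output file (JSON)
#' @return `path` (write) / truth list (read)
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  tr$trajectories <- as.data.frame(tr$trajectories)
  # named vectors as objects so names survive the round trip
  tr$network <- as.list(tr$network)
  tr$mixture <- lapply(tr$mixture, as.list)
  tr$coding <- lapply(tr$coding, as.list)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$network <- unlist(tr$network)
  tr$trajectories <- as.matrix(tr$trajectories)
  tr$mixture <- lapply(tr$mixture, unlist)
  tr$coding <- lapply(tr$coding, unlist)
  tr
}
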