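#' Run the full synthetic recovery pipeline
#'
#' Generates a dataset from a scenario, fits the whole-epoch model with
#' Bayesian model reduction and averaging, then runs sliding-window belief
#' updating for the requested models and returns the modulator trajectories
#' alongside the ground truth.
#'
#' @param scenario a [build_default_scenario()] object
#' @param models list of `model_spec`s to update (default: the winning-model
#'   structure, extrinsic + SP gain)
#' @param grid [window_grid()] for the sliding-window analysis
#' @param n_trials trials per condition (default: the scenario's)
#' @param constants base constants
#' @param ... passed to [invert_csd()]
#' @return list: `dataset`, `whole` ([whole_window_dcm()] output),
#'   `trajectories` (per model id: `posterior_trajectory`), `extracted`
#'   (for models carrying the 4 modulatory parameters per factor), `truth`
#'   (windows x 8 matrix), `recovery` (per-modulator correlation with truth,
#'   for the first extractable model)
#' @export
run_recovery_pipeline <- function(scenario,
                                  models = enumerate_model_space()[5],
                                  grid = window_grid(),
                                  n_trials = scenario$n_trials,
                                  constants = cmc_constants(), ...) {
  ds <- generate_dataset(scenario, n_trials = n_trials, grid = grid,
                         constants = constants)
  ww <- whole_window_dcm(ds$whole_csd, ds$design, constants = constants, ...)
  fixed <- cmc_default_params()
  fixed[names(ww$bma$mean)] <- ww$bma$mean
  fixed[grep("^B_", names(fixed))] <- 0
  truth <- scenario_trajectories(scenario, grid)
  trajs <- list(); extracted <- list(); recovery <- NULL
  for (m in models) {
    init <- gd_subset(ww$bma, model_b_params(m))
    tj <- update_sequence(ds$features, ds$design, init, m, fixed = fixed,
                          constants = constants, ...)
    trajs[[m$id]] <- tj
    if (setequal(m$modulated_sets, c("extrinsic", "SP_gain"))) {
      tr <- extract_trajectories(tj, centers = grid$centers)
      extracted[[m$id]] <- tr
      if (is.null(recovery)) {
        recovery <- vapply(colnames(tr$mean), function(nm) {
          stats::cor(tr$mean[, nm], truth[, nm])
        }, numeric(1))
      }
    }
  }
  list(dataset = ds, whole = ww, trajectories = trajs, extracted = extracted,
       truth = truth, recovery = recovery,
       pooled_evidence = vapply(trajs, function(t) sum(t$free_energies), numeric(1)))
}
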