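# gaintrack

Slow modulations of synaptic gain can explain why predictable sound
sequences change both the oscillatory content and the sustained amplitude of
cortical responses. `gaintrack` implements that modelling stack as a tested,
fully synthetic pipeline: a two-source canonical-microcircuit (CMC) neural
mass model of the auditory processing stream (auditory cortex ⇄ inferior
frontal gyrus), spectral model inversion, time-resolved Bayesian belief
updating of gain parameters, and an elastic-net linking of the recovered
parameter trajectories to sensor-level sustained-field effects. Every stage
runs against a ground-truth generator, so the whole chain is testable
without any empirical recordings.

It is aimed at computational neuroscientists who want a self-contained,
inspectable implementation of dynamic causal modelling for cross-spectral
density (DCM-CSD) with sliding-window belief updating — and at anyone who
needs a calibrated synthetic benchmark for parameter-recovery studies in
this model family.

## The model in brief

Each source holds four neural populations (spiny stellate SS, superficial
pyramidal SP, inhibitory interneurons II, deep pyramidal DP) with
second-order synaptic dynamics

$$\dot V_m = I_m,\qquad \dot I_m = \kappa_m U_m - 2\kappa_m I_m - \kappa_m^2 V_m,$$

presynaptic drive $U_m = \sum_n w_{n\to m}\,\sigma(V_n) + E$, a centred
logistic firing-rate sigmoid, ascending connections SP→SS/DP, descending
(inhibitory) connections DP→SP/II, and self-inhibition "gain" terms on SP
and II. The observed spectra follow analytically from the linearization:
$S(\omega) = T\,\mathrm{diag}(S_u)\,T^* + N$ with
$T(\omega) = C(i\omega I - J)^{-1}L$. Condition effects (sequence
regularity; alphabet size) act as log-modulators $B$ on the gains and the
extrinsic pathways; inversion is variational Laplace on 8–128 Hz
cross-spectral features, with Bayesian model reduction over a five-model
space, Bayesian model averaging, and posterior-to-prior belief updating
over 500 ms windows stepped by 100 ms with covariance inflation
$\Sigma_{const}/j$.

## Worked example

Recover a known gain-modulation schedule from simulated spectra:

```r
library(gaintrack)

sc  <- build_default_scenario(seed = 11, n_trials = 32)
ds  <- generate_dataset(sc)                      # ~15 s
ww  <- whole_window_dcm(ds$whole_csd, ds$design) # full model + BMR + BMA
ww$winner
#> [1] "m5"        # extrinsic + superficial-pyramidal gain

m5    <- enumerate_model_space()[[5]]
init  <- gd_subset(ww$bma, model_b_params(m5))
fixed <- cmc_default_params()
fixed[names(ww$bma$mean)] <- ww$bma$mean
fixed[grep("^B_", names(fixed))] <- 0

traj <- update_sequence(ds$features, ds$design, init, m5, fixed = fixed)
tr   <- extract_trajectories(traj, centers = window_grid()$centers)
round(cor(tr$mean[, "B_reg_Gsp_AC"],
          scenario_trajectories(sc)[, "B_reg_Gsp_AC"]), 2)
#> [1] 1
```

The recovered column `B_reg_Gsp_AC` is the time course of the regularity
effect on auditory-cortex superficial-pyramidal gain (a negative excursion =
disinhibition, peaking ~1850 ms in the default scenario); at the default
settings it tracks the generating schedule with correlation ≈ 1.0. At this
reduced trial count the descending-pathway modulators are noisier (see the
methods vignette); the full study-sized run uses 104 trials per condition.

The numbered drivers under `analysis/` run the complete study on a
generated dataset and write their tables under `results/`:

```sh
Rscript analysis/01_stimuli.R        # tone-pip sequences + latencies
Rscript analysis/02_simulate.R       # ground-truth dataset + truth tables
Rscript analysis/03_whole_window_dcm.R
Rscript analysis/04_belief_updating.R
Rscript analysis/05_tfa.R            # induced time-frequency contrasts
Rscript analysis/06_linking.R        # elastic-net linking (alpha = 0.95)
```

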