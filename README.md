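# envdyn

Resting-state electrophysiological network analysis at the level of
band-limited power envelopes, for researchers studying large-scale brain
organization with MEG/EEG source reconstructions — and for anyone who needs
a fully synthetic, ground-truthed test bench for such analyses.

The package implements two complementary characterizations of resting
activity over a 32-node parcellation spanning six resting-state networks
(DAN, VAN, DMN, pVIS, MOT, LAN):

* **Static connectomics.** For each region pair the analytic signals are
  orthogonalized pairwise,
  `y⊥x(t) = Im( y(t) · conj(x(t)) / |x(t)| )`, removing the zero-lag
  component that spatial leakage can create; connectivity is the
  symmetrized correlation of the 1-Hz low-passed envelopes,
  `r = ½[ corr(lp|x|, lp|y⊥x|) + corr(lp|y|, lp|x⊥y|) ]`, assembled into
  496-connection connectomes per subject and band (theta 4–8, alpha 8–12,
  beta 12–30 Hz), with node power (band-limited variance) and global /
  network summaries.
* **Transient dynamics.** Wide-band (4–30 Hz) envelopes are window-averaged
  to 40 Hz (100-ms windows every 25 ms), normalized, concatenated across
  subjects, PCA-prewhitened, and modelled with a K = 8 state
  Gaussian-observation hidden Markov model (full covariances, 10 EM
  restarts, Viterbi decoding). Each state is summarized by its mean
  lifetime (MLT), fractional occupancy (FO), mean interval length (MIL)
  and a partial-correlation state power map.

Group differences (e.g. children vs young adults vs elders) are tested with
Kruskal–Wallis omnibus tests and post-hoc Tukey range tests on ranks, after
confound regression (power, sex, acquisition system), Bonferroni-corrected
per family: 3 (bands), 18 (bands × networks), K − 1 = 7 (HMM metrics), and
the effective number of band-specific connections
`N_eff = n_bands · ρ(ρ−1)/2` derived from the spatial degrees of freedom ρ.

A synthetic cohort generator (`make_cohort()`, `default_cohort_configs()`)
plants known envelope correlations, band power scales, Markov-switching
state dynamics and leakage mixing, so the whole chain can be validated
against ground truth.

## Worked example

```r
library(envdyn)

# a small synthetic cohort: 3 groups x 2 subjects, 20 s at 250 Hz
cfgs <- default_cohort_configs(n_per_group = 2, duration_s = 20)
cohort <- make_cohort(cfgs, seed = 1)

# leakage-corrected alpha-band connectome for one child and one young adult
conn_c <- build_connectome(cohort$children_01, "alpha")
conn_y <- build_connectome(cohort$young_adults_01, "alpha")
s_c <- summarize_connectome(conn_c, node_power(cohort$children_01, "alpha"))
s_y <- summarize_connectome(conn_y, node_power(cohort$young_adults_01, "alpha"))
round(cbind(children = s_c$connectivity, young_adults = s_y$connectivity), 3)
#>      children young_adults
#> [1,]    0.026        0.154     # global mean over all 496 connections
#> [2,]    0.122        0.265     # DAN   (within-network means follow)
#> [3,]    0.128        0.213     # VAN
#> [4,]    0.221        0.282     # DMN
#> [5,]    0.052        0.499     # pVIS  (single V1-V1 connection)
#> [6,]    0.127        0.462     # MOT
#> [7,]    0.115        0.424     # LAN
```

The young adult's connectome recovers the planted stronger coupling
(within-network envelope correlation 0.5 vs 0.1 for children), attenuated —
as expected — by orthogonalization.

```r
# fit a 2-state HMM to a planted switching signal and decode it
set.seed(1)
plan <- markov_plan(matrix(c(.95, .05, .05, .95), 2, byrow = TRUE),
                    n_regions = 1)
s <- sample_state_sequence(plan, 2000, seed = 5)
x <- matrix(rnorm(2000, mean = c(-3, 3)[s]), ncol = 1)
fit <- fit_hmm(x, K = 2, n_restarts = 3, seed = 1)
fit
#> <envhmm> 2-state Gaussian HMM in 1 dims, 2000 obs
#>   log-likelihood -3266.17 (restart 1 of 3, converged)
sort(drop(fit$means))                       # recovered state means
#> [1] -2.976510  3.053733
v <- predict(fit, x)                        # Viterbi path; labels arbitrary
max(mean(v == s), mean(v == 3 - s))         # agreement after label alignment
#> [1] 0.9995
```

The full pipeline — synthesis, connectomes, summaries, HMM, metrics, maps,
and all statistics tables — runs from one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), "results/run1")
subset(res$stats$network_connectivity, significant & feature == "pVIS.beta")
```

which on the default cohort flags, among others, the planted drop in
primary-visual beta connectivity of elders vs young adults. A thin CLI
wrapper lives at `inst/scripts/envdyn-pipeline.R`.

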