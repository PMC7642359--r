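---
title: "Envelope connectomics and transient state dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope connectomics and transient state dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envdyn)
```

## The scientific problem

Resting-state electrophysiological recordings (MEG/EEG source
reconstructions) exhibit two complementary kinds of large-scale
organization. *Static* functional connectivity: the slow (< 1 Hz)
fluctuations of band-limited power envelopes are correlated across distant
regions, and the matrix of these correlations over a resting-state-network
(RSN) parcellation forms a functional connectome. *Transient* dynamics: the
multivariate envelope signal visits short-lived (100–300 ms) recurrent
states of coordinated activation/deactivation, well described by a hidden
Markov model (HMM).

Both analyses face the same obstacle: source reconstruction has limited
spatial resolution, so each reconstructed regional signal is an
instantaneous real linear mixture of true sources ("spatial leakage"),
which inflates zero-lag correlations artificially. `envdyn` implements the
standard countermeasure — pairwise orthogonalization of analytic signals —
together with the full analysis chain around it, and a synthetic cohort
generator that plants known effects so every stage can be validated end to
end.

## Static connectomics

For a region pair with analytic (Hilbert-transformed, band-limited) signals
$x(t)$, $y(t)$, the leakage-orthogonal component of $y$ relative to $x$ is

$$y_{\perp x}(t) = \mathrm{Im}\!\left(\frac{y(t)\,\overline{x(t)}}{|x(t)|}\right),$$

which removes, at every time point, the part of $y$ collinear with $x$ —
exactly the part that instantaneous mixing can create. The connectivity
estimate is the symmetrized envelope correlation

$$r = \tfrac12\left[\mathrm{corr}\big(lp|x|,\; lp|y_{\perp x}|\big) +
\mathrm{corr}\big(lp|y|,\; lp|x_{\perp y}|\big)\right],$$

with $lp$ a zero-phase 1-Hz low-pass. The order of operations is fixed as:
orthogonalize at the full sampling rate → magnitude → low-pass → trim 1 s
from each edge → correlate, and the two directions are averaged *after* the
envelope low-pass. The estimator is conservative: orthogonalization removes
genuine zero-lag common signal along with leakage, so planted correlations
are recovered attenuated but monotonically (which is all the rank-based
group statistics require). Collinear or otherwise degenerate directions
contribute 0 rather than `NA`, so downstream statistics never see missing
cells; each such fallback is reported through the package log
(`options(envdyn.verbose = TRUE)`).

We deliberately use *pairwise* rather than symmetric multivariate
orthogonalization, reproducing the analysis this package operationalizes;
the known "ghost interaction" residuals of the pairwise scheme come with
it.

Node power is the variance of the band-passed, edge-trimmed signal. Global
and network summaries are plain means (all 496 pairs, within-network pairs,
all 32 nodes, network nodes); for the two-node primary visual network the
network mean is the single V1–V1 connection by construction.

Bands are theta (4–8 Hz), alpha (8–12 Hz), beta (12–30 Hz) and wide
(4–30 Hz). Filters are order-4 Butterworth designs applied
forward-backward (zero phase). The compiled filter kernel pads with odd
reflection (3 × order samples) to suppress startup transients; agreement
with `signal::filtfilt` away from edges is tested. The gamma band is out of
scope throughout.

## Confound regression

Before testing, features are residualized by OLS on an intercept plus
covariates, and the fitted intercept is added back so the grand level is
preserved. Connectivity features use band-specific global power (the mean
node variance in that band), sex and acquisition system; power and HMM
temporal metrics use sex and system only. The power covariate choice
deserves a note: "static power" could be read as per-node or wide-band;
we fix it as the band-specific global power, which is the version that
cleanly separates connectivity effects from power effects in the same band.

## Transient state dynamics

The dynamic chain follows the GLEAN-style recipe: wide-band envelopes are
averaged over 100-ms windows sliding every 25 ms (75% overlap — a 10-Hz
non-overlapping window rate, emitted at 40 Hz), demeaned per channel and
scaled by each subject's pooled envelope SD, concatenated across subjects,
reduced to the leading principal components scaled to unit variance, and
modelled with a K = 8 state Gaussian-observation HMM with full state
covariances. Only windows fully contained in the signal are emitted, so the
output length is $\lfloor (N - w)/s \rfloor + 1$.

Two deliberate substitutions relative to the variational toolbox the recipe
originates from:

* Inference is maximum-likelihood EM (Baum-Welch) with 10 seeded restarts
  (k-means initialization) and selection by final log-likelihood, standing
  in for variational inference with selection by lowest free energy. For a
  point-estimate pipeline feeding rank statistics this changes nothing
  structurally; it avoids carrying a variational machinery that is not the
  object of study.
* The requested 40 principal components exceed the rank of a 32-channel
  parcellation; the count is capped at the numerical rank (32 here) with a
  warning rather than failing.

Numerical choices: EM stops when the per-sample log-likelihood gain drops
below `tol` (default 1e-5) or at `max_iter`; covariance collapse is handled
by diagonal loading (logged); the concatenation is modelled as a single
sequence, matching the group-concatenation recipe. `fit_hmm()` returns a
classed model object with `print`, `summary`, `coef`, `logLik`, `predict`
(Viterbi or posterior decoding) and `simulate` methods.

Viterbi decoding yields mutually exclusive binary state series per subject,
summarized per state as mean lifetime (MLT), fractional occupancy (FO) and
mean interval length (MIL). Censoring rules are not dictated by the
definitions, so they are fixed as: MLT includes visits truncated by the
recording edges; MIL uses only complete between-visit gaps. Never-visited
states get FO = 0 and missing MLT/MIL.

State power maps are partial correlations between each state's binary
series and each channel's envelope, controlling for the other K−1 states.
Because exclusive indicators sum to a constant, demeaning all of them makes
the naive regression collinear; the well-posed formulation used here
residualizes the *raw* indicator and the demeaned envelope on the other
K−1 raw indicators without an intercept (equivalently: the envelope
residual subtracts per-state means), then correlates the residuals.

The per-group HMM variant (`hmm = list(grouping = "per_group")`) fits one
model per group; since state labels are then not comparable across groups,
the group-difference tests on temporal metrics run only in the pooled mode.

## Group statistics

All group comparisons are non-parametric: a Kruskal–Wallis omnibus test per
feature (tie-corrected, chi-square reference; delegated to
`stats::kruskal.test`) with post-hoc Tukey–Kramer range tests on pooled
midranks,

$$q_{ij} = \frac{|\bar R_i - \bar R_j|}{\sqrt{\frac{N(N+1)}{24}\left(\frac1{n_i}+\frac1{n_j}\right)}},$$

referred to the studentized range distribution with infinite error degrees
of freedom — the rank variance $N(N+1)/12$ is known, not estimated, which
is the standard normal-theory approximation for rank post-hocs. Both
statistics are invariant under strictly monotone transforms of the data.

Bonferroni factors per family: 3 (bands) for global measures, 18 (3 bands ×
6 RSNs) for network measures, K − 1 = 7 for HMM temporal metrics (temporal
exclusivity removes one degree of freedom), and for the full connectome the
*effective* number of band-specific connections
$N_\mathrm{eff} = n_\mathrm{bands}\,\rho(\rho-1)/2$, where $\rho$ is the
spatial degrees of freedom estimated as the numerical rank of the mixing
(leadfield stand-in) matrix. The formula as printed in its source is
internally inconsistent with the value reported there ($\rho = 55$ gives
4455, while the reported ≈513 corresponds to an effective dimension ≈19);
`effective_comparisons()` therefore exposes $\rho$ as a parameter, and the
applied connectome factor is capped at the raw count so the correction is
never laxer than raw Bonferroni would be. Significance flags are exactly
`p * factor < 0.05`.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated. Per subject it draws a hidden state
sequence from a Markov plan, synthesizes per-band envelopes with a planted
cross-region correlation structure, modulates them by the active state's
regional gains, multiplies by independent unit-variance narrowband Gaussian
carriers, sums the bands, and optionally applies an instantaneous mixing
matrix as the leakage stand-in.

Baseline envelopes are mean-shifted clipped Gaussians: white noise is
low-pass filtered at 0.7 Hz, linearly mixed to the target correlation, and
mapped to $\max(1 + 0.7\,g(t),\ 0.05)$. The shift-and-clip construction was
chosen over full-wave rectification because rectification provably destroys
the planted correlation (folding a bivariate normal with $\rho = 0.8$
yields envelope correlation ≈0.60), whereas clipping at ≈1.4 SD below the
mean affects ~9% of samples and biases planted correlations by ≲0.01. The
envelope CV of 0.7 is chosen so that the slow envelope dominates the
residual sub-1-Hz fluctuation of the carrier's own Rayleigh envelope; with
narrower CVs the Hilbert-recovered envelope correlates noticeably worse
with the planted one.

Covariates are deterministic (sex alternates within group; the
acquisition-system tag splits each group in half), so cohorts are fully
reproducible from `(configs, seed)`; all child seeds derive from the master
seed.

The default three-group cohort (children / young adults / elders, 15
subjects per group, 60 s at 250 Hz) plants the qualitative effects the
pipeline should detect: children have 2× theta power; alpha/beta
within-network correlations are 0.1 in children vs 0.5 in adults
(background 0.05 vs 0.2); the V1–V1 beta correlation is 0.2 in children,
0.8 in young adults, 0.2 in elders; hidden states are one per network
(envelope gain 0.8, visual state 1.2) with 0.30 s mean dwell except the
elders' visual state at 0.12 s. Recording length and rate are config
options; 60 s at 250 Hz keeps a full three-group run at desk scale (the
reference analyses used minutes-long recordings at 1 kHz, which the
generator also supports). No quantitative effect sizes are claimed for any
real cohort: the defaults are chosen for detectability at n = 15/group.

What the generator does *not* emulate: sensor-level physics and noise
floors, 1/f background spectra, non-stationary artifacts, inter-subject
anatomical variability, and volume-conduction geometry beyond a fixed real
mixing matrix. Passing tests therefore demonstrate that the *estimators and
statistics* behave as specified under their own assumptions — not that any
particular real-data effect size would replicate.

## Problem sizes used in validation

The packaged tests and the acceptance script validate at these scales,
chosen as the smallest that leave comfortable statistical margins: leakage
nulling over 20 seeds × 300 s pairs; HMM recovery on 12 000-sample chains
with 2–8 planted states; type-I error over 5000 null features at
n = 30/group; and the full pipeline on the default 45-subject cohort. The
end-to-end run is the dominant cost (minutes, single core), almost entirely
in the per-subject, per-band connectome stage.

## Known limitations

* Pairwise orthogonalization leaves ghost interactions; only monotone
  recovery of planted correlations is guaranteed, not unbiasedness.
* The EM-fitted HMM provides point estimates only; no uncertainty on state
  parameters or on Viterbi paths is propagated into the group tests.
* With non-integer `fs × step` the windowed downsampler floors window start
  indices, so the realized output grid jitters by up to one input sample
  around the nominal 25-ms spacing (exact at 1000 Hz and 200 Hz; ±2 ms at
  250 Hz).
* The state-power partial-correlation formulation is one of several
  possible conventions; alternatives (e.g. correlating against occupancy-
  weighted contrasts) would differ in scale though not in sign structure.
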