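---
title: "Methods: glucocorticoid-integrated step-selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucocorticoid-integrated step-selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortmove)
```

## The scientific problem

Glucocorticoids regulate foraging: elevated levels stimulate hunger and
should push an animal toward its best foraging habitat, and the effect
should strengthen when energy demands rise, as they do for a female elk
nursing a growing calf. `cortmove` implements the full observational
pipeline needed to test this under natural conditions with GPS-collared
animals and non-invasively collected fecal samples:

1. estimate unobserved calving dates from recursive movement;
2. assign anonymously collected fecal glucocorticoid metabolite (FGM)
   samples to collared individuals, with an auditable screening ledger;
3. cut each accepted sample's hormone-integration window into a movement
   bout and fit an integrated step-selection analysis (iSSA) in which
   selection for foraging habitat interacts with the FGM level;
4. express effects as relative selection strength (RSS) and validate the
   fit with used-habitat calibration (UHC);
5. test for a mean FGM shift across calving with a hierarchical model.

A synthetic-data generator with a complete truth record makes every stage
testable end to end without any field data.

## The selection model

Each GPS fix-to-fix displacement is a *step*. A used step is compared
with $K$ *available* steps sharing its start point and previous bearing,
drawn from movement kernels fitted to the used steps: step length
$\ell \sim \mathrm{Gamma}(k, \theta)$ and turn angle
$\phi \sim \mathrm{vonMises}(\mu, \kappa)$. (We model lengths with the
gamma and angles with the von Mises throughout; a circular distribution
cannot describe a positive length.) The conditional likelihood of the
used step in stratum $s$ with covariates $x$ is

$$\mathcal{L}(\beta) = \sum_s \left[\beta^\top x_{us} -
  \log \sum_{j \in s} \exp(\beta^\top x_{js})\right],$$

the matched conditional-logistic (case-control) likelihood. `fit_ssf()`
maximizes it directly (`mode = "clogit"`) or through the exactly
equivalent Poisson reformulation with one free intercept per stratum
(`mode = "poisson_trick"`); the test suite checks both routes against a
brute-force optimizer of the likelihood above.

The design contains four terms, all in 100-m distance units:

* `dist_end` — distance to cover (forest/shrubland) at the step end.
  Negative selection means the animal stays near cover; positive values
  of the interactions below mean that elevated glucocorticoids push
  steps *away* from cover, i.e. into cropland, the main forage source.
* `dist_fgm` — `dist_end` times the standardized FGM level of the bout.
* `dist_fgm_period` — additionally times the post-calving indicator.
* `dist_fgm_days` — additionally times days since calving.

FGM level, period, and days since calving are constant within a bout, so
only their interactions with the step-varying distance are estimable;
this is what lets a stratified design measure a hormone effect at all.

### Bouts and the 20-h window

FGMs integrate circulating glucocorticoids over roughly the 20 h before
defecation, so `make_bouts()` restricts each sample's GPS data to the
half-open window (deposition − 20 h, deposition]. Bouts with fewer than
3 fixes cannot define a turn angle and are excluded (kept in an
`excluded` attribute so screening ledgers can report them). FGM
concentrations are standardized (mean 0, SD 1, sample-SD denominator)
across the accepted samples; every hormone coefficient is per one SD of
concentration. A sample deposited on its individual's calving date is
post-calving with `days_since = 0`.

### Units, defaults, and numerical choices

* Distance to cover is measured in units of 100 m so coefficients are
  O(1); "200 m from cover" is `dist = 2`.
* $K = 40$ available steps per used step is the default analysis ratio;
  `ratio_sensitivity()` exposes a ladder over $K \in [1, 1000]$. The
  ladder uses *nested* availability draws (one $K_{\max}$ sample per
  used step; smaller ratios reuse its first $K$ draws), a common-random-
  numbers design that isolates the effect of the ratio from independent
  resampling noise.
* Zero-length steps are floored at 1 m before the gamma fit.
* The von Mises MLE inverts $A_1(\kappa) = I_1/I_0$ with a bracketed
  root search; numerically degenerate samples (all angles equal) cap
  $\hat\kappa$ at $10^5$.
* Wald 95% intervals ($\hat\beta \pm 1.96\,\mathrm{SE}$) from the
  observed information, reported on the $\exp(\beta)$ scale as well.
* Complete separation is flagged as non-convergence; rank-deficient
  designs error, naming the collinear columns.
* The Poisson route keeps a dense stratum-intercept GLM and therefore
  guards against more than 3000 strata; use `clogit` beyond that.

Random effects (bout intercepts, individual slopes) are deliberately not
part of the default fit: at desk scale the mixed conditional model is
only weakly identifiable, and the scientific targets are the fixed
effects. The Poisson reformulation is the standard route to add them
(e.g. via `glmmTMB` with the stratum-intercept variance fixed large) for
users who need them.

## Relative selection strength

`log_rss(fit, x1, x2)` is the exact contrast
$\hat\beta^\top(x_1 - x_2)$: the log of the relative probability of
choosing location $x_1$ over $x_2$ when both are available.
`rss_curve()` evaluates it for "in cover" (0 m) versus "200 m from
cover" across the 0.2–0.8 population quantile range of FGM
concentrations, with panels by calving period (days fixed at 0) and by
days since calving (period fixed post-calving). Uncertainty is a
parametric bootstrap: draws of $\beta \sim \mathrm{MVN}(\hat\beta, V)$
and percentile 2.5/97.5 bands. We bootstrap coefficients rather than
data because the stratified design leaves no exchangeable unit smaller
than the bout, and the coefficient bootstrap converges to the analytic
normal interval for a linear contrast (checked in the tests at
$10^5$ draws). Non-PSD covariance matrices are repaired by eigenvalue
clipping, with a warning.

## Used-habitat calibration

`uhc_validate()` splits the data by bout (never by step: strata within a
bout share a trajectory), refits on the training half, then simulates
"predicted used" steps: for each of `n_sims` draws of
$\beta \sim \mathrm{MVN}(\hat\beta, V)$ it samples one step from every
test stratum's choice set with probability $\propto \exp(\beta^\top x)$
(a Gumbel-max draw) and accumulates the kernel density of the covariate
at the sampled steps. Densities are Gaussian-kernel estimates with
Silverman's bandwidth on a fixed 512-point grid, renormalized to
integrate to 1 by the trapezoid rule. The 2.5–97.5% pointwise band is
the calibration envelope; `coverage` is the fraction of grid points
where the observed used-density lies inside it. A model fitted to data
generated from itself should achieve roughly nominal coverage; dropping
the distance-by-FGM interaction from interaction-generated data
visibly degrades it.

## Calving-date detection

Elk calves hide for about five days after birth and their mothers
repeatedly return to them. `count_revisits()` counts distinct entries
of the track into a 300-m buffer around every fix (a revisit is a
maximal time-contiguous run of in-buffer fixes; the run containing the
fix itself counts once). The per-fix feature set is: revisit count,
mean step length and net displacement *rate* in a centred 24-h window
(a rate, m/h, so truncated windows at the track ends remain
comparable), and hour of day. A balanced, seeded down-sample of fixes
inside/outside the known 5-day event windows trains a probability
random forest (100 trees by default; the classifier is a pluggable
`fit`/`predict_prob` pair).

The detection threshold is the mean predicted probability of the fixes
inside observed events. We compute those probabilities
leave-one-event-out (each event scored by a forest trained on the other
events) because the threshold's job is to anticipate how an *unseen*
event scores; resubstitution pushes the threshold to ~1 on separable
data and silently destroys sensitivity. With a single training event the
out-of-bag forest probabilities are used instead.

Detection repeats training `n_repeats` times (default 100; repeats
differ only in the down-sampling and forest seeds), averages the per-fix
probabilities across repeats, and slides a 5-day window fix-by-fix
(ties broken by the earliest start). The best window above threshold is
the event; its first date is the calving date; the spread of per-repeat
best dates is reported as a precision diagnostic. Windows are required
to fit entirely inside the track.

## Sample screening

Samples identified by fecal DNA bypass scoring. Every other sample is
scored against its suspected individual: the scorer is run 500 times
with derived seeds and the sample is accepted when the mean predicted
accuracy reaches the 0.77 threshold. Failures go to candidate
reassignment: individuals with any fix within 20 m of the sample up to
2 d before collection (both boundaries closed) are evaluated in
descending order of qualifying fix count, ties resolved by the highest
mean accuracy, and the first candidate meeting the threshold recovers
the sample. Per-sample seeds are derived from the sample id, so
screening is order-independent, and each (sample, candidate) pair is
scored with its own seed stream. The bundled scorer is a minimal
logistic proximity/recency model intended as a stand-in for a full
movement-based identity model; any replacement needs only a
`predict(sample, track, seed)` function. The `screening_ledger()`
enforces the stage-count identities (candidates = collected − DNA;
accepted ML = candidates − failures + recoveries; and so on) so the
analysis sample sizes are always reproducible from the stage counts.

## Pre/post-calving hormone model

`fit_prepost()` models standardized FGM on the calving period and year
with a random intercept per individual. The likelihood engine is a REML
linear mixed model with Wald intervals; the MCMC engine is the Bayesian
analogue fitted by Gibbs sampling with normal(0, 1) slope priors,
4 chains and 10,000 iterations including 5,000 warmup, reporting
posterior medians and 95% quantile intervals. On well-conditioned data
the engines agree in sign and closely in location; the tests assert
agreement within 0.1 SD. Samples from individual-years with no calving
record have no period and are dropped with a message.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 13 collared
females, two May–August seasons, 30-min fixes, calving dates uniform in
late May–June, about 20% DNA identification success, and FGM
concentrations from a Gaussian hierarchy (population mean 1900 ug/g,
between-individual SD 400, within-individual SD 730). Only the target
quantile range — pooled 0.2/0.8 quantiles near 1,200–2,600 ug/g — is a
property of the emulated population; the mean and the split between
between- and within-individual variance are the package's own
calibration choice to honour that range, fixed once and not revisited.
Movement follows the selection model: at each step the animal draws
`n_candidates` candidate steps from the kernels and picks one with
probability $\propto \exp(b\,d/100)$, where the bout-level coefficient
$b$ combines the configured `betas` with the sample's standardized FGM,
period, and days since calving. During the 5-day hiding window in
season mode, mean step length is multiplied by the suppression factor
(default 0.2) and candidates are pulled toward the calving site; the
attraction strength is a configuration knob (default 2 per 100 m).
The deposition-to-collection lag is uniform on [0, 24] h. Coordinates
are projected metres on a local grid; there is no geographic CRS
handling.

Two fidelity decisions matter for interpretation:

* **Candidate-set fidelity.** The discrete candidate set approximates
  the continuous selection density from below; with `n_candidates = 50`
  we measured a residual discretization bias of a few tenths of a
  standard error in refitted coefficients at study scale, which is
  immaterial for qualitative behaviour but not for coverage
  experiments. Parameter-recovery and CI-coverage runs therefore use
  `n_candidates = 200`, where the bias is below Monte-Carlo resolution;
  the general default stays at 50 for season-long simulations.
* **Bout mode is model-faithful.** In `mode = "bouts"` (the data the
  selection model consumes) movement is generated exactly from the
  step-selection model; calving dates enter only through the
  covariates. Hiding kinematics are an *unmodeled* behaviour from the
  fitted model's point of view, and including them in a recovery
  experiment contaminates the estimand. `mode = "season"` keeps the
  full hiding behaviour and is what the calving detector is trained
  and tested on.

What the generator does **not** emulate: real land-cover geometry,
temporally autocorrelated hormone trajectories, FGM degradation in the
field, herd sociality, predation, or collar fix failures. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every field artefact.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run: 100 (tests) / 40 (script)
recovery replicates at 13 individuals × 2 seasons × 3 samples
(~75 bouts, ~2,900 strata, K = 40); a 16-individual single-season
landscape for calving detection with 20 detector repeats; availability
ladders up to K = 100; $10^5$ bootstrap draws for the RSS interval
check; and 60–100 replicates for the hormone-model null-coverage check.
These sizes were chosen to keep each experiment's Monte-Carlo error
well inside the tolerance it is compared against.

## Known limitations

* The fixed-effects fit ignores within-bout serial dependence between
  strata; our replicate diagnostics show the resulting intervals are
  close to nominal under the generator, but strongly autocorrelated
  real landscapes may need bout-level cluster-robust variances.
* The Poisson route is dense and memory-bound beyond a few thousand
  strata.
* The default identity scorer is intentionally minimal; screening
  conclusions on real data should use a purpose-built identity model.
* The MCMC engine targets interval-level agreement with the likelihood
  engine, not numerical equality with any particular sampler.
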