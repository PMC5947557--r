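---
title: "Models and methods in sociocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sociocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociocc)
```

`sociocc` couples three statistical tools that together let a study
contrast habitat-driven and persecution-driven explanations for a
carnivore's occupancy dynamics: a multiseason occupancy model with staged
AIC selection over covariate structures, a forced-response
randomised-response (RRT) analysis of an illegal behaviour, and a spatial
autocorrelation screen. This vignette documents the models, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The multiseason occupancy model

Each sample unit (SU) $i$ has a latent occupancy state $z_{it} \in \{0,1\}$
in season $t$. The state process is first-order Markov:

$$z_{i1} \sim \mathrm{Bern}(\psi_{1,i}), \qquad
  z_{i,t+1} \mid z_{it} \sim \mathrm{Bern}\!\left(z_{it}(1-\epsilon_{it}) +
  (1-z_{it})\gamma_{it}\right),$$

with local extinction $\epsilon$ and colonisation $\gamma$. Detections
$y_{itj}$ on occasion $j$ are conditionally independent
$\mathrm{Bern}(p_{it} z_{it})$. Every probability is modelled on the logit
scale; season-specific parameters are separate intercepts (one per
between-season interval for $\epsilon,\gamma$, one per season for $p$) with
covariate effects additive on the logit scale, mirroring the
`p(season+understorey)` notation used in occupancy software.

The likelihood marginalises $z$ with a two-state forward recursion. Because
$p$ is constant across occasions within a site-season, the per-season
emission depends on the data only through the number of detections $d$ and
of non-missing occasions $J$; a season with every occasion missing has
$J=0$ and contributes a factor of 1 in both states, which is exactly how an
unsurveyed season (e.g. one zone joining the study a season late) drops out
of the likelihood.

Five base dynamics structures are supported: seasonal and constant Markov;
an equilibrium model with $\epsilon$ derived as $\gamma(1-\psi)/\psi$ (so
occupancy is stationary); random changes with $\epsilon = 1-\gamma$ (season
$t{+}1$ occupancy is $\gamma$ regardless of the previous state); and a
static model with $\gamma=\epsilon=0$. Parameter counts $K$ — the AIC
penalty — follow directly from the free blocks; note the static model with
seasonal detection counts $K = 1 + T$, the rule-based count, even though
some published tables print one more.

### Fitting and numerical choices

* **Link and clipping.** Logit link throughout; linear predictors are
  clipped to $\pm 35$ before the inverse logit so the likelihood is finite
  for any optimizer proposal. The derived equilibrium $\epsilon$ is clipped
  to $[10^{-12}, 1-10^{-12}]$ (the constraint can otherwise exceed 1 for
  small $\psi$); the gradient is zeroed on the clipped set.
* **Optimisation.** BFGS with exact analytic gradients from scaled
  forward–backward recursions (verified against central differences in the
  test suite), 10 jittered starts by default. The first start is a
  deterministic naive initialisation (logits of the raw season-1 occupancy
  and overall detection rate, zero slopes); subsequent starts add N(0,1)
  jitter. During model selection, candidate fits are warm-started from the
  carried-forward structure's estimates, and one start suffices in
  practice.
* **Standard errors** come from inverting a central-difference Hessian at
  the optimum (no external differentiation package is required). A
  singular or non-positive Hessian propagates `converged = FALSE`.
* **Implausibility rule.** Candidate models with $|\beta| > 15$ or
  $SE > 25$ on the logit scale are dropped from selection stages with the
  reason recorded. The literature describes this screen only qualitatively
  ("very large estimates and SEs"); the thresholds are configurable in
  `selection_control()`.
* **Unequal season spacing** is absorbed by the season-specific
  $\epsilon/\gamma$ intercepts, not by time-scaling.

### Staged forward selection

`stepwise_search()` reproduces the step-forward protocol: (1) compare the
base dynamics structures; (2) add detection covariates to $p$; (3) add an
initial-occupancy covariate (plus one configured additive exception —
core habitat plus marginal habitat); (4) extinction then colonisation, and
the reverse order; (5) a final stage that combines extinction predictors.
Models within 2 AIC of a stage's best (strictly `< 2`) count as supported.
Design choices the protocol leaves open, resolved here:

* The covariate stages always use the explicit seasonal Markov
  parameterisation even if a constrained structure (often the equilibrium
  model, which spends fewer parameters) edges it on AIC in stage 1: only
  the explicit parameterisation lets predictors act on both population
  processes. The ledger records the stage-1 ranking and this note.
* After the detection and initial-occupancy stages the AIC-best supported
  structure is carried forward; within the extinction/colonisation stages
  *every* supported structure is carried (both orders are run and the
  final stage operates over their union).
* The final combination merges the predictors of the top two competing
  single-predictor extinction models, provided each improves on the
  extinction-null model's AIC. Two genuine extinction effects usually split
  across the two top single-predictor models with an AIC gap well beyond 2
  (the gap between them reflects the *difference* of two explained
  deviances, which is noisy), so a kept-set-only combination rule would
  almost never form the combined model; conditioning on "top two that beat
  the null" recovers two-covariate truths reliably while the final AIC
  ranking still discards spurious combinations.
* Ties in AIC rank by smaller $K$, then label order; per-fit seeds derive
  from one root seed so ledgers are reproducible.

### Goodness of fit

`mb_gof()` implements a parametric-bootstrap Pearson test on
detection-history frequencies. For each season, sites are grouped into
cohorts sharing a missingness pattern; the expected count of history $h$
with $d$ detections over $J$ observed occasions is
$\sum_i [\psi_{it} p_{it}^d (1-p_{it})^{J-d} + (1-\psi_{it})\,1\{d=0\}]$,
with $\psi_{it}$ the marginal occupancy from the fitted dynamics. The exact
form of the seasonal statistic for a multiseason model is not fully
pinned down in the literature (it lives inside closed-source software);
the construction above is this package's definition and is documented as
such. Never-observed histories contribute through a catch-all cell, and
observed cells with expected count below 0.5 are pooled into it (standard
sparse-cell practice). The global statistic sums the seasons; bootstrap
replicates simulate from the fitted model with the observed missingness
pattern, refit (warm-started), and the p-value is the inclusive proportion
of replicates at or above the observed statistic. Refits that fail fall
back to the generating estimates so a replicate still contributes; more
than 10% failures records a warning in the result.

## Forced-response RRT analysis

In a forced-response design with forcing probabilities $p_{fy}, p_{fn}$,
the observed yes-probability is
$\lambda = p_{fy} + (1 - p_{fy} - p_{fn})\,\pi$, inverted by
`rrt_prevalence()`. The raw estimate is reported unclipped (a yes-rate
below the forcing floor legitimately produces a negative point estimate in
small samples) together with a clipped companion. The default design is
symmetric 1/6–1/6: the study this emulates reports only a forcing
probability of 0.167 and that both answers were prescribed, so the
symmetric-die assumption is documented here rather than asserted as the
study's device.

`rrt_logistic()` maximises the likelihood with
$q_i = p_{fy} + (1 - p_{fy} - p_{fn})\,\mathrm{logit}^{-1}(x_i'\beta)$,
reducing exactly to ordinary logistic regression when both forcing
probabilities are zero (cross-checked against `glm` in the tests).
Separation — the typical failure mode when a near-deterministic predictor
meets a rare behaviour — is flagged at $|\beta| > 10$ and such predictors
should be excluded and the model refitted. Confidence intervals for the
prevalence use respondent-level percentile bootstrap (1,000 draws by
default, no BCa correction: nothing in the emulated design motivates one);
predictor significance uses likelihood-ratio tests
($\Delta G^2 = 2\,\Delta\ell$, chi-square with the difference in parameter
counts) and effect sizes are odds ratios $e^\beta$ with Wald intervals.

## Moran's I screen

`moran_test()` uses binary weights within a fixed distance band (default
3000 m — about three home ranges for a small felid, so neighbouring SU
centres fall inside it) rather than row-standardised weights; the
fixed-band phrasing of the emulated protocol motivates the binary choice.
The per-site value fed to the test is the proportion of non-missing
occasions with a detection in a season (`detection_rates()`); the emulated
study says only "detection/non-detection data", so this summary is the
package's documented definition. Significance comes from a two-sided
permutation test (999 permutations, observed value included in the null
set) with the normal-approximation p-value reported for reference.

## The synthetic-data generator

`scenario_config()` encodes the stated world of the emulated study:
145 SUs (73 central-valley units surveyed in seasons 2–4 only, 72 Andean
units surveyed all four seasons), 10–12 two-day occasions per SU per
season from pooled camera pairs, a 3% occasion-level missingness rate
standing in for camera malfunctions and thefts, 233 questionnaire
respondents (one household per SU, a second where needed), and a latent
killing prevalence of 10% under the symmetric 1/6 forcing design.

Continuous landscape covariates are truncated normals matching printed
moments and ranges (forest 27.5 ± 18.9% in [1.8, 76]; shrub 26 ± 8.3% in
[9.1, 53.1]; patches 52.9 ± 25.7 in [14, 163]; subdivision 41.3 ± 37.2 in
[1, 314]; patch shape 3.13 ± 1.3 in [1.3, 7.8]); integer covariates are
rounded after truncation. Values with no printed distribution are chosen
once as field-realistic and fixed: edge length mean 20 km within the
printed [4.755, 48] km range; dog counts Poisson(2); income lognormal
around US$400/month; ordinal understorey/bamboo on four levels (the
source's supplementary scales are not in the main text, so the 4-level
coding is an assumption); encounter frequency on a 0–3 scale with
marginals 51/28/11/10% reproducing the printed 49% lifetime / 21% decade /
10% recent sighting rates. Redundant fragmentation metrics (cohesion,
weighted patch area, gyration tracking forest; landscape shape index
tracking patch number) are generated deliberately collinear so the
collinearity screen (`collinearity_screen()`, flagged at
max(|Pearson|, |Spearman|) > 0.7, priority-ranked retention) has realistic
work to do.

The generating occupancy truth follows the final-model structure of the
emulated study — initial occupancy declining weakly with forest cover on
the raw percentage scale (slope −0.0363 per point, ~0.78 at the mean),
season-specific extinction around 0.2 decreasing with patch number (−0.90
per SD) and increasing with subdivision (+0.944 per SD), season-specific
colonisation around 0.4, detection around 0.15 per two-day occasion rising
with understorey (+0.343 per SD). Percentages stay on their natural scale
and all other covariates are z-scored before the truth is applied, the
same convention the analysis uses (`standardise_covariates()` with sample
(n−1) standard deviations, matching mainstream statistical software).

The questionnaire generator links the latent behaviour to z-scored
encounter frequency with log-odds 0.85 by default, calibrating the
intercept numerically so the population prevalence hits the configured
value; its `true_kill` column is synthetic truth retained for validation.

What the generator does **not** emulate: spatially autocorrelated
covariate fields or detection (sites are exchangeable given covariates, so
a green Moran test on generated data checks the test's null behaviour, not
its power); observer effects or questionnaire non-response; rasters and
the patch-metric computations behind the landscape covariates (treated as
given). A green end-to-end test therefore establishes that the estimators
are correct under the stated model, not that the model is right for any
particular field system.

## Scaling choices in the test suite

Simulation-based checks are scaled to run on one CPU within a CI budget:
selection-consistency and null-retention use 20 replicates at 500 and 300
sites with a reduced predictor catalog (the generating covariates plus
decoys); bootstrap-calibration uses 20 replicates of 200 bootstrap
iterations at 60 sites; the chi-square calibration of the RRT
likelihood-ratio test uses 400 null replicates. One property of the kept
rule is worth noting explicitly: each null-vs-one-predictor comparison
falsely drops the baseline with probability
$P(\chi^2_1 > 4) \approx 4.6\%$, so baseline retention can only be
expected at the nominal rate for the first-order stages; later stages
condition on carried-forward structures and compound those errors, which
is an inherent cost of forward selection rather than a defect of the
implementation. Production analyses should
use the documented defaults (5,000 GOF iterations, 1,000 bootstrap
resamples, 10 optimisation starts).

## Known limitations

* No spatially explicit (autologistic) occupancy, multi-species structure
  or Bayesian fitting; AIC only (no AICc/QAIC re-ranking — the emulated
  protocol did not apply the overdispersion correction).
* The RRT module covers the forced-response design only.
* The delta-method intervals for derived occupancy and prediction curves
  are normal approximations on the linear scale; they can be optimistic in
  small samples near the boundary.
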