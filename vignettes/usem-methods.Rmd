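---
title: "Unified SEM for effective connectivity: models, search and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified SEM for effective connectivity: models, search and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usemr)
```

## The modelling problem

Correlation between two regional time series says nothing about direction.
Effective-connectivity analysis asks a stronger question: which region
drives which, instantaneously and across time. The unified SEM (uSEM)
answers it by representing each of R regions with two observed variables —
the current standardized series and its one-volume-delayed copy — and
estimating a directed path model over all 2R variables at once. Three path
kinds exist:

* **autoregressive** `lag-X -> X`: each region's dependence on its own past,
  present in every model from the start (fMRI series are strongly
  autocorrelated, and omitting these terms would push that autocorrelation
  into spurious cross paths);
* **contemporaneous** `A -> B`: a directed within-volume effect;
* **longitudinal** `lag-A -> B`: a directed effect across adjacent volumes.

In matrix form, with `x_t` the current vector,

$$x_t = B x_t + \Phi x_{t-1} + e_t, \qquad e_t \sim N(0, \mathrm{diag}(\psi)),$$

so the generative (reduced) form is
$x_t = (I-B)^{-1}(\Phi x_{t-1} + e_t)$ — exactly what `simulate_usem()`
draws from. Fitting and simulation are inverse operations by construction,
which is what makes the parameter-recovery and search-recovery tests
meaningful.

## Data preparation

`standardize_panel()` normalizes every subject's every ROI series to mean 0
and variance 1. The variance uses the population denominator `N`, so the
postcondition is exact and testable; either denominator convention is
accepted downstream (the check in `lag_embed()` allows a small variance
band). `lag_embed()` then pairs volume *t* with volume *t − 1* strictly
within subject — the first volume of one subject is never paired with the
last of another — and pools the rows of all subjects, giving
`N_effective = sum(T_s - 1)` rows and the pooled covariance `S` (denominator
`N_effective − 1`, the common SEM-software convention; the chi-square then
uses `N − 1` with `N = N_effective`).

Pooling rows, rather than averaging per-subject covariance matrices, is the
default because it weighs subjects by their usable volumes and keeps `S`
positive-definite under mild conditions; per-subject matrices remain
accessible in the panel for anyone preferring the other convention, and
`lagged_dataset_from_cov()` accepts any externally computed covariance.

## Estimation

`usem()` minimizes the ML discrepancy
$F_{ML} = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \ln|S| - 2R$
with $\Sigma(\theta) = (I-A)^{-1}\Psi(I-A)^{-\top}$ in reticular-action
form (`A` = path coefficients, `Psi` = residual variances of current
variables plus the free lag-block covariances; no current–lag residual
coupling).

Numerical choices:

* **Lag block concentrated out.** Because `Psi` has no current–lag
  coupling, the Gaussian likelihood factorizes into a marginal term for the
  lag variables and a conditional term for the current ones; the saturated
  lag-block ML estimate is therefore the sample lag block itself,
  regardless of the path parameters. The optimizer runs only over path
  coefficients and log residual variances. The lag block still counts
  R(R+1)/2 free parameters in the degrees of freedom:
  `df = p(p+1)/2 - (paths + R + R(R+1)/2)`, `p = 2R`. Published dof values
  for this family of analyses vary with exactly this convention, so it is
  stated rather than treated as a reproduction target.
* **Start values** come from per-equation least squares on `S`, which is
  already the ML solution for recursive systems; BFGS with the analytic
  gradient (`grad_A F = 2 E^T G \Sigma` with `G = \Sigma^{-1}(\Sigma-S)\Sigma^{-1}`,
  `E = (I-A)^{-1}`) then handles non-recursive structures. Relative
  objective tolerance 1e-10, at most 500 iterations; the `converged` flag
  additionally requires a gradient norm below 1e-4 and is reported, never
  silently ignored.
* **Restart stability**: jittered starts reach the same optimum within
  1e-6 on the test models (a unit test enforces this).
* **Degenerate input**: a pooled covariance with condition number above
  1e12 is refused with advice to use more rows or fewer ROIs — silent
  near-singular fits would corrupt every downstream index.
* Variances are optimized on the log scale, so they stay positive without
  constraints.

## Fit indices

Four descriptive measures are reported per fit, all derived from one
chi-square (`(N-1) F_ML`) and one implied covariance, so they are mutually
consistent by construction:

* **RMSEA** `sqrt(max(chi2 - df, 0) / (df (N-1)))`; the search's primary
  criterion because of its insensitivity to sample size. 0.05–0.08 is the
  conventional acceptable band; the search stops at the 0.08 edge
  (configurable via `rmsea_target`) rather than continuing toward 0.05 —
  the band gives a satisficing criterion, not an optimization target.
  `rmsea()` is undefined at df = 0; inside fit objects a saturated model
  with chi-square 0 reports 0 (perfect reproduction).
* **TLI** against the null-model baseline (autoregressive paths only) —
  the explicitly defined starting model of the search, not the
  pure-independence model, which would not even be meaningful here since
  lag copies of autocorrelated series are never uncorrelated with their
  sources. TLI is clipped to [0, 1]: unclipped it exceeds 1 at perfect
  fit, and the reported range runs from 0 (no fit) to 1 (perfect fit).
  A df = 0, chi-square = 0 model is treated as a perfect fit (ratio 0,
  TLI 1); df = 0 with positive chi-square errors.
* **GFI**, ML form `1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`,
  clipped to [0, 1], scale-invariant.
* Values of 0.95 or greater on TLI/GFI are read as a good model; the
  acceptance suite verifies that well-specified fits at study scale reach
  this level in ≥ 90% of replicates.

## Exploratory model search

`usem_search()` grows the model from the null model one *connection* at a
time; a connection is an ordered region pair `A -> B` contributing both the
contemporaneous path and the longitudinal path `lag-A -> B` (df drops by
exactly 2 per step). Candidate scoring is two-stage:

1. **Modification indices** (`modification_indices()`): score-test
   approximations of the chi-square drop from freeing one fixed path,
   using the expected information and a Schur complement over all free
   parameters. They are cheap (no refitting) and, at T = 2000 on 4-ROI
   models, track exact refit drops to within 25% (an acceptance test).
   The two MIs of a connection are summed; summing (rather than taking
   the maximum) favors pairs with support on both time scales, and either
   convention selects the same pair in the overwhelming majority of seeds.
2. The top 5 pairs by summed MI are actually added and refit; the realized
   RMSEA decides. Ties resolve to the lexicographically first pair, making
   the whole search deterministic — two runs on the same dataset produce
   identical traces (tested).

The loop stops when RMSEA enters the band, no candidate improves it, or a
step cap of 3R connections is hit (a guard against pathological inputs,
far above anything the band criterion allows in practice). Pruning then
removes, in reverse order of addition and repeating to a fixed point, every
non-autoregressive path whose removal leaves RMSEA equal or lower —
removing a path raises chi-square but also df, so genuinely useless paths
lower RMSEA when dropped. Pruning is idempotent, and autoregressive paths
are never candidates in either direction: lag variables are exogenous
copies, so into-lag and lag-to-lag paths are structurally excluded.

## Group comparison

Given best-fit models for two groups:

* **Reversed-model cross-fits** (`cross_fit()`): each model re-estimated,
  structure fixed, on the other group's data. Comparable indices indicate
  no gross network difference.
* **Hybrid model** (`build_hybrid()`): the union of both path sets, so the
  same structure can be estimated on both datasets.
* **Joint fit** (`fit_joint()`): two-group ML minimizing
  `sum_g (N_g - 1) F_g`; unconstrained parameters are group-specific,
  constrained paths share one coefficient. With no constraints the
  problem separates and the total chi-square is exactly the sum of the
  separate fits (a tested identity). The joint RMSEA uses the total
  chi-square, total df and total N.
* **Per-path tests** (`compare_all_paths()`): each hybrid path in turn is
  equality-constrained; the chi-square increase over the unconstrained
  joint fit is a 1-df likelihood-ratio statistic. Default alpha 0.05 with
  no multiplicity correction — raw p-values are emitted so any correction
  can be applied downstream. A non-converging constrained fit marks that
  path untestable (`NA`) and the run continues.

"Joint data" is deliberately implemented as a two-group SEM rather than
physical row concatenation: concatenating rows from two populations mixes
between-group covariance differences into every moment, so a path-equality
test on pooled rows would confound path differences with everything else.
`concat_datasets()` exists for fidelity experiments with the pooled-rows
convention.

A calibration property justifies treating the equality statistic as
chi-square(1) even though lag-embedded rows are serially dependent: the
SEM pseudo-likelihood of the row set equals the true conditional (Markov)
likelihood of the series plus a term involving only the saturated lag
block, which cancels in every likelihood-ratio difference between models
sharing that block. Standard conditional-ML asymptotics then apply. The
acceptance suite confirms the implied 5% null rejection rate empirically
(0.05 ± 0.02 over 500 replicates).

## ROI extraction

For volume inputs, the selection rules are: voxel-level threshold
z ≥ 2.3, connected-component clustering, extent filter of 15 voxels,
a 5 mm diameter sphere at each surviving cluster's peak, mean series over
the sphere, then standardization. Choices the thresholding literature
leaves open are fixed as:

* **6-connectivity** (faces only) — the conservative default; 18/26
  available as options;
* **peak ties** go to the first voxel in ascending scan order
  (deterministic);
* **sphere membership** by voxel-center distance (with 5 mm diameter on
  common fMRI grids this reduces to one or a handful of voxels);
* random-field cluster-level correction is **not** reimplemented; the
  voxel threshold plus extent rule is the documented approximation, and
  corrected statistic maps produced elsewhere can be supplied directly.

`make_synthetic_volume()` plants panel series inside spheres with optional
Gaussian noise and emits a z-map whose blobs peak exactly at the planted
centers, so the whole chain is testable: on noise-free volumes,
threshold → cluster → sphere → extract → standardize returns the planted
series exactly.

## What the simulator does and does not emulate

`usem_sim_spec()` / `simulate_usem()` generate stationary multivariate
series with known contemporaneous and lag-1 directed effects, Gaussian
innovations, independent subjects, and a burn-in of 50 discarded samples so
the retained series is effectively stationary. The defaults — 14 subjects,
150 volumes, autoregressive effects 0.35, cross coefficients 0.4–0.6 in
`planted_network_spec()` — are the scale at which the recovery experiments
run. Gaussianity matches the distributional assumption already inside the
ML discrepancy; subjects are i.i.d. draws from one spec, and group
differences are modeled by giving each group its own spec.

Deliberately absent: hemodynamic-response convolution, physiological noise,
scanner drift, motion artifacts, and between-subject heterogeneity in the
true network. Passing recovery tests therefore demonstrate that the
estimator and search behave correctly *when the model family is true at
the study's scale* — they do not certify performance on real fMRI data,
where HRF smoothing attenuates lagged effects and subject heterogeneity
blurs group models. The oracle for the simulator itself is analytic:
`stationary_covariance()` solves the discrete-time Lyapunov equation of
the reduced-form VAR, and the simulated sample covariance must converge to
it (tested at 3 Monte-Carlo standard errors).

## Problem sizes in the test suite

The suite runs entirely on synthetic data generated at test time: recovery
and calibration experiments use 14 subjects × 150 volumes (N ≈ 2000 pooled
rows) on 3–6 ROI networks, oracle comparisons use single subjects at
T = 2000, and the simulator-convergence check uses T = 1e5. These sizes
were chosen to put sampling error well below the tested tolerances while
keeping the full suite in the low minutes on a single core.

## Known limitations

* Contemporaneous direction is identified only through the lagged
  structure; with purely contemporaneous truth and no lagged signal, the
  reversed direction can fit nearly as well, and the greedy search keeps
  whichever direction wins on RMSEA.
* Greedy stepwise search finds *a* well-fitting parsimonious model, not
  the global optimum; with correlated candidates the first steps shape
  later ones.
* One model per group: no subject-level heterogeneity in path sets or
  coefficients (no random effects, no individual-level search).
* The chi-square treats pooled rows via `N_effective`; between-subject
  variance beyond the modeled covariance is not propagated.
* Latent variables, mean structures and missing-data ML are out of scope.
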