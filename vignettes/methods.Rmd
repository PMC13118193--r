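---
title: "Models, simulation and statistical methods in dkiupgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation and statistical methods in dkiupgrade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkiupgrade)
```

# The signal models

Diffusion-weighted MRI probes water displacement: the signal at diffusion
weighting $b$ (s/mm²) decays from its unweighted value $S_0$. Two
orientation-averaged scalar models are implemented.

**Monoexponential (ADC).** $S(b) = S_0 e^{-b\,\mathrm{ADC}}$ assumes Gaussian
diffusion, so $\ln S$ is linear in $b$. In tissue this holds only up to about
$b \approx 1000\text{–}1200$ s/mm²; beyond that, restriction by membranes
makes the decay sub-exponential. The ADC fit therefore uses b-values up to
1200 s/mm² (configurable via `b_max`), including $b=0$.

**Diffusion kurtosis.** $S(b) = S_0 \exp(-b D_{app} + b^2 D_{app}^2 K / 6)$
is the two-parameter cumulant representation of non-Gaussian diffusion:
$D_{app}$ is the diffusivity corrected for non-Gaussian behaviour and the
dimensionless kurtosis $K \ge 0$ measures the excess of the displacement
distribution over a Gaussian. $K = 0$ recovers the monoexponential model
exactly. Dense, heterogeneous tumour tissue shows lower $D_{app}$/ADC and
higher $K$ than benign prostate — the contrast that the upgrade analysis
exploits.

Units: $b$ in s/mm²; diffusivities are carried on the conventional
$10^{-3}$ mm²/s scale in every interface and converted to mm²/s inside the
exponent. $S_0$ is in arbitrary scanner units and every fit is
scale-equivariant in it.

# Fitting

Because $\ln S$ is *exactly* quadratic in $b$ under the kurtosis model, the
reference algorithm is a closed-form degree-2 polynomial least-squares fit of
$\ln S$ on $b$: with $\ln S = c_0 + c_1 b + c_2 b^2$,

$$D_{app} = -c_1, \qquad K = 6 c_2 / c_1^2, \qquad S_0 = e^{c_0}.$$

This is exact on model data (the noiseless round-trip recovers parameters to
relative error $<10^{-8}$ over the whole plausible range, which the test
suite checks on a 1000-point grid), fully deterministic, and fast enough to
run voxelwise without compiled code: voxels whose six signals are all
positive are solved in one vectorised QR decomposition, the rest fall back to
a per-voxel fit on the usable subset. An optional bounded nonlinear
refinement (`refine = TRUE`, L-BFGS-B on the untransformed signal) is
available for users who prefer unweighted least squares on the linear scale;
on clean data the two agree and the refinement is kept only when it does not
worsen the objective.

Numerical choices, all surfaced rather than silent:

* **Constraints.** $D_{app} \in (0, 4]\times10^{-3}$ mm²/s and $K \in [0, 3]$
  (physiologically motivated bounds for prostate; configurable). Estimates
  beyond the bounds are clamped and the fit is marked `clamped`.
* **Failure, not fabrication.** A non-decaying log-signal ($c_1 \ge 0$) or
  fewer than 3 (kurtosis) / 2 (ADC) usable points invalidates the voxel; map
  voxels carry an explicit validity mask and are never silently zeroed.
* **Non-positive signals** (possible under simulated magnitude noise) are
  excluded from the log fit rather than floored at a small constant —
  flooring would bias the high-b tail — and their count is recorded per
  voxel.
* No spatial regularisation or smoothing is applied across voxels.

ROI statistics are unweighted arithmetic means over valid voxels;
`roi_stats_table()` uses the voxel set valid in *all* maps so that ADC,
$D_{app}$ and $K$ for one lesion always come from identical voxels, mirroring
how an ROI drawn on the ADC map is propagated to the other maps.

# The synthetic data

**Phantoms.** `generate_phantom()` builds piecewise-constant parameter fields
(ellipsoidal lesions in a uniform background), evaluates the kurtosis forward
model and adds Rician noise: two independent Gaussian quadrature channels of
standard deviation $\sigma = S_0/(\mathrm{SNR}\sqrt{n_{avg}})$ followed by a
magnitude operation. The $\sqrt{n_{avg}}$ factor models the five signal
averages of the default protocol; the test suite verifies the b = 0 noise
distribution against the noncentral-$\chi^2$ law implied by the Rician model.
Lesion ROIs are returned eroded by one voxel, emulating margin-avoiding ROI
placement. Defaults: a 24×24×6 grid at 2.2×2.2×3.5 mm, benign-like
background ($D_{app} = 1.8$, $K = 0.6$), one tumour-like lesion
($D_{app} = 0.914$, $K = 1.311$), SNR 50. Phantoms deliberately do *not*
emulate anatomy, partial-volume mixing, motion, eddy-current or ghosting
artefacts — so a passing recovery test demonstrates correctness of the
estimator under the stated noise model, not robustness to scanner physics.

**Cohorts.** `generate_cohort()` draws lesion records per biopsy-GG stratum
and arm (upgrade / no-upgrade) from independent normal distributions with the
packaged group moments (`default_group_moments()`), truncated at zero by
redraw (not clamped, keeping the shape near-normal). Variables are drawn
independently because no covariance structure is prescribed; real ADC, D and
K values are strongly correlated, so simulated multivariable analyses would
be optimistic — which is one reason the package evaluates predictors one at a
time. Arm sizes equal the largest per-variable n; clinical variables with a
smaller n are left `NA` for the remainder. The prostatectomy GG of a
simulated upgrade is one tier above the biopsy GG (capped at 5) — sufficient
for all bookkeeping, which depends only on the upgrade indicator.

**Reference table.** `fixture_lesion_table()` is a deterministic 142-lesion
table whose marginals (strata 27/67/35/13, prostatectomy GG 9/47/61/13/12,
per-stratum upgrades 20/36/8/4, zone 105/37, PI-RADS 4/71/67) anchor the
bookkeeping; the joint biopsy×prostatectomy completion is under-determined by
those marginals, so one consistent completion (including the few downgrades)
was fixed, and all row-level attributes beyond the marginals are synthetic.

# Group comparisons

Within each biopsy-GG stratum, each of K, D, ADC, PSA and PSAD is compared
between arms:

* **Test selection.** The either/or rule "t-test or Mann–Whitney U" needs an
  explicit criterion; we gate on per-arm Shapiro–Wilk normality at
  $\alpha = 0.05$ — both arms pass → Welch t-test, otherwise Mann–Whitney U,
  always two-sided. Arms with $n < 3$ (normality untestable) are flagged
  `skipped`; jointly constant arms are flagged `degenerate` with $p = 1$.
  Shapiro–Wilk is defined up to $n = 5000$; larger arms are gated on their
  first 5000 values (irrelevant at clinical cohort sizes).
* **Holm family.** The five variables within one stratum form one family of
  $m = 5$; this family size reproduces published per-stratum adjusted values
  exactly in the worked examples of the test suite. `holm_adjust()` delegates
  to `stats::p.adjust(method = "holm")` and is verified against a brute-force
  closed-testing oracle.
* **Effect size.** Classical pooled-SD Cohen's d, signed upgrade minus
  no-upgrade (positive for K, negative for ADC/D at the packaged moments).
  Reported effect sizes in the applied literature are not always computed
  with a stated formula; this package fixes the pooled form and reports it
  consistently rather than matching any unstated variant.

# Diagnostic performance

`cv_logistic_roc()` evaluates one predictor at a time by logistic regression
with 5 repeats of stratified 5-fold cross-validation (folds reduced with a
warning when the smaller class is too small). Design decisions where the
procedure admits more than one reading:

* **Aggregation.** Within each repeat the out-of-fold predicted
  probabilities are pooled into one ROC; the reported cross-validated AUC is
  the mean of the five per-repeat AUCs. The full-sample raw-predictor AUC is
  also emitted: for a single monotone predictor the logistic map preserves
  ranking, so the two agree to within sampling noise of the fold assignment
  (a tested invariant, ±0.01).
* **Confidence interval.** DeLong 95% CI computed on each lesion's
  out-of-fold score averaged across repeats (via pROC). A bootstrap CI would
  also be defensible; DeLong is deterministic given the scores.
* **Operating point.** The Youden index $J = \text{sens} + \text{spec} - 1$
  is maximised over all midpoints between adjacent distinct values of the
  *raw predictor* (thresholds are reported in predictor units, not on the
  probability scale, since a monotone logistic map makes them equivalent).
  Ties in $J$ resolve toward higher specificity, then deterministically
  toward the more conservative threshold.
* **Orientation** is fixed a priori per predictor (K, PSA, PSAD
  higher-positive; ADC, D lower-positive) so that an uninformative predictor
  can honestly score below 0.5.
* AUC itself is the normalized Mann–Whitney U statistic (ties one half),
  which equals the trapezoid area under the tie-grouped empirical ROC
  exactly — an identity the tests assert on tied data.

# Problem sizes and determinism

Every stochastic routine takes a seed and restores the caller's RNG state.
The test suite works at deliberately modest sizes chosen to make the checked
properties sharp: noiseless round-trips on a 1000-point parameter grid;
SNR-50 phantom recovery with a ~130-voxel ROI (bias bounds 5% for
$D_{app}$/ADC, 10% for K); type-I error of the gated comparison over 2000
null replicates at $n = 30$ per arm; moment convergence at $n = 10^5$ draws;
AUC reproduction on binormal cohorts of $10^6$ lesions per arm (Monte-Carlo
error ≈ 0.0005, far below the ±0.03 acceptance band). The pipeline smoke
tests use a 10×10×4 phantom and 3×2-fold cross-validation.

# Known limitations

* Scalar, orientation-averaged models only: no IVIM/bi-exponential,
  stretched-exponential or tensor-valued variants.
* ROIs are inputs (or phantom-derived); there is no lesion detection or
  segmentation, and no registration between sequences.
* The cohort simulator reproduces first and second moments per arm, not the
  joint dependence structure of real lesions; passing cohort-level tests
  shows the statistical machinery is correct, not that real cohorts will
  attain the same AUCs.
* Per-lesion analysis treats lesions as independent even when one patient
  contributes several; no clustering adjustment is applied.
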