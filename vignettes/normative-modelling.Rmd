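---
title: "Voxel-wise normative modelling of neonatal brain microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise normative modelling of neonatal brain microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Group-mean comparisons of preterm- and term-born neonatal imaging assume
that atypical development is homogeneous across infants — same regions,
same direction. Normative modelling drops that assumption: a reference
model of typical development is fitted at every voxel, and each individual
is expressed as a standardized deviation from the reference given their
age and sex, exactly as a pediatric growth chart expresses a child's
height as a centile. `voxnorm` implements this for diffusion-tensor scalar
maps — fractional anisotropy (FA, unitless in $[0,1]$) and mean
diffusivity (MD, in $\mu m^2/ms$) — in a neonatal cohort scanned between
37 and 45 weeks postmenstrual age (PMA).

## The per-voxel model

At each intracerebral voxel we model the two metrics jointly as a
two-output Gaussian process over the predictors $x = (\text{PMA}_{std},
\text{sex})$, using the intrinsic coregionalization construction:

$$\mathrm{cov}\!\left(y_a(x_i),\, y_b(x_j)\right) =
B_{ab}\, \exp\!\left(-\frac{\lVert x_i - x_j \rVert^2}{2\ell^2}\right) +
\delta_{ij}\,\delta_{ab}\,\sigma^2_a ,$$

with $a, b \in \{\mathrm{FA}, \mathrm{MD}\}$. $B = LL^\top$ is a
$2 \times 2$ positive-semidefinite coregionalization matrix (parameterized
by its Cholesky factor, 3 free parameters) that carries the shared signal
between FA and MD; $\ell$ is a single RBF lengthscale over the
standardized predictors; $\sigma^2_a$ are per-output white-noise
variances. Six hyperparameters per voxel are optimized by maximizing the
log marginal likelihood

$$\log p(y) = -\tfrac{1}{2} y^\top K^{-1} y - \tfrac{1}{2}\log|K|
- \tfrac{N}{2}\log 2\pi$$

with L-BFGS-B on log-transformed positive parameters (analytic
gradients), taking the best of `restarts` seeded starts (default 3; the
first start is data-driven, from linear-fit residual variances and the
observed FA–MD correlation). Restart seeds derive from (global seed,
voxel index), so fits are reproducible and independent of the order in
which voxels are processed.

Design choices worth stating explicitly:

* **Why one joint model rather than two independent GPs?** FA and MD share
  maturational signal; the coregionalization matrix lets the model borrow
  strength across the two outputs while the two noise terms stay separate.
* **Why standardize per voxel?** FA ($\sim 0.2$) and MD ($\sim 1$) differ
  in scale by an order of magnitude and could not share one kernel
  otherwise. Outputs are centred and scaled by the training mean and
  sample SD ($n-1$ denominator — the convention used everywhere in this
  package); PMA likewise; sex enters as an unscaled 0/1 coordinate under
  the shared lengthscale. All constants are stored for exact inversion.
* **Degenerate voxels** (zero output variance in the training sample) are
  flagged, never fitted; downstream stages exclude them from both the
  numerator and the denominator of any percentage and report the count.
* **Numerics.** A jitter of $10^{-8}$ (standardized scale) is added to the
  covariance diagonal before Cholesky factorization, escalated tenfold up
  to three times before failing loudly. Optimizer failures on all restarts
  leave a flagged model with a warning, never a silent fallback.

## Deviation scores

A subject with covariates $x_*$ and observed value $y_*$ at a voxel gets

$$Z = \frac{y_* - \mu(x_*)}{\sigma(x_*)},$$

where $\mu, \sigma$ are the posterior predictive mean and SD. The
predictive SD **includes the noise variance** by default
(`include_noise = TRUE`): deviations are measured against total predictive
uncertainty, which is the only convention under which a typical subject's
Z-scores are standard normal and $\approx 0.194\%$ of null voxels exceed
$|Z| > 3.1$ — the package's null-calibration tests depend on this, and it
matches the growth-chart analogy (a healthy child is scored against the
population spread, not against the uncertainty of the centile curve
alone).

Extreme deviations use strict inequalities ($Z > 3.1$, $Z < -3.1$) giving
four directional masks per subject (FA+, FA−, MD+, MD−). Group overlap
maps are the per-voxel percentage of subjects with an extreme deviation;
the consistency rule keeps voxels where strictly more than 4% of the group
deviates. The whole-brain atypicality index is the percentage of valid
intracerebral voxels in each directional mask; the denominator is the
template mask minus flagged voxels.

Normative subjects are scored from their held-out fold of a PMA-stratified
k-fold cross-validation (subjects sorted by PMA and dealt round-robin into
folds, ties broken by a seeded shuffle, so every fold spans the full PMA
range); holdout (preterm) subjects are scored against the model trained on
the whole normative sample. No subject is ever scored by a model trained
on itself.

## The statistical battery

Stage one: four group comparisons of the indices (Mann–Whitney U from
mid-ranks, normal approximation with tie and continuity correction —
appropriate at cohort sizes of tens to hundreds — with Vargha–Delaney
$A = U_x / (n_x n_y)$ as effect size); Spearman correlations (Pearson on
mid-ranks, t-approximation p; exact permutation available for $n \le 9$)
of each index with gestational age at birth within each group, and with
each outcome score within each group. Holm's step-down correction is
applied **within each family separately** (the group-comparison family;
the GA family per group; the outcome grid per group) — the family
boundaries follow the analysis blocks, since finer boundaries are not
dictated by the two-stage design. Degenerate tests (an index constant
within a group) are reported as NA rows and sit out of the correction
rather than aborting the battery.

Stage two, for index–outcome pairs surviving correction in the atypical
group: OLS of the outcome on the index plus GA, sex, head motion and
deprivation score (IMD), reporting per-term t p-values, adjusted $R^2$, the
overall F test, a Shapiro–Wilk residual-normality p and a Breusch–Pagan
heteroscedasticity p (diagnostics only, never gates); a case-resampling
percentile bootstrap CI for the adjusted $R^2$ (1000 replications;
singular resamples are redrawn and counted, >10% is an error; negative
draws are kept unless `truncate_at_zero` is set); out-of-bag bootstrap
prediction accuracy (100 resamples, mean adjusted $R^2$ of predictions on
the out-of-bag rows, falling back to unadjusted $R^2$ when the out-of-bag
set is too small to adjust); and an influential-observation rerun that
standardizes the index (sample SD), drops $|Z| > 3.1$ observations and
recomputes the correlation.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable with known ground
truth. It emulates: two groups (defaults 270 normative / 82 atypical, the
scale of the study design this package targets); PMA at scan uniform over
37–45 weeks in both groups; GA at birth $\ge$ 37 weeks (normative) vs a
truncated normal around 32 weeks (atypical); per-voxel linear age trends
with FA increasing (slopes uniform over 0.002–0.020 per week) and MD
decreasing (−0.055 to −0.008 $\mu m^2/ms$ per week), spatially smoothed so
neighbouring voxels are correlated; i.i.d. subject-level Gaussian noise
(defaults 0.025 FA, 0.07 $\mu m^2/ms$ MD — below the whole-brain MAE of a
real fit, which also absorbs registration and model error); small constant
sex offsets; and focal spherical lesions (random centres inside the mask,
1–4 clusters of radius 1.5–3 voxels per atypical subject) that raise MD
and lower FA by 5 subject-noise SDs, giving the heterogeneous,
little-overlapping deviation patterns the analysis is designed to detect.
Intercept and slope fields are smoothed Gaussian random fields
rank-uniformized to their documented ranges, so the marginal distribution
over the mask is exactly uniform and does not depend on grid size.

Outcome scores are a *testing device*: atypical outcomes decline linearly
in the subject's total lesion volume fraction (slope −2 score points per
percent, noise SD 6) so that brain–behaviour correlation tests have a
known sign and magnitude; normative outcomes are independent noise with
the composite-score convention (mean 100, SD 15). Lesion load is
independent of GA. Real data differ in ways the generator does not
attempt: spatially correlated (registration-induced) noise, non-Gaussian
tails, age-dependent variance, partial-volume effects at the cortex, and
outcome dependence on unmeasured clinical covariates. Passing tests
therefore demonstrate the *machinery* is correct and calibrated under its
own assumptions, not that the assumptions hold in any particular cohort.

## Problem sizes used by the validation suite

Exact GP inference is quadratic in memory and cubic in time in the number
of subject–output pairs, and fits are per voxel, so the suite validates
each property at the smallest scale that exercises it: oracle equivalence
on $n \le 10$ instances against dense base-R linear algebra; null
calibration on a $20^3$ grid (spherical mask, ~2,100 voxels) with 100
training and 200 held-out null subjects, expecting the grand
$|Z| > 3.1$ fraction inside [0.1%, 0.35%] (the plug-in use of estimated
hyperparameters makes held-out scores slightly heavy-tailed relative to
$2(1-\Phi(3.1)) = 0.194\%$ — a $t$-like effect that shrinks as the
training cohort grows); slope recovery (38→42-week finite difference of
the predictive mean against the generating slopes) at $n = 100$ on an
$8^3$ grid; lesion detection at $n = 60 + 20$ on a $10^3$ grid; and the
power/FWER simulation at $50 + 16$ subjects on a $5^3$ grid with 5 folds —
chosen so that fold-training (40) and full-model (50) sizes are close,
because the same plug-in tail effect otherwise makes CV-scored normative
indices systematically heavier-tailed than full-model-scored atypical
indices and biases the null group comparison at small $n$ (at study scale,
270 vs 216, the effect is negligible). The demo pipeline configuration
used for the byte-identical determinism check runs 24 + 12 subjects on a
$6^3$ grid with 3 folds.

## Known limitations

* Exact inference only: cohorts of a few hundred subjects fit comfortably,
  but the per-voxel cost grows as $O((2n)^3)$; thousands of subjects would
  need sparse approximations, which are out of scope.
* Voxels are fitted independently — no spatial regularization; overlap
  maps inherit whatever spatial smoothness the data carry.
* The Mann–Whitney p uses the corrected normal approximation; exact
  enumeration exists only in the test oracles (group sizes here make the
  approximation accurate to a few percent at worst).
* Predictive uncertainty is plug-in: hyperparameter uncertainty is not
  propagated, so extreme-tail fractions run slightly above the Gaussian
  ideal at small training sizes (quantified above and bounded in tests).
* No anatomical labelling of clusters, no parcellated indices, no raw
  diffusion preprocessing — inputs are coregistered scalar maps.
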