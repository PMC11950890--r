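---
title: "Fill states: quantifying the spatial extent of PET pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fill states: quantifying the spatial extent of PET pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fillstate)
```

## The marker

Conventional PET quantification summarizes a region by its mean tracer
uptake: the SUV ratio (SUVR), target-region mean divided by a
reference-region mean. SUVR measures *how intense* pathology is, but two
patients with the same meta-ROI SUVR can differ enormously in *how much*
of the region is affected. The **fill state** quantifies that spatial
extent directly:

1. intensity-normalize the subject volume to a reference region
   (`intensity_normalize()`), giving an SUVR map;
2. z-standardize each voxel against a cohort of amyloid-negative,
   cognitively normal controls: $z(v) = (x(v) - \mu(v)) / \sigma(v)$,
   where $\mu, \sigma$ are the voxelwise control mean and sample SD
   (`fit_control_model()`, `z_standardize()`);
3. classify each meta-ROI voxel as abnormal when $z > 1.65$ for
   hyper-signal tracers (amyloid, tau) or $z < -1.65$ for hypo-signal
   neurodegeneration (`classify_voxels()`);
4. report the percentage of abnormal voxels in the meta-ROI
   (`fill_state()`).

The cutoff 1.65 is the one-tailed 5% standard-normal quantile at the
conservative two-decimal convention ($\Phi^{-1}(0.95) = 1.6449 \to
1.65$). A direct consequence is the marker's *null floor*: a subject
drawn from the control distribution itself has an expected fill state of
$100\,(1 - \Phi(1.65)) \approx 4.95\%$, not 0%. Every quantitative check
in the package is built around this analytic anchor.

Two companion markers are computed alongside: the ROI SUVR
(`roi_suvr()`, the intensity marker) and the mean z-score of only the
abnormal voxels (`abnormal_intensity()`, undefined — not zero — when no
voxel is abnormal).

### Assumptions and conventions

* All volumes live on one template grid. Two grids are "aligned" when
  shapes match and affines agree within 1e-4 elementwise; nothing is ever
  resampled, and misalignment is an error, not a warning.
* Standardization is plain Gaussian; no small-sample t correction is
  applied, so control cohorts should not be tiny (the stored
  `n_controls` lets users judge). With $n$ controls the null exceedance
  is slightly above 4.95% because $\hat\sigma$ is noisy; at $n \ge 40$
  the bias is well inside the Monte-Carlo tolerances used here.
* Ties at exactly the cutoff are negative (strict inequality).
* Control-SD values below `sd_floor` (default 1e-6 SUVR) are clamped and
  counted, so constant voxels cannot produce infinite z.
* Non-finite voxels inside the ROI are excluded from both the numerator
  and the denominator of the fill state and counted in `n_missing`.

## The statistical battery

Marker distributions are skewed, so group staging uses Kruskal–Wallis
H (midranks, tie-corrected, $\chi^2$ approximation) with post hoc
Mann–Whitney U tests. `mann_whitney()` uses exact enumeration over all
$\binom{n_1+n_2}{n_1}$ assignments when the combined sample is at most
16 (valid under ties), and the tie-corrected normal approximation with
continuity correction above that.

Diagnostic performance for cognitive impairment (MCI + dementia vs SCD)
uses the AUC, computed through the U-statistic identity
$\mathrm{AUC} = U / (n_1 n_2)$ with ties counted one half. Because fill
state and SUVR are measured on the same subjects, their AUCs are
compared with the DeLong test for correlated ROC curves; a zero-variance
difference (e.g. one marker a monotone transform of the other) is
flagged degenerate rather than reported as $p = 1$.

Associations with cognition are partial Spearman correlations: all
variables are midrank-transformed and the partial Pearson correlation of
the ranked marker and score given ranked age, sex and education is taken
from least-squares residuals; $p$ comes from the t distribution with
$n - k - 2$ df. This construction is invariant under monotone transforms
of any variable and reduces exactly to plain Spearman with no
covariates.

Regression models 1–3 fit the block of cognitive scores on one
modality's fill state, SUVR, age, sex (0/1) and education (years);
model 4 uses all three fill states plus covariates. Per-term
multivariate tests use Wilks' lambda with Rao's F approximation and
type III cross-products — the default of the mainstream statistical
packages this battery mirrors; the exact multivariate criterion is a
genuinely open choice, and Pillai would differ only in edge cases. With
a single dependent variable the term F reduces exactly to the
univariate partial F, which the tests assert. Coefficients are reported
on raw scales. For left-skewed scores the conventional
reflect-and-square-root transform $t(x) = \sqrt{\max(x) + 1 - x}$ is
provided; the reflection constant ($\max + 1$) affects only the
coefficient scale, never ranks or significance, and flips association
signs. Results are flagged at three tiers: $\alpha = .05$, the
Bonferroni level for three modality comparisons ($.05/3 = .017$ at
display precision), and $\alpha = .001$.

## The synthetic phantom cohort

Real amyloid/tau/FDG cohorts are access-controlled, so the package ships
a generator whose ground truth is known exactly.

* **Geometry** (32³ default): a centered ellipsoid meta-ROI covering
  ~30% of the grid (10,136 voxels), a disjoint reference slab standing
  in for the cerebellar reference, and a gray-matter ellipsoid
  containing the ROI.
* **Controls**: voxelwise independent $N(\mu(v), \sigma(v))$ with smooth
  low-frequency fields, $\mu \in [1.0, 1.4]$ SUVR and
  $\sigma \in [0.05, 0.15]$ — the scale and variability of normalized
  PET maps. Changing the ranges creates distribution-shifted "external"
  cohorts.
* **Patients**: a lesion occupying a requested fraction $f$ of the ROI,
  grown by breadth-first accretion from a random seed voxel
  (6-connectivity, randomized neighbor order) so pathology is spatially
  contiguous, shifted by $+\delta\,\sigma(v)$ (amyloid/tau) or
  $-\delta\,\sigma(v)$ (neurodegeneration) with $\delta = 5$ SD by
  default. A `scattered` mode places lesion voxels uniformly to
  dissociate extent from contiguity.
* **Cohort structure**: group mean lesion fractions 0.02 (CN), 0.10
  (SCD), 0.30 (MCI), 0.55 (dementia) with group-specific jitter —
  encoding the designed ordering of pathology extent with clinical
  stage. Ages are Normal(70, 7) truncated to [50, 90], education
  Normal(14, 3) truncated to [8, 22], sex Bernoulli(0.5): plausible
  memory-clinic ranges, not fitted to any dataset. Cognitive scores
  (global/MMSE-like, memory, executive) are linear in $(f,$ age, sex,
  education$)$ plus Gaussian noise, with strictly negative loadings on
  $f$.
* **Amyloid positivity**: thresholds like 1.11 are tracer- and
  scale-specific literature values for real SUVR data; on the phantom,
  whose control ROI mean is ~1.2 by construction, the default is
  therefore `"auto"` — the phantom's control ROI mean plus the signal a
  lesion covering 5% of the ROI would add. Numeric thresholds can be
  set in the pipeline config for real data.

Under these defaults the analytic expectation for a patient with lesion
fraction $f$ at $\delta = 5$ is a fill state of about
$100f\,\Phi(\delta - 1.65) + 4.95\,(1 - f)$ — i.e. slope just under 1
and intercept at the null floor when regressing on $100 f$, which is
exactly what the acceptance checks measure.

What the phantom does *not* emulate: spatial noise autocorrelation
(PET is smooth; a Gaussian-blur option exists but the calibration
bounds assume independent noise), scanner point-spread and
partial-volume effects, anatomic heterogeneity of meta-ROIs, off-target
binding, and longitudinal dynamics. Passing tests therefore demonstrate
the *method's* correctness and calibration, not clinical performance on
real scans.

## The CNN estimator

Computing a fill state requires a control cohort; the CNN removes that
dependency by learning the mapping from the SUVR volume to the fill
state. The architecture is a compact 3D regression network sized for
32³ CPU training: a fixed 2× average-pooling stem, three 3×3×3
convolution blocks (8/16/32 channels, ReLU, 2× average pooling after
the first two), global average pooling, and one dense sigmoid unit
scaled to [0, 1]. Convolutions are evaluated as im2col patch matrices
times weight matrices (BLAS), and training is plain Adam
(lr 3e-3, batch 16, 30 epochs) on mean absolute error — MAE being the
headline metric reported for the estimator. Inputs are scaled by fixed
constants ($(x - 1.2) \times 4$), not by any cohort statistic, keeping
inference strictly single-subject.

Global average pooling is the structurally right inductive bias here:
the target is itself a spatial average of a voxel property, so the conv
stack only has to learn a local abnormality detector. The sigmoid head
keeps estimates in [0, 100]%; an unbounded head (`bounded = FALSE`)
is retained for fidelity experiments — unbounded regression can
estimate beyond 100%, and such estimates are clipped with a logged
message at prediction time.

Determinism: initialization, the 70/30 train/validation split, and the
per-epoch shuffling all derive from the config seed, and generators
restore the caller's RNG state. On the default synthetic benchmark (200
volumes per cohort, 70/30 split) validation MAE is ~2 percentage points
and $r^2 > 0.98$; a distribution-shifted external phantom cohort
degrades the error while keeping $r^2$ positive, mirroring the expected
external-validation pattern.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the sizes the phantom
defaults define: 200-subject null calibration, 10 lesion fractions × 3
replicates for extent recovery, 2000-replicate null calibrations of each
test, a 120-subject cohort for the qualitative clinical pattern, and
200-volume CNN cohorts — sizes at which the Monte-Carlo tolerances
(1.5 pp on the null mean, [0.85, 1.05] on the extent slope, [0.035,
0.065] on type-I rates) are comfortably discriminating. Sub-seeds for
subject-level volumes are drawn from the cohort seed, so any volume is
reproducible in isolation. Exact Mann–Whitney enumeration switches to
the normal approximation above a combined n of 16 (12,870 assignments),
a size chosen so the exact path stays instant.

## Known limitations

* Meta-ROI and reference-region definitions are inputs; the package
  takes masks as given and does not ship an atlas.
* No spatial normalization, partial-volume correction, or Centiloid
  harmonization — volumes must already be in template space.
* The CNN is a desk-scale stand-in sized for the phantom; applying it to
  real resolution data would require rescaling the architecture and
  retraining.
* Whether subject-level gray-matter exclusion should apply inside
  meta-ROIs is left to the caller (supply a tighter mask if so).
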