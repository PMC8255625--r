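---
title: "Characterizing subcortical nuclei from multiparametric quantitative MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing subcortical nuclei from multiparametric quantitative MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmri)
```

## The problem

Deep gray-matter nuclei of the basal ganglia, midbrain and brainstem differ
in iron load, myelin and macromolecule content, cell density and free-water
fraction. Four quantitative MR contrasts probe these properties from
complementary angles:

* **QSM** — voxel-wise magnetic susceptibility $\chi$ (ppm), driven largely
  by tissue iron;
* **sodium imaging** — total tissue sodium concentration (mmol/l),
  reflecting extracellular volume and membrane integrity;
* **MTR** — magnetization transfer ratio (percentage units), a
  semi-quantitative proxy for the macromolecule-bound proton pool;
* **T1 mapping** — longitudinal relaxation time (ms).

The question this package operationalizes: *taking only the voxel values
inside a structure's VOI — no geometry, no atlas position — how well can the
structure (or its functional group) be identified?* The analysis chain is:
per-structure descriptive statistics and rankings, pooled voxel-wise
correlations between contrasts, a tri-axial ellipsoid visualization/overlap
analysis, first-order feature extraction, and random-forest classification
with cross-validation, feature importances and a contrast-subset ablation.

Because the underlying volunteer data are not publicly deposited, the
package ships a packaged table of per-structure reference statistics
(`load_reference_params()`): 21 structures — 19 nuclei and 2 fiber tracts in
5 functional groups — with the per-contrast mean and SD of each. A synthetic
cohort generator reproduces data with exactly this statistical structure, so
every downstream stage runs end to end and is testable.

## The synthetic cohort model

`generate_cohort()` draws, for each subject $s$, structure $k$ and contrast
$c$:

$$ m_{skc} = \mu_{kc} + f\,\sigma_{kc}\,u_{skc}, \qquad
   x_{iskc} = m_{skc} + \sqrt{1-f^2}\,\sigma_{kc}\,\varepsilon_{iskc}, $$

with $u$ and $\varepsilon$ standard normal. The four contrasts of one draw
are coupled through a common correlation matrix $R$ at both levels. By the
law of total variance the pooled voxel variance is exactly
$\sigma_{kc}^2$ for any $f$, so the generated cohort matches the reference
SDs by construction; the pooled mean matches $\mu_{kc}$ in expectation.

Key parameters (all in `cohort_config()`):

* `inter_subject_fraction` ($f$, default **0.4**). The reference table
  reports only pooled SDs; no between/within decomposition is published.
  We attribute 40% of the SD to between-subject variation — enough that
  subjects have distinct signatures (so leave-one-out folds are not
  trivially easy), while the structure separations that the reference
  statistics imply remain intact. Configurable; nothing downstream assumes
  the default.
* `voxels_per_structure` (default **200**). VOI sizes are not published;
  200 voxels per structure is a realistic manually-segmented VOI size for
  structures of this scale and keeps every structure equally weighted in
  pooled statistics.
* `grid_shape` (default 30×30×30). Structures are placed as disjoint
  axis-aligned blocks. No anatomical geometry is modeled: the
  classification analysis uses matrices of voxel values only, so spatial
  arrangement is irrelevant to every statistic the package computes.
* **CSF compartment**: a dedicated label with sodium
  $\mathcal{N}(140, 5^2)$ mmol/l. The 140 mmol/l center is the
  physiological CSF concentration used as the referencing anchor; the 5
  mmol/l SD is a package choice (CSF variability is not published).
  The remaining CSF parameters (χ ≈ 0 ppm, MTR ≈ 1.5 p.u., T1 ≈ 4300 ms)
  are literature-plausible free-water values at 7T; only the sodium channel
  matters for the referencing path.
* Distributions are Gaussian throughout: only means and SDs are available
  as constraints, so no heavier-tailed model is attempted.

Determinism: the cohort seed derives one seed per subject
(`(seed + i * 7919) mod (2^31 - 1)`), and every randomized analysis step
takes an explicit seed, so all results are reproducible bit for bit.

### What the phantom does *not* emulate

No acquisition physics (k-space, coil sensitivity, B0/B1), no partial-volume
mixing at structure boundaries, no segmentation error, no registration
misalignment, no spatial autocorrelation of noise. These are precisely the
effects that make real-data classification hard; accuracies measured on the
synthetic cohort are therefore an *upper* bound on what identically
parameterized real data would give, and tests treat published accuracies as
floors, not as point targets.

## Calibrating the residual correlation

Pooled voxel-wise correlations between contrasts are a reported feature of
the data (e.g. T1–Na $r = 0.58$, T1–MTR $r = -0.46$). In the generator the
pooled covariance over all VOI voxels decomposes exactly as

$$ \mathrm{cov}_{\text{pooled}}(c_1, c_2)
   = \mathrm{Cov}_k(\mu_{kc_1}, \mu_{kc_2})
   + R_{c_1 c_2} \cdot \overline{\sigma_{kc_1} \sigma_{kc_2}}, $$

linear in $R$ with per-entry dependence.
`calibrate_residual_correlation()` inverts this relation analytically for a
starting guess, then iterates: simulate a cohort with a fixed calibration
seed, measure the achieved pooled correlations, apply the linearized
update, clamp entries to $[-1, 1]$ and project back to the nearest
positive-semidefinite correlation matrix; the best iterate is kept.

The decomposition also exposes a structural limit. The between-structure
term is fixed by the reference means, and the residual term is bounded by
$|R_{ij}| \le 1$; with equal VOI sizes the achievable pooled T1–Na
correlation tops out near 0.52 — below the reported 0.58 — and the reported
MTR–QSM value of −0.01 would need a residual entry below −1. The reported
values evidently reflect properties the per-structure reference table does
not constrain (unequal real VOI sizes chief among them: pooled correlations
weight structures by voxel count). The calibration therefore typically
terminates as a best-effort compromise, warns, and records the achieved
matrix in the `calibration` attribute; downstream code uses the calibrated
configuration regardless. We deliberately do not re-weight VOI sizes to
force a match — voxel counts are a stated study condition, not a free
parameter.

## Derived maps

* `compute_mtr()`: $\mathrm{MTR} = (M_0 - M_{\text{sat}})/M_0 \times 100$
  voxel-wise, in percentage units. Voxels with non-positive $M_0$ inside
  the mask are invalidated and counted in a warning. Values outside
  $[-100, 100]$ (possible with noise) are retained, not clipped, and
  reported if they exceed 1% of valid voxels.
* `reference_sodium()`: multiplies a raw sodium volume by
  $140 / \overline{\text{raw}}_{\text{CSF}}$ so the CSF mean is exactly 140
  mmol/l. The arithmetic mean over all CSF-mask voxels is used, untrimmed.
  The operation is idempotent, and `generate_raw_sodium()` /
  `generate_raw_mt_pair()` provide exact-inversion test paths for both maps.

## Descriptive statistics

Per-VOI summaries use the arithmetic mean and the *sample* SD
(denominator $n-1$) over voxels. Grand means across the 19 nuclei (or the 2
fiber tracts) are **unweighted** means of the per-structure means, with the
SD across structure means using denominator $n$; this pair of conventions
reproduces the published cross-structure values to well under 0.5% and is
the simplest reading of a mean "across structures". Pooled correlations use
all VOI voxels of all structures and subjects, with two-sided p-values from
the t transform with $n-2$ degrees of freedom ($\alpha = 0.05$; no
multiple-testing correction is applied, matching the original analysis
protocol). Rankings are ascending by mean with alphabetical tie-break.

## Ellipsoid overlap

`make_ellipsoid()` builds, per structure, an axis-aligned ellipsoid in
$(\chi, \mathrm{MTR}, T_1)$ space centered at the means with semi-axes equal
to the SDs; mean sodium is carried as a color attribute. Overlap of two
ellipsoids $Q_1(x) \le 1$, $Q_2(x) \le 1$ is decided by minimizing $Q_2$
subject to $Q_1 \le 1$: coordinates are first normalized to unit-SD units of
the first ellipsoid (making the test scale-free across ppm / p.u. / ms),
and the constrained minimizer is found by a bounded 1-D root search on the
Lagrange multiplier (tolerance $10^{-10}$). The margin is
$\min Q_2 - 1$: negative means overlap, and tangency counts as overlap
(closed ellipsoids). `overlap_matrix()` symmetrizes the (directional)
margins by taking the smaller of the two; the overlap decision itself is
direction-independent.

A numerical finding worth recording: with semi-axes of exactly one SD, the
reference table yields RN–SN disjointness and mutual disjointness of LGB,
Pul and HB — but most other qualitative overlap statements attached to the
published 3-D scatter figure only reproduce once the semi-axes are doubled
(at 2 SD, NC–Put, SN–Pal and RN–STN all overlap while RN–SN stays
disjoint). NC–Put at one SD is the uniquely closest non-touching pair
(margin ≈ 0.7 versus ≥ 5 for every other disjoint extrapyramidal pair). The
package keeps the stated one-SD rule and asserts only the claims that are
unambiguous under it; the rest are reported, not asserted.

## Feature schema

Each VOI is flattened to a 1-D signal per contrast in a canonical voxel
order — lexicographic by (slice, row, column), ascending. The order is a
package convention: no flattening order is published, and gradient features
depend on it, so an explicit canonical order is the only way to make them
reproducible. Eight features per contrast: mean, variance, min, max of the
signal and of its gradient — 32 features per sample. Numerical conventions:

* variance uses denominator $n$ (population), the default of the numeric
  stack the original analysis was built on;
* the gradient uses central differences at interior points and one-sided
  differences at the endpoints, unit spacing (the de-facto array-gradient
  convention); a length-1 signal has all gradient features 0, with a
  warning.

Mean/var/min/max are invariant to voxel permutation; gradient features are
not, which is exactly why the canonical order exists. On the synthetic
phantom the gradient features carry noise ordering rather than anatomy —
they are retained because the schema is fixed, but their importances on
synthetic data should not be over-interpreted.

## Classification protocol

Three prediction tasks over the feature table: all structures (18 classes
after exclusions), functional groups (5 classes), and structures within one
group. MB, LC and HB are excluded by default: they are small, lie against
CSF, and suffer the strongest partial-volume effects at sodium resolution.
Nuclei from different subjects are treated as independent samples.

`run_task()` uses a random forest with 100 trees (package `randomForest`,
conventional defaults otherwise — no further hyperparameters are part of
the protocol), refit in every cross-validation fold. Leave-one-out CV is
the default for the three tasks; the contrast ablation uses 100 runs of
stratified 5-fold CV — both protocols are part of the original analysis
description, and keeping both (selectable by argument) exposes rather than
hides the discrepancy. "100 runs" is interpreted as re-seeding the forest
(and the fold shuffle, for k-fold) with the data fixed; run $r$ uses seed
$\texttt{seed} + r$. Aggregation:

* mean accuracy over runs (identical to the class-count-weighted mean of
  per-class recalls, since every sample is tested once per run);
* confusion counts summed over folds and runs, then row-normalized
  (rows = true class; zero rows stay zero);
* feature importances: mean decrease in Gini impurity from forests refit on
  the full data in each run, averaged and normalized to sum 1;
  per-contrast importance is the sum over that contrast's 8 features.

`contrast_ablation()` re-runs the task on every requested contrast subset
with identical seeds, reporting singletons, pairs, triples, then all four.

## Problem sizes and runtimes

The package's test suite and the acceptance script run the reference-scale
protocol: 5 subjects × 21 structures × 200 voxels, 100-run LOO for the
prediction tasks and 100-run 5-fold for the ablation, plus
property suites at reduced sizes (2-subject mini-cohorts, 3–5 run CV) where
the property does not depend on scale. The two 90-sample LOO tasks dominate
the cost (a few minutes each on one CPU); everything else is seconds.

## Limitations

* Synthetic accuracies are optimistic relative to real data (see the
  phantom caveats above); published accuracies function as lower bounds in
  tests, and published per-class confusions (e.g. the difficulty of MGB)
  are not expected to reproduce.
* The pooled-correlation calibration is best-effort by construction; see
  the feasibility discussion above.
* Gradient features depend on the package's canonical flattening order; a
  different reimplementation choice would produce different (equally valid)
  gradient features on identical volumes.
* The QSM reconstruction chain, T1 fitting, registration and manual
  segmentation that produce real input maps are out of scope; the package
  starts from co-registered quantitative maps plus a label volume.
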