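# mpmri — multiparametric quantitative MRI characterization of subcortical nuclei

Deep gray-matter nuclei of the basal ganglia, midbrain and brainstem carry
distinct histoarchitectural signatures — iron load, macromolecule content,
cell density, free-water fraction — that four quantitative MR contrasts
probe from complementary angles: magnetic susceptibility (QSM, χ in ppm),
tissue sodium concentration (mmol/l), magnetization transfer ratio (MTR,
percentage units) and T1 relaxation time (ms). `mpmri` implements a complete
analysis chain for the question: *using only the voxel values inside each
structure's VOI, how well can 21 subcortical structures (in 5 functional
groups) be told apart?*

The package is aimed at quantitative-neuroimaging researchers who want a
tested, reproducible reference implementation of this analysis — either to
run on their own co-registered NIfTI maps plus a label volume, or on the
packaged synthetic cohort generator that reproduces the statistical
structure of published 7T reference values.

## What it computes

* **Synthetic cohorts** (`generate_cohort`): hierarchical Gaussian phantom
  with subject-level means `m = μ + f·σ·u` and voxel values
  `m + √(1−f²)·σ·ε`, cross-contrast coupling through a residual correlation
  matrix `R`, and a CSF compartment (sodium centered on 140 mmol/l). By the
  law of total variance the pooled voxel SD per structure equals the
  reference σ exactly. `calibrate_residual_correlation` tunes `R` against
  reported pooled voxel-wise correlations.
* **Derived maps** (`compute_mtr`, `reference_sodium`):
  `MTR = (M0 − Msat)/M0 × 100`; sodium rescaled so the CSF mean is exactly
  140 mmol/l.
* **VOI statistics** (`summarize_voi`, `pool_and_summarize`,
  `rank_structures`, `grand_means`, `pooled_correlation`): per-structure
  mean ± SD, ascending rankings, unweighted grand means across nuclei or
  fiber tracts, pooled Pearson correlations with t-transform p-values.
* **Ellipsoid overlap** (`make_ellipsoid`, `ellipsoid_overlap`,
  `overlap_matrix`): per-structure tri-axial ellipsoids in (χ, MTR, T1)
  space (center = means, semi-axes = SDs, color = mean sodium); pairwise
  intersection decided by constrained minimization of one quadratic form
  over the other, via a bounded root search on the Lagrange multiplier.
* **Features** (`extract_features`): each VOI flattened to a 1-D signal per
  contrast in canonical (slice, row, column) order; mean, variance
  (denominator n), min, max of the signal and of its gradient (central
  differences, one-sided at endpoints) — 32 features per sample.
* **Classification** (`build_dataset`, `run_task`, `contrast_ablation`):
  random forests with 100 trees, leave-one-out (or stratified k-fold) CV,
  repeated over 100 seeded runs; mean accuracy, row-normalized confusion
  matrices, impurity-decrease feature/contrast importances, and a
  contrast-subset ablation. Very small CSF-adjacent structures (MB, LC, HB)
  are excluded by default.
* **Pipeline** (`run_pipeline`): one call from generator to report, writing
  NIfTI volumes, TSV tables and a JSON report, reproducible bit for bit
  from a single seed.

See the vignette (`vignettes/multiparametric-subcortical.Rmd`) for the
model, conventions, numerical choices and limitations.

## Worked example

```r
library(mpmri)
specs <- load_reference_params()
grand_means(specs, "nuclei")
#>   contrast         mean           sd n_structures
#> 1      qsm 3.024737e-02   0.03676168           19
#> 2       na 5.092632e+01  14.23908047           19
#> 3      mtr 2.215789e+01   2.13869507           19
#> 4      t1  1.447737e+03 177.04975278           19
```

The unweighted grand means across the 19 nuclei — sodium 50.9 mmol/l, MTR
22.2 p.u., T1 1447.7 ms — summarize where subcortical gray matter sits in
each contrast. Generate a 5-subject cohort and check that pooled statistics
match the reference values (globus pallidus: χ 0.0851 ± 0.0095 ppm):

```r
cfg <- cohort_config(n_subjects = 5, seed = 42)
cohort <- generate_cohort(cfg, specs)
summaries <- summarize_cohort(cohort)
subset(summaries, structure == "Pal")
#>    structure  scope n_voxels   qsm_mean      qsm_sd  na_mean    na_sd mtr_mean
#> 13       Pal pooled     1000 0.08626784 0.009043217 38.45227 1.813395 22.72941
#>      mtr_sd  t1_mean    t1_sd
#> 13 1.713946 1235.553 14.69141
```

Classify the six extrapyramidal nuclei from their 32 voxel-value features:

```r
features <- extract_features(cohort, specs)
report <- run_task(build_dataset(features, "within_group",
                                 group = "extrapyramidal"),
                   n_runs = 5, cv = "loo", seed = 42)
report
#> Task: within_group (extrapyramidal)
#> Mean accuracy over 5 runs (loo CV): 100.0%
#> Per-class accuracy:
#>  NC Pal Put  RN  SN STN
#>   1   1   1   1   1   1
round(report$contrast_importance, 3)
#>   qsm    na   mtr    t1
#> 0.234 0.272 0.273 0.221
```

On the clean synthetic cohort the extrapyramidal nuclei separate perfectly
(the per-class accuracies are the diagonal of the row-normalized confusion
matrix), with the four contrasts contributing comparable importance. Real
data add partial-volume and segmentation noise that the phantom deliberately
omits, so synthetic accuracies are upper bounds.

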