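Package: mpmri
Title: Multiparametric Quantitative MRI Characterization of Subcortical Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how well deep gray-matter structures of the basal
    ganglia, midbrain and brainstem can be told apart from combined
    quantitative MR contrasts: magnetic susceptibility (QSM, ppm), tissue
    sodium concentration (mmol/l), magnetization transfer ratio (MTR, p.u.)
    and T1 relaxation time (ms). Provides a hierarchical Gaussian phantom
    generator parameterized by packaged per-nucleus reference statistics,
    derived-map computation (MTR from an MT-on/MT-off pair, CSF-referenced
    sodium), per-structure descriptive statistics with pooled voxel-wise
    correlations, tri-axial ellipsoid overlap analysis, first-order
    signal/gradient feature extraction, and random-forest classification of
    structures and functional groups with leave-one-out or k-fold
    cross-validation, normalized confusion matrices, feature importances and
    a contrast-subset ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
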