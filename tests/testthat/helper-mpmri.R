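# Shared fixtures, built in code.

# A small reference-table subset (two functional groups, two structures
# each) for cheap cohort generation in unit tests.
mini_specs <- function() {
  specs <- load_reference_params()
  specs[specs$structure %in% c("Pal", "Put", "DRN", "PPN"), , drop = FALSE]
}

tiny_config <- function(seed = 303, ...) {
  cohort_config(n_subjects = 2, voxels_per_structure = 30, csf_voxels = 30,
                grid_shape = c(8, 8, 8), seed = seed, ...)
}

# Hand-built voxel block (already in canonical order).
toy_block <- function(values, subject_id = "s1", structure = "toy") {
  structure(list(subject_id = subject_id, structure = structure,
                 n = length(values[[1]]), values = values,
                 voxel_order = "slice_row_column"),
            class = "voxel_block")
}

# One-row summary data frame for ellipsoid construction.
toy_summary <- function(structure = "a",
                        center = c(qsm = 0, mtr = 0, t1 = 0),
                        axes = c(qsm = 1, mtr = 1, t1 = 1),
                        na_mean = 50) {
  data.frame(structure = structure,
             qsm_mean = center[["qsm"]], mtr_mean = center[["mtr"]],
             t1_mean = center[["t1"]], na_mean = na_mean,
             qsm_sd = axes[["qsm"]], mtr_sd = axes[["mtr"]],
             t1_sd = axes[["t1"]], na_sd = 1,
             stringsAsFactors = FALSE)
}

# Dense-sampling oracle for ellipsoid intersection: uniform points in the
# intersection of the two bounding boxes; reports TRUE if a point inside both
# ellipsoids is found. Used only against the analytic decision.
overlap_sampling_oracle <- function(e1, e2, n_points = 40000) {
  lo <- pmax(e1$center - e1$semi_axes, e2$center - e2$semi_axes)
  hi <- pmin(e1$center + e1$semi_axes, e2$center + e2$semi_axes)
  if (any(lo > hi)) return(FALSE)  # bounding boxes disjoint
  pts <- cbind(runif(n_points, lo[1], hi[1]),
               runif(n_points, lo[2], hi[2]),
               runif(n_points, lo[3], hi[3]))
  q <- function(p, e) {
    ((p[, 1] - e$center[1]) / e$semi_axes[1])^2 +
      ((p[, 2] - e$center[2]) / e$semi_axes[2])^2 +
      ((p[, 3] - e$center[3]) / e$semi_axes[3])^2
  }
  any(q(pts, e1) <= 1 & q(pts, e2) <= 1)
}

random_ellipsoid <- function() {
  make_ellipsoid(toy_summary(
    center = c(qsm = runif(1, -2, 2), mtr = runif(1, -2, 2),
               t1 = runif(1, -2, 2)),
    axes = c(qsm = runif(1, 0.2, 1.5), mtr = runif(1, 0.2, 1.5),
             t1 = runif(1, 0.2, 1.5))))
}
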