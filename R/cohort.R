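#' Configuration for synthetic cohort generation
#'
#' The generator draws, for every structure and contrast, a subject-level mean
#' `m = mu + f * sigma * u` (with `u` standard normal, the four contrasts
#' coupled through `residual_correlation`) and voxel values
#' `m + sqrt(1 - f^2) * sigma * eps` (per-voxel `eps` coupled through the same
#' matrix). The pooled voxel variance per structure and contrast is therefore
#' exactly `sigma^2` regardless of `f` (law of total variance), matching the
#' packaged reference SDs.
#'
#' @param n_subjects Number of subjects in a cohort (default 5).
#' @param voxels_per_structure Voxels per structure VOI; a single integer or a
#'   vector recycled over structures (default 200).
#' @param csf_voxels Voxels in the dedicated CSF compartment (default 200).
#' @param inter_subject_fraction Fraction `f` in `[0, 1)` of the total SD
#'   attributed to between-subject variation (default 0.4).
#' @param residual_correlation 4x4 symmetric positive-semidefinite matrix with
#'   unit diagonal coupling the contrasts at both the subject and the voxel
#'   level (default identity; see [calibrate_residual_correlation()]).
#' @param seed Integer master seed for the cohort.
#' @param grid_shape Dimensions of the synthetic label volume (default
#'   `c(30, 30, 30)`).
#' @param csf_params Named list of CSF tissue parameters; sodium is centered
#'   on the physiological 140 mmol/l.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5L,
                          voxels_per_structure = 200L,
                          csf_voxels = 200L,
                          inter_subject_fraction = 0.4,
                          residual_correlation = diag(4),
                          seed = 42L,
                          grid_shape = c(30L, 30L, 30L),
                          csf_params = list(na_mean = 140, na_sd = 5,
                                            qsm_mean = 0, qsm_sd = 0.003,
                                            mtr_mean = 1.5, mtr_sd = 0.8,
                                            t1_mean = 4300, t1_sd = 150)) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              voxels_per_structure = as.integer(voxels_per_structure),
              csf_voxels = as.integer(csf_voxels),
              inter_subject_fraction = inter_subject_fraction,
              residual_correlation = residual_correlation,
              seed = as.integer(seed),
              grid_shape = as.integer(grid_shape),
              csf_params = csf_params)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  f <- cfg$inter_subject_fraction
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f >= 1) {
    stop("inter_subject_fraction must be a single value in [0, 1)",
         call. = FALSE)
  }
  R <- cfg$residual_correlation
  if (!is.matrix(R) || !all(dim(R) == c(4, 4))) {
    stop("residual_correlation must be a 4x4 matrix", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8) {
    stop("residual_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("residual_correlation must be positive semidefinite", call. = FALSE)
  }
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive", call. = FALSE)
  if (any(cfg$voxels_per_structure < 1L) || cfg$csf_voxels < 1L) {
    stop("voxel counts must be positive", call. = FALSE)
  }
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1L)) {
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-subject seed derivation; keeps seeds inside 32-bit range.
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + as.numeric(i) * 7919) %% 2147483647)
}

# Square-root factor of a PSD correlation matrix; eigen-based so that exactly
# semidefinite matrices (from PSD projection) are accepted.
psd_factor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
}

# Place K disjoint axis-aligned blocks on the grid; returns an integer label
# volume where label k occupies exactly counts[k] voxels (labels 1..K).
place_structures <- function(grid_shape, counts) {
  k <- length(counts)
  side <- max(2L, ceiling(max(counts)^(1 / 3)))
  cells <- grid_shape %/% side
  if (prod(cells) < k) {
    stop("grid of shape ", paste(grid_shape, collapse = "x"),
         " is too small to place ", k, " disjoint structures of up to ",
         max(counts), " voxels", call. = FALSE)
  }
  labels <- array(0L, dim = grid_shape)
  cell_idx <- arrayInd(seq_len(k), cells)
  for (s in seq_len(k)) {
    orig <- (cell_idx[s, ] - 1L) * side
    # voxel offsets within the cell in canonical (slice, row, column) order
    off <- expand.grid(i = seq_len(side), j = seq_len(side), k = seq_len(side))
    off <- off[order(off$k, off$i, off$j), , drop = FALSE][seq_len(counts[s]), ]
    labels[cbind(orig[1] + off$i, orig[2] + off$j, orig[3] + off$k)] <- s
  }
  labels
}

#' Draw the volumes of one synthetic subject
#'
#' Generates a label volume with disjoint axis-aligned VOIs for every
#' structure in `specs` plus a dedicated CSF compartment, and four
#' co-registered quantitative maps drawn from the hierarchical Gaussian model
#' described in [cohort_config()]. Background voxels are zero in all maps.
#'
#' @param specs A `nucleus_reference` data frame (see
#'   [load_reference_params()]); subsets are allowed for small phantoms.
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Subject identifier string.
#' @return A list of class `subject_volumes` with elements `labels` (integer
#'   volume; 0 background, 1..K structures in `specs` order, K+1 CSF), `maps`
#'   (named list of the four real volumes), `csf_mask` (logical volume),
#'   `label_table` (named integer vector mapping structure abbreviation to
#'   label), `subject_id` and `seed`.
#' @export
sample_subject <- function(specs, config, subject_seed, subject_id = "s1") {
  validate_cohort_config(config)
  k <- nrow(specs)
  counts <- rep_len(config$voxels_per_structure, k)
  labels <- place_structures(config$grid_shape, c(counts, config$csf_voxels))
  csf_label <- k + 1L
  csf_mask <- labels == csf_label

  contrasts <- mp_contrasts()
  f <- config$inter_subject_fraction
  L <- psd_factor(config$residual_correlation)
  maps <- setNames(
    lapply(contrasts, function(cc) array(0, dim = config$grid_shape)),
    contrasts)

  set.seed(as.integer(subject_seed))
  mu <- as.matrix(specs[, paste0(contrasts, "_mean")])
  sg <- as.matrix(specs[, paste0(contrasts, "_sd")])
  for (s in seq_len(k)) {
    idx <- which(labels == s)
    n <- length(idx)
    u <- as.vector(L %*% rnorm(4))
    m <- mu[s, ] + f * sg[s, ] * u
    eps <- matrix(rnorm(n * 4), n, 4) %*% t(L)
    for (ci in seq_along(contrasts)) {
      maps[[ci]][idx] <- m[ci] + sqrt(1 - f^2) * sg[s, ci] * eps[, ci]
    }
  }
  csf_idx <- which(csf_mask)
  p <- config$csf_params
  for (cc in contrasts) {
    maps[[cc]][csf_idx] <- rnorm(length(csf_idx),
                                 mean = p[[paste0(cc, "_mean")]],
                                 sd = p[[paste0(cc, "_sd")]])
  }

  structure(
    list(labels = labels,
         maps = maps,
         csf_mask = csf_mask,
         label_table = setNames(c(seq_len(k), csf_label),
                                c(specs$structure, "CSF")),
         structures = specs$structure,
         subject_id = subject_id,
         seed = as.integer(subject_seed)),
    class = "subject_volumes")
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param specs Reference parameters; defaults to the packaged table.
#' @return A list of class `mp_cohort` of [sample_subject()] results, one per
#'   subject, with the config attached as attribute `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, voxels_per_structure = 30,
#'                      grid_shape = c(18, 18, 18), seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)
generate_cohort <- function(config = cohort_config(),
                            specs = load_reference_params()) {
  validate_cohort_config(config)
  cohort <- lapply(seq_len(config$n_subjects), function(i) {
    sample_subject(specs, config, subject_seed(config$seed, i),
                   subject_id = sprintf("s%02d", i))
  })
  attr(cohort, "config") <- config
  attr(cohort, "specs") <- specs
  class(cohort) <- "mp_cohort"
  cohort
}

#' Generate a raw MT-on/MT-off magnitude pair from a subject's MTR map
#'
#' Constructs the non-saturated magnitude volume `m0` (constant `m0_level`)
#' and the MT-saturated volume `msat = m0 * (1 - MTR/100)` so that
#' [compute_mtr()] inverts the pair back to the subject's MTR map exactly.
#'
#' @param subject A `subject_volumes` object.
#' @param m0_level Positive baseline magnitude (arbitrary units).
#' @return List with volumes `m0` and `msat`.
#' @export
generate_raw_mt_pair <- function(subject, m0_level = 100) {
  if (m0_level <= 0) stop("m0_level must be positive", call. = FALSE)
  mtr <- subject$maps$mtr
  labeled <- subject$labels > 0L
  if (any(mtr[labeled] >= 100)) {
    stop("MTR >= 100 p.u. on labeled voxels; magnitude pair undefined",
         call. = FALSE)
  }
  m0 <- array(m0_level, dim = dim(mtr))
  list(m0 = m0, msat = m0 * (1 - mtr / 100))
}

#' Generate an unreferenced raw sodium volume
#'
#' Scales the subject's (CSF-referenced) sodium truth map by an arbitrary
#' hidden factor, emulating the scanner-unit volume that [reference_sodium()]
#' normalizes back via the CSF mask.
#'
#' @param subject A `subject_volumes` object.
#' @param hidden_scale Positive scale factor.
#' @return The raw sodium volume (3D array).
#' @export
generate_raw_sodium <- function(subject, hidden_scale = 2.5) {
  if (hidden_scale <= 0) stop("hidden_scale must be positive", call. = FALSE)
  if (!any(subject$csf_mask)) stop("empty CSF mask", call. = FALSE)
  subject$maps$na * hidden_scale
}
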