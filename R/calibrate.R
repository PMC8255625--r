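#' Reported pooled correlation targets
#'
#' The five pooled voxel-wise Pearson correlations used as calibration
#' targets: T1-Na 0.58, T1-MTR -0.46, Na-MTR -0.25, T1-QSM -0.24 and
#' MTR-QSM -0.01. The QSM-Na pair was not reported and is left
#' unconstrained (`NA`).
#'
#' @return Symmetric 4x4 matrix with `NA` on the diagonal and for
#'   unconstrained pairs, dimnames [mp_contrasts()].
#' @export
default_correlation_targets <- function() {
  cn <- mp_contrasts()
  tgt <- matrix(NA_real_, 4, 4, dimnames = list(cn, cn))
  tgt["t1", "na"] <- tgt["na", "t1"] <- 0.58
  tgt["t1", "mtr"] <- tgt["mtr", "t1"] <- -0.46
  tgt["na", "mtr"] <- tgt["mtr", "na"] <- -0.25
  tgt["t1", "qsm"] <- tgt["qsm", "t1"] <- -0.24
  tgt["mtr", "qsm"] <- tgt["qsm", "mtr"] <- -0.01
  tgt
}

# Analytic moments of the pooled voxel distribution under equal VOI sizes:
# between-structure covariance of the reference means (population weighting),
# the mean within-structure sigma_i * sigma_j matrix, and total variances.
pooled_moments <- function(specs) {
  cn <- mp_contrasts()
  mu <- as.matrix(specs[, paste0(cn, "_mean")])
  sg <- as.matrix(specs[, paste0(cn, "_sd")])
  n <- nrow(mu)
  Cb <- cov(mu) * (n - 1) / n
  M <- crossprod(sg) / n
  V <- diag(Cb) + diag(M)
  dimnames(Cb) <- dimnames(M) <- list(cn, cn)
  list(between = Cb, within = M, total_var = setNames(V, cn))
}

# Project a symmetric matrix to the nearest positive-semidefinite correlation
# matrix: clip eigenvalues, then renormalize to unit diagonal.
project_correlation <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  R <- e$vectors %*% diag(pmax(e$values, 1e-6), nrow(R)) %*% t(e$vectors)
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Calibrate the residual correlation matrix against pooled targets
#'
#' Searches for a residual correlation matrix `R` such that the pooled
#' voxel-wise correlations of a generated cohort match the supplied targets.
#' Starting from a moment-matched analytic guess (the pooled covariance
#' decomposes as `between-structure covariance + R_ij * mean(sigma_i
#' sigma_j)`, linear in `R`), the search iterates: generate a cohort with a
#' fixed calibration seed, measure the achieved pooled correlations, apply
#' the linearized update, clamp entries to `[-1, 1]` and project back to a
#' positive-semidefinite correlation matrix. The best iterate (smallest
#' maximum target deviation) is kept.
#'
#' Targets can be genuinely infeasible: because the reference means already
#' fix the between-structure covariance, each pooled correlation can only be
#' moved within the band allowed by `|R_ij| <= 1`, and the PSD constraint
#' couples the pairs. In that case the function warns, returns the best
#' achievable configuration and records the achieved values.
#'
#' @param config A [cohort_config()]; its `residual_correlation` is replaced.
#' @param targets Symmetric 4x4 target matrix with `NA` for unconstrained
#'   pairs (default [default_correlation_targets()]).
#' @param specs Reference parameters.
#' @param tol Maximum absolute deviation declared converged (default 0.05).
#' @param max_iter Iteration cap (default 15).
#' @return The updated `cohort_config`, with attribute `calibration`: a list
#'   with `converged`, `achieved` (4x4 matrix), `targets`, `max_deviation`
#'   and `iterations`.
#' @export
calibrate_residual_correlation <- function(config = cohort_config(),
                                           targets = default_correlation_targets(),
                                           specs = load_reference_params(),
                                           tol = 0.05, max_iter = 15) {
  cn <- mp_contrasts()
  stopifnot(all(dim(targets) == c(4, 4)))
  free <- is.na(targets)
  if (any(abs(targets[!free]) >= 1)) {
    stop("correlation targets must lie in (-1, 1)", call. = FALSE)
  }
  mom <- pooled_moments(specs)
  S <- sqrt(outer(mom$total_var, mom$total_var))

  # linear inverse of the pooled-correlation map, target scale -> R scale
  to_resid <- function(rpool) (rpool * S - mom$between) / mom$within

  R <- to_resid(targets)
  R[free] <- 0
  diag(R) <- 1
  R <- project_correlation(pmin(pmax(R, -1), 1))

  calib_seed <- subject_seed(config$seed, 10007L)
  measure <- function(R) {
    cfg <- config
    cfg$residual_correlation <- R
    cfg$seed <- calib_seed
    tab <- pooled_correlation_matrix(cohort_blocks(generate_cohort(cfg, specs)))
    ach <- matrix(NA_real_, 4, 4, dimnames = list(cn, cn))
    for (k in seq_len(nrow(tab))) {
      ach[tab$contrast_a[k], tab$contrast_b[k]] <- tab$r[k]
      ach[tab$contrast_b[k], tab$contrast_a[k]] <- tab$r[k]
    }
    diag(ach) <- 1
    ach
  }

  best <- list(R = R, dev = Inf, achieved = NULL)
  for (it in seq_len(max_iter)) {
    ach <- measure(R)
    dev <- max(abs(ach[!free] - targets[!free]))
    if (dev < best$dev) best <- list(R = R, dev = dev, achieved = ach, it = it)
    if (dev <= tol) break
    step <- (targets - ach) * S / mom$within
    step[free] <- 0
    R <- project_correlation(pmin(pmax(R + step, -1), 1))
  }

  converged <- best$dev <= tol
  if (!converged) {
    warning("calibration did not reach all targets (max deviation ",
            format(round(best$dev, 3)),
            "); targets are infeasible given the between-structure mean ",
            "configuration -- returning the best achievable matrix",
            call. = FALSE)
  }
  config$residual_correlation <- best$R
  attr(config, "calibration") <- list(converged = converged,
                                      achieved = best$achieved,
                                      targets = targets,
                                      max_deviation = best$dev,
                                      iterations = it)
  config
}
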