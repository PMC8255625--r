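#' Build the tri-axial ellipsoid of a structure
#'
#' Ellipsoids live in (chi, MTR, T1) space: centered at the per-contrast mean
#' with semi-axes equal to the per-contrast SD. Mean sodium concentration is
#' carried as a display attribute (color), not as a fourth axis.
#'
#' @param summary One-row structure summary (see [summarize_voi()] /
#'   [pool_and_summarize()]), or a row of the reference table with the same
#'   mean/sd columns.
#' @return List of class `ellipsoid` with `structure`, `center` (chi ppm, MTR
#'   p.u., T1 ms), `semi_axes` and `color_value` (mean sodium, mmol/l).
#' @export
make_ellipsoid <- function(summary) {
  stopifnot(nrow(summary) == 1)
  center <- c(qsm = summary$qsm_mean, mtr = summary$mtr_mean,
              t1 = summary$t1_mean)
  axes <- c(qsm = summary$qsm_sd, mtr = summary$mtr_sd, t1 = summary$t1_sd)
  if (any(axes <= 0)) {
    stop("degenerate ellipsoid for '", summary$structure,
         "': zero SD in ", paste(names(axes)[axes <= 0], collapse = ", "),
         call. = FALSE)
  }
  structure(list(structure = summary$structure, center = center,
                 semi_axes = axes, color_value = summary$na_mean),
            class = "ellipsoid")
}

#' Decide whether two axis-aligned ellipsoids intersect
#'
#' Two closed ellipsoids overlap iff a point `x` exists with `Q1(x) <= 1` and
#' `Q2(x) <= 1`, where `Qi` is the axis-aligned quadratic form of ellipsoid
#' `i`. The decision minimizes `Q2` subject to `Q1 <= 1`: coordinates are
#' first normalized to unit-SD units of `e1` (making the test scale-free
#' across ppm / p.u. / ms); if the center of `e2` lies inside `e1` the
#' minimum is 0, otherwise the constrained minimizer is found by a bounded
#' 1-D root search on the Lagrange multiplier. Tangency counts as overlap.
#'
#' @param e1,e2 `ellipsoid` objects.
#' @param tol Root-search tolerance on the multiplier (default 1e-10).
#' @return List with `overlaps` (logical), `margin` (`min Q2 - 1`; negative
#'   means overlap, `-1` for concentric ellipsoids) and `point` (the
#'   minimizing point in original coordinates, a witness when overlapping).
#' @export
#' @examples
#' s <- data.frame(structure = "a", qsm_mean = 0, mtr_mean = 0, t1_mean = 0,
#'                 qsm_sd = 1, mtr_sd = 1, t1_sd = 1, na_mean = 50)
#' e <- make_ellipsoid(s)
#' ellipsoid_overlap(e, e)$margin  # -1
ellipsoid_overlap <- function(e1, e2, tol = 1e-10) {
  stopifnot(inherits(e1, "ellipsoid"), inherits(e2, "ellipsoid"))
  # unit-SD coordinates of e1: e1 becomes the unit ball at the origin
  cc <- (e2$center - e1$center) / e1$semi_axes
  b <- e2$semi_axes / e1$semi_axes

  q2 <- function(x) sum(((x - cc) / b)^2)
  if (sum(cc^2) <= 1) {
    min_q2 <- 0
    x_star <- cc
  } else {
    # minimizer on ||x|| = 1: x_d = c_d / (1 + lambda * b_d^2), lambda >= 0
    g <- function(lambda) sum((cc / (1 + lambda * b^2))^2) - 1
    hi <- 1
    iter <- 0
    while (g(hi) > 0) {
      hi <- hi * 4
      iter <- iter + 1
      if (iter > 200) {
        stop("ellipsoid overlap root search failed to bracket; centers ",
             paste(format(cc), collapse = ", "), call. = FALSE)
      }
    }
    lambda <- uniroot(g, c(0, hi), tol = tol)$root
    x_star <- cc / (1 + lambda * b^2)
    min_q2 <- q2(x_star)
  }
  margin <- min_q2 - 1
  list(overlaps = margin <= 1e-9, margin = margin,
       point = x_star * e1$semi_axes + e1$center)
}

#' Pairwise overlap matrix for a set of structures
#'
#' @param summaries Data frame of structure summaries (one row per
#'   structure), e.g. one functional group of [summarize_cohort()] output or
#'   of the reference table.
#' @return Symmetric logical matrix (diagonal `TRUE`) with the symmetric
#'   margin matrix attached as attribute `margins`.
#' @export
overlap_matrix <- function(summaries) {
  n <- nrow(summaries)
  stopifnot(n >= 1)
  ells <- lapply(seq_len(n), function(i) {
    make_ellipsoid(summaries[i, , drop = FALSE])
  })
  nm <- summaries$structure
  ov <- matrix(TRUE, n, n, dimnames = list(nm, nm))
  mg <- matrix(-1, n, n, dimnames = list(nm, nm))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        # the constrained minimum is directional; symmetrize by taking the
        # smaller margin (the overlap decision itself agrees both ways)
        res_ij <- ellipsoid_overlap(ells[[i]], ells[[j]])
        res_ji <- ellipsoid_overlap(ells[[j]], ells[[i]])
        ov[i, j] <- ov[j, i] <- res_ij$overlaps || res_ji$overlaps
        mg[i, j] <- mg[j, i] <- min(res_ij$margin, res_ji$margin)
      }
    }
  }
  attr(ov, "margins") <- mg
  ov
}
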