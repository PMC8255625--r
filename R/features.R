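feature_stats <- function() {
  c("mean", "var", "min", "max", "mean_grad", "var_grad", "min_grad",
    "max_grad")
}

#' Canonical feature names
#'
#' Eight first-order statistics per contrast -- mean, variance, minimum and
#' maximum of the flattened voxel signal and of its gradient -- named
#' `<stat>_<contrast>` and ordered contrast-major (all qsm features, then na,
#' mtr, t1): 32 names in total.
#'
#' @param contrasts Contrasts to include (default all four).
#' @return Character vector of feature names.
#' @export
#' @examples
#' head(feature_names())
feature_names <- function(contrasts = mp_contrasts()) {
  stopifnot(all(contrasts %in% mp_contrasts()))
  as.vector(vapply(contrasts, function(cc) paste0(feature_stats(), "_", cc),
                   character(8)))
}

#' Flatten a VOI to a one-dimensional signal
#'
#' Returns the block's voxel vector for one contrast. Blocks produced by
#' [extract_voi()] already carry voxels in canonical (slice, row, column)
#' order, which fixes the gradient-based features.
#'
#' @param block A `voxel_block`.
#' @param contrast One of [mp_contrasts()].
#' @return Numeric vector of length `block$n`.
#' @export
flatten_voi <- function(block, contrast) {
  stopifnot(inherits(block, "voxel_block"))
  contrast <- match.arg(contrast, mp_contrasts())
  block$values[[contrast]]
}

# Array-style numeric gradient: central differences at interior points,
# one-sided at the two endpoints, unit spacing.
signal_gradient <- function(x) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (x[i + 1] - x[i - 1]) / 2
  }
  g
}

#' First-order features of a one-dimensional signal
#'
#' Computes mean, variance (population, denominator `n`), minimum and
#' maximum of the signal and the same four statistics of its gradient
#' (central differences at interior points, one-sided at the endpoints).
#'
#' @param x Numeric signal of length >= 1.
#' @return Named numeric vector of length 8 (names [feature_stats()]-style,
#'   without contrast suffix). For a length-1 signal the gradient features
#'   are 0, with a warning.
#' @export
#' @examples
#' signal_features(c(0, 1, 2, 3))  # mean 1.5, var 1.25, all gradients 1
signal_features <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty signal", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite signal values", call. = FALSE)
  if (n == 1) {
    warning("length-1 signal: gradient features reported as 0",
            call. = FALSE)
    g <- 0
  } else {
    g <- signal_gradient(x)
  }
  var_pop <- function(v) mean((v - mean(v))^2)
  c(mean = mean(x), var = var_pop(x), min = min(x), max = max(x),
    mean_grad = mean(g), var_grad = var_pop(g), min_grad = min(g),
    max_grad = max(g))
}

#' Full feature vector of a voxel block
#'
#' @param block A `voxel_block`.
#' @param group Optional functional group label to attach.
#' @return One-row data frame: `subject_id`, `structure`, `group`, then the
#'   32 feature columns in canonical order.
#' @export
feature_vector <- function(block, group = NA_character_) {
  feats <- unlist(lapply(mp_contrasts(), function(cc) {
    f <- signal_features(flatten_voi(block, cc))
    setNames(f, paste0(names(f), "_", cc))
  }))
  out <- data.frame(subject_id = block$subject_id,
                    structure = block$structure,
                    group = group, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(feats), check.names = FALSE))
}

#' Feature table of a cohort
#'
#' One row per (subject, structure) with the 32 canonical features plus
#' structure and functional-group labels.
#'
#' @param cohort An `mp_cohort`, or a list of `voxel_block`s.
#' @param specs Reference table supplying group labels.
#' @return Data frame of class `feature_table`.
#' @export
extract_features <- function(cohort, specs = load_reference_params()) {
  blocks <- if (inherits(cohort, "mp_cohort")) cohort_blocks(cohort) else cohort
  groups <- setNames(specs$group, specs$structure)
  out <- do.call(rbind, lapply(blocks, function(b) {
    feature_vector(b, group = unname(groups[b$structure]))
  }))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
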