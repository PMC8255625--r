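#' Extract the voxel block of one structure
#'
#' Collects the index-aligned per-contrast voxel vectors of a labeled VOI in
#' canonical order: voxels sorted lexicographically by (slice, row, column),
#' all ascending. The canonical order makes gradient-based features
#' reproducible across otherwise equivalent label volumes.
#'
#' @param maps Named list of the four contrast volumes (arrays or
#'   `quant_map`s), co-registered (same shape as `labels`).
#' @param labels Integer label volume.
#' @param structure Integer label, or structure name resolved through
#'   `label_table`.
#' @param label_table Named integer vector mapping structure names to labels
#'   (as carried by `subject_volumes`); only needed for name lookup.
#' @param subject_id Identifier recorded in the block.
#' @return A list of class `voxel_block` with fields `subject_id`,
#'   `structure`, `n` and `values` (named list of four equal-length numeric
#'   vectors).
#' @export
extract_voi <- function(maps, labels, structure, label_table = NULL,
                        subject_id = "s1") {
  maps <- lapply(maps, map_values)
  if (!all(mp_contrasts() %in% names(maps))) {
    stop("maps must be named with all of: ",
         paste(mp_contrasts(), collapse = ", "), call. = FALSE)
  }
  for (cc in mp_contrasts()) {
    if (!all(dim(maps[[cc]]) == dim(labels))) {
      stop("map '", cc, "' shape ", paste(dim(maps[[cc]]), collapse = "x"),
           " does not match label shape ", paste(dim(labels), collapse = "x"),
           call. = FALSE)
    }
  }
  if (is.character(structure)) {
    if (is.null(label_table) || !(structure %in% names(label_table))) {
      stop("structure '", structure, "' not found in label table",
           call. = FALSE)
    }
    lab <- label_table[[structure]]
    name <- structure
  } else {
    lab <- structure
    name <- if (!is.null(label_table) && lab %in% label_table) {
      names(label_table)[match(lab, label_table)]
    } else {
      as.character(lab)
    }
  }
  idx <- which(labels == lab)
  if (length(idx) == 0) {
    stop("label ", lab, " absent from the label volume", call. = FALSE)
  }
  pos <- arrayInd(idx, dim(labels))          # columns: row, column, slice
  idx <- idx[order(pos[, 3], pos[, 1], pos[, 2])]
  values <- lapply(maps[mp_contrasts()], function(v) v[idx])
  if (any(vapply(values, function(v) any(!is.finite(v)), logical(1)))) {
    stop("non-finite map values inside VOI '", name, "'", call. = FALSE)
  }
  structure(list(subject_id = subject_id, structure = name,
                 n = length(idx), values = values,
                 voxel_order = "slice_row_column"),
            class = "voxel_block")
}

#' Extract all voxel blocks of a cohort
#'
#' @param cohort An `mp_cohort` from [generate_cohort()].
#' @return List of `voxel_block`s, one per (subject, structure); CSF is not
#'   included.
#' @export
cohort_blocks <- function(cohort) {
  out <- list()
  for (subj in cohort) {
    for (s in subj$structures) {
      out[[length(out) + 1]] <- extract_voi(subj$maps, subj$labels, s,
                                            subj$label_table,
                                            subj$subject_id)
    }
  }
  out
}

new_structure_summary <- function(structure, scope, vals) {
  n <- length(vals[[1]])
  if (n == 1) warning("single-voxel block: SD reported as 0", call. = FALSE)
  row <- list(structure = structure, scope = scope, n_voxels = n)
  for (cc in mp_contrasts()) {
    row[[paste0(cc, "_mean")]] <- mean(vals[[cc]])
    row[[paste0(cc, "_sd")]] <- if (n > 1) sd(vals[[cc]]) else 0
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Summarize a voxel block
#'
#' Per-contrast arithmetic mean and sample standard deviation (denominator
#' `n - 1`) over the block's voxels.
#'
#' @param block A `voxel_block`.
#' @return One-row data frame with columns `structure`, `scope`, `n_voxels`
#'   and `<contrast>_mean` / `<contrast>_sd`.
#' @export
summarize_voi <- function(block) {
  stopifnot(inherits(block, "voxel_block"))
  new_structure_summary(block$structure, "single_subject", block$values)
}

#' Pool voxel blocks across subjects and summarize
#'
#' @param blocks List of `voxel_block`s of the same structure.
#' @return One-row data frame as in [summarize_voi()] with scope `"pooled"`.
#' @export
pool_and_summarize <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  structure_name <- unique(vapply(blocks, `[[`, "", "structure"))
  if (length(structure_name) != 1) {
    stop("blocks span several structures: ",
         paste(structure_name, collapse = ", "), call. = FALSE)
  }
  vals <- setNames(lapply(mp_contrasts(), function(cc) {
    unlist(lapply(blocks, function(b) b$values[[cc]]), use.names = FALSE)
  }), mp_contrasts())
  new_structure_summary(structure_name, "pooled", vals)
}

#' Pooled per-structure summaries for a whole cohort
#'
#' @param cohort An `mp_cohort`, or a list of `voxel_block`s.
#' @return Data frame with one pooled summary row per structure.
#' @export
summarize_cohort <- function(cohort) {
  blocks <- if (inherits(cohort, "mp_cohort")) cohort_blocks(cohort) else cohort
  by_structure <- split(blocks, vapply(blocks, `[[`, "", "structure"))
  out <- do.call(rbind, lapply(by_structure, pool_and_summarize))
  rownames(out) <- NULL
  out
}

#' Rank structures by mean value of one contrast
#'
#' @param summaries Data frame of structure summaries (needs `structure` and
#'   `<contrast>_mean` columns).
#' @param contrast One of [mp_contrasts()].
#' @return The summaries reordered strictly ascending by mean; ties broken
#'   alphabetically by structure name. A `rank` column is prepended.
#' @export
rank_structures <- function(summaries, contrast) {
  contrast <- match.arg(contrast, mp_contrasts())
  stopifnot(nrow(summaries) >= 2)
  ord <- order(summaries[[paste0(contrast, "_mean")]], summaries$structure)
  out <- summaries[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Grand means across nuclei or fiber tracts
#'
#' Unweighted mean of the per-structure means for each contrast, together
#' with the SD of those means (denominator `n`, i.e. the population SD across
#' structures).
#'
#' @param summaries Data frame with `structure` and `<contrast>_mean` columns
#'   (a cohort summary or the reference table itself).
#' @param subset `"nuclei"` (the 19 gray-matter structures) or
#'   `"fiber_tracts"` (CP, ML).
#' @param specs Reference table supplying the group membership.
#' @return Data frame with columns `contrast`, `mean`, `sd`, `n_structures`.
#' @export
#' @examples
#' grand_means(load_reference_params())  # sodium ~51.0 mmol/l, T1 ~1448.5 ms
grand_means <- function(summaries, subset = c("nuclei", "fiber_tracts"),
                        specs = load_reference_params()) {
  subset <- match.arg(subset)
  wanted <- if (subset == "nuclei") {
    specs$structure[specs$group != "fiber_tract"]
  } else {
    specs$structure[specs$group == "fiber_tract"]
  }
  missing <- setdiff(wanted, summaries$structure)
  if (length(missing) > 0) {
    stop("summaries incomplete; missing structure(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- summaries[match(wanted, summaries$structure), , drop = FALSE]
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  do.call(rbind, lapply(mp_contrasts(), function(cc) {
    m <- rows[[paste0(cc, "_mean")]]
    data.frame(contrast = cc, mean = mean(m), sd = sd_pop(m),
               n_structures = length(m), stringsAsFactors = FALSE)
  }))
}

#' Pooled voxel-wise Pearson correlation between two contrasts
#'
#' Pools the voxels of all supplied blocks (across structures and subjects,
#' ignoring structure identity) and computes Pearson's r with a two-sided
#' p-value from the t transform with `n - 2` degrees of freedom.
#'
#' @param blocks List of `voxel_block`s.
#' @param pair Character vector of two contrasts, e.g. `c("t1", "na")`.
#' @return List of class `correlation_result` with `pair`, `r`, `p`, `n`.
#' @export
pooled_correlation <- function(blocks, pair = c("t1", "na")) {
  stopifnot(length(pair) == 2, all(pair %in% mp_contrasts()))
  x <- unlist(lapply(blocks, function(b) b$values[[pair[1]]]),
              use.names = FALSE)
  y <- unlist(lapply(blocks, function(b) b$values[[pair[2]]]),
              use.names = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pooled voxels", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in contrast '",
         pair[c(var(x) == 0, var(y) == 0)][1],
         "'; correlation undefined", call. = FALSE)
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  structure(list(pair = pair, r = r, p = p, n = n),
            class = "correlation_result")
}

#' All pairwise pooled correlations
#'
#' @param blocks List of `voxel_block`s.
#' @return Data frame with one row per unordered contrast pair.
#' @export
pooled_correlation_matrix <- function(blocks) {
  pairs <- combn(mp_contrasts(), 2)
  do.call(rbind, apply(pairs, 2, function(p) {
    res <- pooled_correlation(blocks, p)
    data.frame(contrast_a = p[1], contrast_b = p[2], r = res$r, p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  }))
}
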