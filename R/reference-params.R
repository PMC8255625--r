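#' MR contrasts handled by the package
#'
#' The four quantitative contrasts, in canonical order: `"qsm"` (magnetic
#' susceptibility chi, ppm), `"na"` (tissue sodium concentration, mmol/l),
#' `"mtr"` (magnetization transfer ratio, percentage units) and `"t1"`
#' (longitudinal relaxation time, ms).
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' mp_contrasts()
mp_contrasts <- function() {
  c("qsm", "na", "mtr", "t1")
}

#' Physical units of each contrast
#'
#' @return Named character vector mapping contrast code to unit string.
#' @export
contrast_units <- function() {
  c(qsm = "ppm", na = "mmol/l", mtr = "p.u.", t1 = "ms")
}

#' Functional groups of subcortical structures
#'
#' @return Character vector with the five group codes: `"epi_thalamic"`
#'   (geniculate bodies, pulvinar, habenula), `"aras"` (ascending reticular
#'   activating system), `"limbic"`, `"extrapyramidal"` and `"fiber_tract"`.
#' @export
functional_groups <- function() {
  c("epi_thalamic", "aras", "limbic", "extrapyramidal", "fiber_tract")
}

#' Load the packaged per-nucleus reference statistics
#'
#' Reads the packaged table of 21 subcortical structures (19 nuclei and 2
#' fiber tracts) with their functional group and the per-contrast population
#' mean and standard deviation: susceptibility (ppm), sodium concentration
#' (mmol/l), MTR (p.u.) and T1 (ms). These values parameterize the synthetic
#' cohort generator and serve as the reference surface for the descriptive
#' analyses.
#'
#' @param path Path to a tab-separated reference table. Defaults to the file
#'   shipped with the package.
#' @return A data frame of class `nucleus_reference` with columns
#'   `structure` (canonical abbreviation), `name`, `group`, and
#'   `<contrast>_mean` / `<contrast>_sd` for each of the four contrasts.
#' @export
#' @examples
#' specs <- load_reference_params()
#' specs[specs$structure == "Pal", c("qsm_mean", "qsm_sd")]
load_reference_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nucleus_reference.tsv", package = "mpmri")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("reference parameter table not found; the package installation ",
         "appears to be incomplete", call. = FALSE)
  }
  specs <- read.delim(path, stringsAsFactors = FALSE)
  validate_reference_params(specs)
  class(specs) <- c("nucleus_reference", "data.frame")
  specs
}

validate_reference_params <- function(specs) {
  needed <- c("structure", "name", "group",
              paste0(rep(mp_contrasts(), each = 2), c("_mean", "_sd")))
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols) > 0) {
    stop("corrupt reference table: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(specs$structure)) {
    stop("corrupt reference table: duplicated structure abbreviations",
         call. = FALSE)
  }
  if (!all(specs$group %in% functional_groups())) {
    stop("corrupt reference table: unknown functional group(s) ",
         paste(setdiff(specs$group, functional_groups()), collapse = ", "),
         call. = FALSE)
  }
  sd_cols <- paste0(mp_contrasts(), "_sd")
  vals <- as.matrix(specs[, c(paste0(mp_contrasts(), "_mean"), sd_cols)])
  if (any(!is.finite(vals))) {
    stop("corrupt reference table: non-finite values", call. = FALSE)
  }
  if (any(vals[, sd_cols] < 0)) {
    stop("corrupt reference table: negative standard deviation", call. = FALSE)
  }
  invisible(specs)
}

#' Structures excluded from classification by default
#'
#' The mammillary body, locus coeruleus and habenula lie immediately adjacent
#' to CSF and are strongly affected by partial volume at the low resolution of
#' sodium imaging; they are excluded from the automated classification tasks.
#'
#' @return Character vector of structure abbreviations.
#' @export
default_excluded_structures <- function() {
  c("MB", "LC", "HB")
}
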