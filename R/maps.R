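#' Quantitative map container
#'
#' @param values 3D numeric volume.
#' @param contrast One of [mp_contrasts()].
#' @param mask Logical volume of valid voxels (same shape as `values`).
#' @return A list of class `quant_map` with fields `values`, `contrast`,
#'   `units` and `mask`. Values are guaranteed finite wherever `mask` is TRUE.
#' @export
quant_map <- function(values, contrast, mask = NULL) {
  contrast <- match.arg(contrast, mp_contrasts())
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  if (!all(dim(mask) == dim(values))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match value shape ", paste(dim(values), collapse = "x"),
         call. = FALSE)
  }
  if (any(!is.finite(values[mask]))) {
    stop("non-finite values inside the valid mask", call. = FALSE)
  }
  structure(list(values = values, contrast = contrast,
                 units = unname(contrast_units()[contrast]), mask = mask),
            class = "quant_map")
}

#' @export
as.array.quant_map <- function(x, ...) x$values

# Accept either a bare array or a quant_map.
map_values <- function(x) if (inherits(x, "quant_map")) x$values else x

#' Compute a magnetization transfer ratio map
#'
#' `MTR = (m0 - msat) / m0 * 100`, voxel-wise, in percentage units, where
#' `m0` is the non-MT-saturated and `msat` the MT-saturated magnitude volume.
#' Voxels outside the mask (or with non-positive `m0`) are flagged invalid
#' (`NA` in the returned values). MTR values outside `[-100, 100]` are
#' retained, not clipped; a message is emitted if they exceed 1% of valid
#' voxels.
#'
#' @param m0 Non-saturated magnitude volume (array or `quant_map`).
#' @param msat MT-saturated magnitude volume, same shape.
#' @param mask Optional logical volume; defaults to `m0 > 0`.
#' @return A [quant_map()] with contrast `"mtr"`.
#' @export
#' @examples
#' m0 <- array(100, c(2, 2, 1)); msat <- array(78, c(2, 2, 1))
#' compute_mtr(m0, msat)$values[1, 1, 1]  # 22 p.u.
compute_mtr <- function(m0, msat, mask = NULL) {
  m0 <- map_values(m0); msat <- map_values(msat)
  if (!all(dim(m0) == dim(msat))) {
    stop("m0 shape ", paste(dim(m0), collapse = "x"),
         " does not match msat shape ", paste(dim(msat), collapse = "x"),
         call. = FALSE)
  }
  if (is.null(mask)) mask <- m0 > 0
  if (!all(dim(mask) == dim(m0))) {
    stop("mask shape does not match volume shape", call. = FALSE)
  }
  bad <- mask & !(m0 > 0)
  if (any(bad)) {
    warning(sum(bad), " masked voxel(s) with non-positive m0 invalidated",
            call. = FALSE)
    mask <- mask & !bad
  }
  values <- array(NA_real_, dim = dim(m0))
  values[mask] <- (m0[mask] - msat[mask]) / m0[mask] * 100
  out_of_range <- sum(abs(values[mask]) > 100)
  if (out_of_range > 0.01 * sum(mask)) {
    message("compute_mtr: ", out_of_range, " voxels (> 1%) outside ",
            "[-100, 100] p.u.; retained unclipped")
  }
  quant_map(values, "mtr", mask)
}

#' Reference a sodium volume to physiological CSF concentration
#'
#' Rescales a raw sodium volume so that its mean over the CSF mask equals the
#' physiological concentration of 140 mmol/l. The arithmetic mean over all
#' mask voxels is used, untrimmed. The operation is idempotent: referencing an
#' already-referenced map leaves it unchanged.
#'
#' @param raw Raw sodium volume (array or `quant_map`), arbitrary scale.
#' @param csf_mask Logical volume marking CSF voxels.
#' @param target CSF reference concentration in mmol/l (default 140).
#' @return A [quant_map()] with contrast `"na"` whose CSF mean is exactly
#'   `target` (to machine precision).
#' @export
reference_sodium <- function(raw, csf_mask, target = 140) {
  raw <- map_values(raw)
  if (!all(dim(csf_mask) == dim(raw))) {
    stop("csf_mask shape does not match volume shape", call. = FALSE)
  }
  if (!any(csf_mask)) stop("empty CSF mask", call. = FALSE)
  csf_mean <- mean(raw[csf_mask])
  if (!is.finite(csf_mean) || csf_mean <= 0) {
    stop("non-positive CSF mean (", format(csf_mean),
         "); cannot reference sodium", call. = FALSE)
  }
  quant_map(raw * (target / csf_mean), "na")
}
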