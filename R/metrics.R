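## Muscle measurements from a PDFF/T2* map and a segmentation mask.
##
## Volumes use the full mask (voxel count x voxel volume, no interpolation);
## the mean PDFF uses the T2*-filtered mask only, mirroring a post-processing
## step that removes voxels with implausible T2* (bone, artefact) from the
## PDFF analysis without touching the volumetry. Fat volume is
## (mean PDFF / 100) x total volume and contractile volume is the remainder,
## so the two sum back to the total at machine precision.

#' Exclude voxels with implausible T2* from the PDFF analysis
#'
#' Retains in-mask voxels whose T2* lies in `[low, high]` ms (boundaries
#' inclusive) and is valid; voxels below `low` or above `high` — typically
#' bone fragments or susceptibility artefacts — are dropped. The input mask
#' is not modified.
#'
#' @param mask A [muscle_mask()].
#' @param t2star_map 3D numeric array of T2* in ms, same shape as the mask;
#'   `NA` marks invalid estimates (also dropped).
#' @param low,high Retention bounds in ms (defaults 5 and 100).
#' @return A new `muscle_mask` restricted to retained voxels. When nothing
#'   survives, an all-`FALSE` mask is returned with attribute `"empty" = TRUE`
#'   and a warning: downstream mean PDFF is then undefined.
#' @export
apply_t2star_filter <- function(mask, t2star_map, low = 5, high = 100) {
  stopifnot(inherits(mask, "muscle_mask"))
  if (!identical(dim(t2star_map), dim(mask$voxels)))
    stop("'t2star_map' shape must match the mask")
  if (!is.numeric(low) || !is.numeric(high) || low > high)
    stop("need low <= high (ms)")
  keep <- mask$voxels & !is.na(t2star_map) &
    t2star_map >= low & t2star_map <= high
  if (!any(keep)) {
    warning("T2* filter removed every voxel; mean PDFF will be undefined")
    out <- mask
    out$voxels <- keep
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- mask
  out$voxels <- keep
  attr(out, "empty") <- FALSE
  out
}

#' Contractile tissue volume
#'
#' The functional muscle component: total muscle volume minus muscle fat
#' volume.
#'
#' @param total_ml Total muscle volume, mL.
#' @param fat_ml Muscle fat volume, mL; must satisfy `0 <= fat <= total`.
#' @return Contractile tissue volume in mL.
#' @examples
#' compute_contractile_volume(294.1, 28.5)  # 265.6
#' @export
compute_contractile_volume <- function(total_ml, fat_ml) {
  if (any(!is.finite(total_ml)) || any(!is.finite(fat_ml)))
    stop("volumes must be finite")
  if (any(fat_ml < 0) || any(total_ml < 0)) stop("volumes must be >= 0")
  if (any(fat_ml > total_ml)) stop("fat volume cannot exceed total volume")
  total_ml - fat_ml
}

#' Muscle metrics from a PDFF map and mask
#'
#' Computes the standard muscle-composition record: total volume from the
#' full mask's voxel count, mean PDFF over the T2*-filtered mask, fat volume
#' as `mean PDFF / 100 * total volume` and contractile volume as the
#' difference.
#'
#' @param pdff_map 3D numeric array of PDFF in %.
#' @param mask Full [muscle_mask()] (defines the volumetry).
#' @param filtered_mask Mask after [apply_t2star_filter()]; must be a subset
#'   of `mask`. Defaults to `mask` (no filtering).
#' @return A list of class `muscle_metrics`: `mean_pdff` (%), `total_volume`,
#'   `fat_volume`, `contractile_volume` (mL), `n_voxels_total`,
#'   `n_voxels_pdff_valid`.
#' @examples
#' pd <- array(10, c(10, 10, 10))
#' m <- muscle_mask(array(TRUE, c(10, 10, 10)), c(3, 3, 6))
#' compute_metrics(pd, m)  # 54 mL total, 5.4 mL fat
#' @export
compute_metrics <- function(pdff_map, mask, filtered_mask = mask) {
  stopifnot(inherits(mask, "muscle_mask"))
  if (!identical(dim(pdff_map), dim(mask$voxels)))
    stop("'pdff_map' shape must match the mask")
  if (!identical(dim(filtered_mask$voxels), dim(mask$voxels)))
    stop("'filtered_mask' shape must match the mask")
  if (any(filtered_mask$voxels & !mask$voxels))
    stop("'filtered_mask' must be a subset of 'mask'")
  n_total <- sum(mask$voxels)
  if (n_total == 0) stop("mask is empty")
  n_valid <- sum(filtered_mask$voxels)
  if (n_valid == 0)
    stop("filtered mask is empty: mean PDFF undefined after T2* filtering")
  total_ml <- n_total * voxel_volume_ml(mask$voxel_spacing)
  mean_pdff <- mean(pdff_map[filtered_mask$voxels])
  if (is.na(mean_pdff) || mean_pdff < 0 || mean_pdff > 100)
    stop("mean PDFF outside [0, 100]: check the PDFF map")
  fat_ml <- mean_pdff / 100 * total_ml
  structure(
    list(mean_pdff = mean_pdff,
         total_volume = total_ml,
         fat_volume = fat_ml,
         contractile_volume = compute_contractile_volume(total_ml, fat_ml),
         n_voxels_total = n_total,
         n_voxels_pdff_valid = n_valid),
    class = "muscle_metrics")
}

#' @export
print.muscle_metrics <- function(x, ...) {
  cat(sprintf(
    "<muscle_metrics> PDFF %.2f%%, total %.1f mL, fat %.1f mL, contractile %.1f mL (%d voxels, %d PDFF-valid)\n",
    x$mean_pdff, x$total_volume, x$fat_volume, x$contractile_volume,
    x$n_voxels_total, x$n_voxels_pdff_valid))
  invisible(x)
}

#' Convert muscle metrics to a one-row data frame
#'
#' @param x A `muscle_metrics` object.
#' @param row.names,optional,... Passed through for S3 consistency; unused.
#' @return A one-row `data.frame` with the metric columns.
#' @export
as.data.frame.muscle_metrics <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(mean_pdff_pct = x$mean_pdff,
             total_ml = x$total_volume,
             fat_ml = x$fat_volume,
             contractile_ml = x$contractile_volume,
             n_voxels = x$n_voxels_total,
             n_voxels_pdff = x$n_voxels_pdff_valid)
}
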