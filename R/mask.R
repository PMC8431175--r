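#' Labelled 3D muscle segmentation mask
#'
#' Wraps a binary 3D voxel mask together with its voxel spacing and an
#' anatomical annotation of the inferior-superior axis: which array axis runs
#' along the muscle and which end of it is proximal (towards the muscle's
#' origin).
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @param voxel_spacing Numeric length-3 voxel size in mm.
#' @param axis Which array dimension (1, 2 or 3) is the inferior-superior
#'   (lengthwise) axis.
#' @param proximal_end `"first"` if slice index 1 along `axis` is the proximal
#'   end, `"last"` otherwise.
#' @param label Optional muscle name (e.g. `"psoas"`).
#' @return An object of class `muscle_mask`.
#' @export
muscle_mask <- function(voxels, voxel_spacing, axis = 3L,
                        proximal_end = c("first", "last"), label = NULL) {
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array")
  v <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(v)) stop("'voxels' must not contain NA")
  if (!any(v)) stop("mask is empty")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("'voxel_spacing' must be three positive values (mm)")
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("'axis' must be 1, 2 or 3")
  proximal_end <- match.arg(proximal_end)
  structure(
    list(voxels = v, voxel_spacing = voxel_spacing, axis = axis,
         proximal_end = proximal_end, label = label),
    class = "muscle_mask"
  )
}

#' @export
print.muscle_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<muscle_mask>%s %d x %d x %d, %d voxels, axis %d (%s end proximal)\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    d[1], d[2], d[3], sum(x$voxels), x$axis, x$proximal_end))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A [muscle_mask()].
#' @return Integer voxel count.
#' @export
mask_n_voxels <- function(mask) {
  stopifnot(inherits(mask, "muscle_mask"))
  sum(mask$voxels)
}

# volume of one voxel in mL (mm^3 / 1000)
voxel_volume_ml <- function(voxel_spacing) prod(voxel_spacing) / 1000
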