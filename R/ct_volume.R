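# Voxel containers. Volumes are axis-aligned; world coordinates of voxel
# (i, j, k) (0-based) are origin + c(i, j, k) * spacing, in the room frame
# (x = LR, y = AP, z = SI). Voxel values are Hounsfield units.

#' CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units, dims (nx, ny, nz)
#' @param spacing voxel spacing in mm, length 3 (`spacing[3]` is the slice
#'   thickness)
#' @param origin world position (mm) of the center of voxel (0, 0, 0)
#' @param phase respiratory phase index (0-based), or `NA`
#' @return a `ct_volume`
#' @export
ct_volume <- function(voxels, spacing, origin, phase = NA_integer_) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, all(is.finite(voxels)))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "ct_volume")
}

#' Binary GTV mask aligned to a CT volume
#'
#' @param mask 3D logical (or 0/1) array with the same dims as its volume
#' @param spacing,origin as in [ct_volume()]
#' @param phase respiratory phase index
#' @return a `gtv_mask`
#' @export
gtv_mask <- function(mask, spacing, origin, phase = NA_integer_) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("GTV mask is empty")
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "gtv_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume %s, spacing %s mm, HU range [%g, %g], phase %s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels), x$phase))
  invisible(x)
}

# world coordinates of voxel centers along each axis
voxel_axes <- function(vol) {
  d <- dim(if (!is.null(vol$voxels)) vol$voxels else vol$mask)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Voxel-weighted centroid of a mask (world mm)
#' @param m a `gtv_mask`
#' @return 3-vector, mm
#' @export
mask_centroid_3d <- function(m) {
  stopifnot(inherits(m, "gtv_mask"))
  idx <- which(m$mask, arr.ind = TRUE) - 1   # 0-based
  m$origin + colMeans(idx) * m$spacing
}

#' Mask volume in cm^3
#' @param m a `gtv_mask`
#' @return volume in cubic centimeters
#' @export
mask_volume_cm3 <- function(m) {
  sum(m$mask) * prod(m$spacing) / 1000
}

#' Keep only the GTV's attenuation in a CT volume
#'
#' Voxels inside the mask keep their HU; everything outside is set to air
#' (-1000 HU) so that a DRR of the result shows the GTV footprint alone.
#' Idempotent.
#'
#' @param volume a [ct_volume()]
#' @param mask a [gtv_mask()] with the same dims
#' @return a `ct_volume`
#' @export
gtv_only_volume <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "gtv_mask"))
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    stop("volume and mask shapes differ")
  v <- volume$voxels
  v[!mask$mask] <- -1000
  ct_volume(v, volume$spacing, volume$origin, volume$phase)
}
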