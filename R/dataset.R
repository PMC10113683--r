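# Training-set factory: for one patient and one tube angle, render paired
# original / GTV-only DRRs under a grid of small SI/AP beam-angle
# perturbations, extract the GTV silhouette mask from the GTV-only DRR and
# overlay it on the original DRR as an instance label. With the default
# +/-3.5 deg grid at 0.5 deg steps (15 x 15 = 225 geometries) and a 10-phase
# 4DCT this yields 2250 labeled samples per tube angle.

#' Angle-perturbation grid
#'
#' Inclusive Cartesian grid over SI and AP tilt angles, built from integer
#' multiples of the step to avoid floating-point accumulation.
#'
#' @param range_deg half-range in degrees (default 3.5)
#' @param step_deg step in degrees (default 0.5); `range_deg` must be an
#'   integer multiple
#' @return a `perturbation_grid` with a data frame `entries`
#'   (`perturb_si`, `perturb_ap`), symmetric about and containing (0, 0)
#' @export
make_grid <- function(range_deg = 3.5, step_deg = 0.5) {
  stopifnot(step_deg > 0, range_deg >= 0)
  k <- range_deg / step_deg
  if (abs(k - round(k)) > 1e-9)
    stop("range_deg must be an integer multiple of step_deg")
  vals <- (-round(k):round(k)) * step_deg
  entries <- expand.grid(perturb_si = vals, perturb_ap = vals,
                         KEEP.OUT.ATTRS = FALSE)
  structure(list(range_deg = range_deg, step_deg = step_deg,
                 entries = entries),
            class = "perturbation_grid")
}

#' @export
print.perturbation_grid <- function(x, ...) {
  cat(sprintf("perturbation_grid: +/-%g deg @ %g deg, %d entries\n",
              x$range_deg, x$step_deg, nrow(x$entries)))
  invisible(x)
}

#' GTV silhouette mask from a GTV-only DRR
#'
#' Pixels with a strictly positive radiological path (`path > eps`) are the
#' tumor footprint; if the silhouette splits into several connected
#' components only the largest is kept (single-GTV assumption). An empty
#' silhouette (GTV outside the field of view) signals an invalid sample via
#' a condition of class `"orthotrack_sample_invalid"`.
#'
#' @param gtv_drr a `projection_image` rendered from a GTV-only volume
#' @param eps path threshold (default 1e-6)
#' @return logical matrix, same shape as the projection
#' @export
gtv_mask_from_gtv_drr <- function(gtv_drr, eps = 1e-6) {
  stopifnot(inherits(gtv_drr, "projection_image"))
  m <- gtv_drr$path > eps
  if (!any(m))
    stop(structure(class = c("orthotrack_sample_invalid", "error", "condition"),
                   list(message = "empty GTV silhouette (outside field of view)",
                        call = sys.call())))
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    m <- lab == which.max(counts)
  }
  matrix(as.logical(m), nrow(gtv_drr$path), ncol(gtv_drr$path))
}

#' Outer boundary polygon of a binary mask
#'
#' Counterclockwise vertices in 0-based (u, v) pixel coordinates of the
#' mask's largest component boundary.
#'
#' @param mask logical matrix
#' @return n x 2 matrix of (u, v) vertices
#' @export
mask_boundary_polygon <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  oc <- EBImage::ocontour(lab)
  poly <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  poly <- poly - 1      # ocontour is 1-based
  if (nrow(poly) < 3) {
    # tiny (1-2 px) component: fall back to the half-pixel-outset bounding box
    idx <- which(mask, arr.ind = TRUE) - 1
    u0 <- min(idx[, 1]) - 0.5; u1 <- max(idx[, 1]) + 0.5
    v0 <- min(idx[, 2]) - 0.5; v1 <- max(idx[, 2]) + 0.5
    poly <- cbind(c(u0, u1, u1, u0), c(v0, v0, v1, v1))
  }
  # enforce counterclockwise orientation (positive shoelace area)
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  a2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  if (a2 < 0) poly <- poly[n:1, , drop = FALSE]
  colnames(poly) <- c("u", "v")
  poly
}

#' Build the labeled training set for one tube angle
#'
#' One sample per (phase x grid entry): the original-volume DRR and the
#' GTV-only DRR are rendered under the same perturbed geometry, the GTV mask
#' is extracted from the GTV-only DRR and its boundary polygon traced.
#' Invalid samples (GTV out of view) are excluded with a warning.
#'
#' @param phases list of per-phase lists with elements `volume`
#'   ([ct_volume()]) and `mask` ([gtv_mask()]); a `phantom4d$phases` works
#'   directly
#' @param tube_angle tube angle in degrees
#' @param grid a [make_grid()] result
#' @param panel a [panel_spec()]
#' @param downsample rendering downsample factor
#' @param mu_water see [hu_to_mu()]
#' @return list of `labeled_sample`: `image` (original-volume DRR),
#'   `gtv_mask`, `gtv_polygon`, `phase`, `perturbation`, `tube_angle`
#' @export
build_training_set <- function(phases, tube_angle, grid = make_grid(),
                               panel = panel_spec(), downsample = 1L,
                               mu_water = 0.02) {
  stopifnot(length(phases) >= 1, inherits(grid, "perturbation_grid"))
  gtv_vols <- lapply(phases, function(p) gtv_only_volume(p$volume, p$mask))
  samples <- list()
  for (pi in seq_along(phases)) {
    for (gi in seq_len(nrow(grid$entries))) {
      si <- grid$entries$perturb_si[gi]
      ap <- grid$entries$perturb_ap[gi]
      geom <- build_geometry(tube_angle, si, ap, panel)
      drr <- render_drr(phases[[pi]]$volume, geom, downsample, mu_water)
      gtv_drr <- render_drr(gtv_vols[[pi]], geom, downsample, mu_water)
      msk <- tryCatch(gtv_mask_from_gtv_drr(gtv_drr),
                      orthotrack_sample_invalid = function(e) NULL)
      if (is.null(msk)) {
        warning(sprintf(
          "sample excluded (GTV out of view): phase %d, perturbation (%g, %g)",
          pi - 1, si, ap))
        next
      }
      samples[[length(samples) + 1L]] <- structure(list(
        image = drr, gtv_mask = msk,
        gtv_polygon = mask_boundary_polygon(msk),
        phase = pi - 1L, perturbation = c(si = si, ap = ap),
        tube_angle = geom$tube_angle
      ), class = "labeled_sample")
    }
  }
  samples
}

#' Export labeled samples as COCO-style instance-segmentation annotations
#'
#' Writes 8-bit PNG images and a single JSON annotation file with one
#' category (`"GTV"`), one image record and one annotation per sample.
#' Round-trips losslessly through [import_annotations()].
#'
#' @param samples non-empty list of `labeled_sample`
#' @param directory output directory
#' @return invisibly, the annotation file path
#' @export
export_annotations <- function(samples, directory) {
  if (length(samples) == 0) stop("no samples to export")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  images <- vector("list", length(samples))
  annotations <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fn <- sprintf("sample_%05d.png", i)
    # PNG rows are v, columns u; display is (u, v) so transpose
    png::writePNG(t(s$image$display) / 255, file.path(directory, fn))
    poly <- s$gtv_polygon
    bbox <- c(min(poly[, 1]), min(poly[, 2]),
              diff(range(poly[, 1])), diff(range(poly[, 2])))
    images[[i]] <- list(id = i, file_name = fn,
                        width = nrow(s$image$path), height = ncol(s$image$path),
                        phase = s$phase,
                        perturb_si = unname(s$perturbation["si"]),
                        perturb_ap = unname(s$perturbation["ap"]),
                        tube_angle = s$tube_angle)
    annotations[[i]] <- list(id = i, image_id = i, category_id = 1L,
                             segmentation = list(as.numeric(t(poly))),
                             bbox = bbox, area = sum(s$gtv_mask),
                             iscrowd = 0L)
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "GTV",
                                      supercategory = "tumor")))
  path <- file.path(directory, "annotations.json")
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a COCO-style annotation file
#' @param path annotation JSON path
#' @return the parsed annotation list (images, annotations, categories)
#' @export
import_annotations <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
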