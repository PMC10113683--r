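# DRR rendering: radiological path integrals by Siddon ray traversal through
# the HU volume mapped to linear attenuation. No scatter, no beam hardening,
# no detector physics -- a pixel holds the bare line integral of mu (mm^-1 *
# mm, dimensionless), plus an 8-bit display mapping for visual use.

#' Hounsfield units to linear attenuation coefficient
#'
#' Single-energy water-scaled map: `mu = mu_water * (1 + hu/1000)`, clamped
#' at zero. The default `mu_water = 0.02` per mm corresponds to roughly
#' 70 keV; it scales contrast only, never geometry.
#'
#' @param hu Hounsfield units (vectorized)
#' @param mu_water attenuation of water, mm^-1
#' @return attenuation in mm^-1, `>= 0`
#' @export
hu_to_mu <- function(hu, mu_water = 0.02) {
  pmax(mu_water * (1 + hu / 1000), 0)
}

#' Radiological path of a ray through a CT volume
#'
#' Exact sum of `mu_i * l_i` over the voxels traversed between the ray's
#' entry into and exit from the volume bounding box (Siddon parametric
#' traversal); 0 if the ray misses the volume.
#'
#' @param volume a [ct_volume()]
#' @param ray a [make_ray()] / [ray_through_pixel()] result
#' @param mu_water see [hu_to_mu()]
#' @return dimensionless path integral
#' @export
radiological_path <- function(volume, ray, mu_water = 0.02) {
  stopifnot(inherits(volume, "ct_volume"), inherits(ray, "ray"))
  mu <- hu_to_mu(volume$voxels, mu_water)
  .siddon_path_cpp(as.numeric(mu), dim(volume$voxels),
                   volume$origin, volume$spacing,
                   ray$origin, ray$direction)
}

#' Render a DRR
#'
#' One radiological path per pixel center. With `downsample = d` the panel is
#' rendered as an `(n_u/d) x (n_v/d)` grid whose pixel centers are the centers
#' of `d x d` blocks of physical pixels (effective pitch `d * pixel_pitch`).
#'
#' @param volume a [ct_volume()]
#' @param geom an `imaging_geometry`
#' @param downsample integer >= 1 dividing both `n_u` and `n_v`
#' @param mu_water see [hu_to_mu()]
#' @return a `projection_image`: list with `path` (nu x nv matrix, u fastest),
#'   `display` (8-bit integer matrix, `exp(-path)` min-max rescaled),
#'   `geometry`, `downsample`, `pixel_pitch_eff`, `phase_or_timestamp`
#' @export
render_drr <- function(volume, geom, downsample = 1L, mu_water = 0.02) {
  stopifnot(inherits(volume, "ct_volume"), inherits(geom, "imaging_geometry"))
  downsample <- as.integer(downsample)
  if (downsample < 1 || geom$n_u %% downsample != 0 || geom$n_v %% downsample != 0)
    stop("downsample must be >= 1 and divide both panel dimensions")
  nu <- geom$n_u %/% downsample
  nv <- geom$n_v %/% downsample
  pitch_eff <- geom$pixel_pitch * downsample
  # effective pixel (0,0) center = center of the first d x d physical block
  det00 <- panel_point(geom, (downsample - 1) / 2, (downsample - 1) / 2)
  mu <- hu_to_mu(volume$voxels, mu_water)
  path <- .render_drr_cpp(as.numeric(mu), dim(volume$voxels),
                          volume$origin, volume$spacing, geom$source,
                          det00,
                          pitch_eff * geom$u_axis, pitch_eff * geom$v_axis,
                          nu, nv)
  projection_image(path, geom, downsample,
                   phase_or_timestamp = volume$phase)
}

#' Construct a projection image from a path matrix
#' @param path nu x nv matrix of radiological paths (dimensionless, >= 0)
#' @param geometry the `imaging_geometry` it was rendered under
#' @param downsample the downsampling factor used
#' @param phase_or_timestamp phase index or acquisition timestamp
#' @return a `projection_image`
#' @export
projection_image <- function(path, geometry, downsample = 1L,
                             phase_or_timestamp = NA) {
  stopifnot(is.matrix(path), all(path >= 0))
  structure(list(path = path,
                 display = path_to_display(path),
                 geometry = geometry,
                 downsample = as.integer(downsample),
                 pixel_pitch_eff = geometry$pixel_pitch * downsample,
                 phase_or_timestamp = phase_or_timestamp),
            class = "projection_image")
}

# 8-bit display: transmitted intensity exp(-path), min-max rescaled per image
path_to_display <- function(path) {
  I <- exp(-path)
  rng <- range(I)
  if (diff(rng) < .Machine$double.eps) {
    matrix(0L, nrow(path), ncol(path))
  } else {
    matrix(as.integer(round(255 * (I - rng[1]) / diff(rng))),
           nrow(path), ncol(path))
  }
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf(
    "projection_image %dx%d px (downsample %d), tube %.1f deg, path range [%.3g, %.3g]\n",
    nrow(x$path), ncol(x$path), x$downsample,
    x$geometry$tube_angle, min(x$path), max(x$path)))
  invisible(x)
}

#' Pixel scale of a projection image at the isocenter plane
#' @param img a `projection_image`
#' @return mm per (rendered) pixel at the isocenter
#' @export
projection_pixel_scale <- function(img) {
  img$pixel_pitch_eff * img$geometry$sid / img$geometry$sdd
}

#' Gaussian prefilter of a projection image
#'
#' Blurs the display grid with an isotropic 2D Gaussian to emulate a coarser
#' imaging resolution (e.g. to match clinical projection images to the DRR
#' resolution before prediction). `sigma_mm` is converted to pixels with the
#' image's effective panel pitch; `sigma_mm = 0` is the identity. The kernel
#' is an explicitly truncated (4 sigma) normalized sampled Gaussian;
#' replicate border handling.
#'
#' @param image a `projection_image`
#' @param sigma_mm Gaussian sigma at the panel, mm, `>= 0`
#' @return a `projection_image` with filtered `display` (and `path` filtered
#'   identically, so downstream thresholds stay meaningful)
#' @export
gaussian_prefilter <- function(image, sigma_mm) {
  stopifnot(inherits(image, "projection_image"))
  if (sigma_mm < 0) stop("sigma must be non-negative")
  if (sigma_mm == 0) return(image)
  sigma_px <- sigma_mm / image$pixel_pitch_eff
  k <- gaussian_kernel_2d(sigma_px)
  out <- image
  out$path <- conv2_replicate(image$path, k)
  out$display <- matrix(
    as.integer(round(conv2_replicate(image$display + 0, k))),
    nrow(image$display), ncol(image$display))
  out
}

#' Sampled, truncated, normalized 2D Gaussian kernel
#' @param sigma_px sigma in pixels
#' @param truncate kernel half-width in sigmas (default 4)
#' @return odd-sized square matrix summing to 1
#' @export
gaussian_kernel_2d <- function(sigma_px, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma_px))
  g <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2D convolution with replicate padding (EBImage filter2 does the heavy work)
conv2_replicate <- function(x, k) {
  y <- EBImage::filter2(x, k, boundary = "replicate")
  matrix(as.numeric(y), nrow(x), ncol(x))
}
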