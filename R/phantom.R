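# Synthetic 10-phase breathing-thorax phantom: a body ellipsoid enclosing two
# lung ellipsoids, a tumor (GTV) ellipsoid moving along a fixed displacement
# vector with a cos^power respiratory waveform, and optional gold fiducial
# markers rigidly co-moving with the tumor. Ground truth (GTV center, marker
# positions) is analytic, so every downstream stage can be scored exactly.

#' Respiratory displacement fraction for a phase
#'
#' `w(p) = ((1 - cos(2*pi*p/n)) / 2)^power`: 0 at the end-exhale reference
#' phase 0, 1 at mid-cycle. `power = 2` gives the characteristic end-exhale
#' dwell of free breathing.
#'
#' @param phase 0-based phase index (vectorized)
#' @param n_phases number of phases in the cycle (default 10)
#' @param power waveform exponent (default 2)
#' @return displacement fraction(s) in `[0, 1]`
#' @export
breathing_displacement <- function(phase, n_phases = 10, power = 2) {
  stopifnot(all(phase >= 0), all(phase < n_phases))
  ((1 - cos(2 * pi * phase / n_phases)) / 2)^power
}

#' Phantom specification
#'
#' Defaults emulate the reported lung-SBRT cohort: a spherical GTV of
#' 7.42 cm^3 (the cohort median; semi-axis 12.1 mm), mean GTV HU of -176
#' (a mid-cohort value), a 22 mm 3D motion range dominated by the SI
#' direction, 10 respiratory phases, and 3 implanted markers.
#'
#' @param grid_shape voxel counts, length 3 (default 128 x 128 x 96)
#' @param spacing_mm voxel spacing, length 3 (default 2 mm isotropic,
#'   matching the clinical 2-2.5 mm slice thickness)
#' @param body_hu,lung_hu,tumor_hu Hounsfield units of the three tissues
#' @param tumor_semi_axes_mm GTV ellipsoid semi-axes (mm)
#' @param tumor_center_ref_mm GTV center at the reference (end-exhale) phase
#' @param motion_vector_mm peak-to-peak displacement vector; the 3D motion
#'   range is its norm
#' @param n_phases respiratory phases per cycle
#' @param waveform_power exponent of the cos-power waveform
#' @param marker_offsets_mm list of 3-vectors: marker centers relative to the
#'   tumor center (rigid co-motion); 0-5 markers
#' @param marker_radius_mm,marker_hu marker sphere size and HU
#' @param rng_seed seed recorded in the spec (generation is deterministic)
#' @return a `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 96L),
                         spacing_mm = c(2, 2, 2),
                         body_hu = 0, lung_hu = -750, tumor_hu = -176,
                         tumor_semi_axes_mm = c(12.1, 12.1, 12.1),
                         tumor_center_ref_mm = c(-50, 10, -30),
                         motion_vector_mm = c(2, 5, sqrt(22^2 - 2^2 - 5^2)),
                         n_phases = 10L,
                         waveform_power = 2,
                         marker_offsets_mm = list(c(16, 0, 0), c(-12, 10, 6),
                                                  c(0, -14, -9)),
                         marker_radius_mm = 2, marker_hu = 3000,
                         rng_seed = 1L) {
  stopifnot(n_phases >= 2, all(spacing_mm > 0), all(grid_shape >= 4),
            all(tumor_semi_axes_mm > 0),
            length(marker_offsets_mm) <= 5)
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing_mm),
    body_hu = body_hu, lung_hu = lung_hu, tumor_hu = tumor_hu,
    tumor_semi_axes = as.numeric(tumor_semi_axes_mm),
    tumor_center_ref = as.numeric(tumor_center_ref_mm),
    motion_vector = as.numeric(motion_vector_mm),
    n_phases = as.integer(n_phases), waveform_power = waveform_power,
    marker_offsets = lapply(marker_offsets_mm, as.numeric),
    marker_radius = marker_radius_mm, marker_hu = marker_hu,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
  ext <- (spec$grid_shape - 1) * spec$spacing / 2
  for (p in c(0, which.max(abs(breathing_displacement(
    seq_len(n_phases) - 1, n_phases, waveform_power))) - 1)) {
    ctr <- tumor_center_at_phase(spec, p)
    if (any(abs(ctr) + spec$tumor_semi_axes > ext))
      stop("tumor leaves the grid at phase ", p)
    for (off in spec$marker_offsets)
      if (any(abs(ctr + off) + spec$marker_radius > ext))
        stop("a marker leaves the grid at phase ", p)
  }
  spec
}

#' Analytic tumor center at a phase
#' @param spec a [phantom_spec()]
#' @param phase 0-based phase index
#' @return 3-vector (mm)
#' @export
tumor_center_at_phase <- function(spec, phase) {
  spec$tumor_center_ref +
    breathing_displacement(phase, spec$n_phases, spec$waveform_power) *
      spec$motion_vector
}

# logical mask of an ellipsoid on the voxel grid (voxel-center rule)
ellipsoid_mask <- function(axes_xyz, center, semi) {
  a2 <- ((axes_xyz[[1]] - center[1]) / semi[1])^2
  b2 <- ((axes_xyz[[2]] - center[2]) / semi[2])^2
  c2 <- ((axes_xyz[[3]] - center[3]) / semi[3])^2
  outer(outer(a2, b2, `+`), c2, `+`) <= 1
}

#' Generate the 4D phantom
#'
#' Each phase volume stacks body, lungs, tumor and markers by overwrite (a
#' voxel belongs to a structure iff its center is inside the ellipsoid /
#' sphere; no partial volume). The phantom's grid is centered on the
#' isocenter.
#'
#' @param spec a [phantom_spec()]
#' @return a `phantom4d`: per-phase list with `volume` ([ct_volume()]),
#'   `mask` ([gtv_mask()]), `gtv_centroid` (analytic center, mm) and
#'   `marker_positions` (list of analytic marker centers, mm); plus
#'   `spec` and `reference_phase` (0)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$grid_shape
  origin <- -(sh - 1) * spec$spacing / 2
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(sh[a]) - 1) * spec$spacing[a])
  ext <- (sh - 1) * spec$spacing / 2

  body_semi <- pmin(c(115, 85, 1e6), ext * c(0.95, 0.9, 1e6))
  body <- ellipsoid_mask(axes, c(0, 0, 0), c(body_semi[1], body_semi[2], 1e6))
  lung_semi <- pmin(c(42, 58, 85), body_semi * c(0.45, 0.75, 1))
  lungs <- ellipsoid_mask(axes, c(-52, 5, 0), lung_semi) |
           ellipsoid_mask(axes, c( 52, 5, 0), lung_semi)

  phases <- vector("list", spec$n_phases)
  for (p in seq_len(spec$n_phases) - 1) {
    ctr <- tumor_center_at_phase(spec, p)
    tumor <- ellipsoid_mask(axes, ctr, spec$tumor_semi_axes)
    vox <- array(-1000, sh)
    vox[body] <- spec$body_hu
    vox[body & lungs] <- spec$lung_hu
    vox[tumor] <- spec$tumor_hu
    markers <- lapply(spec$marker_offsets, function(off) ctr + off)
    for (mpos in markers) {
      msk <- ellipsoid_mask(axes, mpos, rep(spec$marker_radius, 3))
      vox[msk] <- spec$marker_hu
    }
    phases[[p + 1]] <- list(
      volume = ct_volume(vox, spec$spacing, origin, phase = p),
      mask = gtv_mask(tumor, spec$spacing, origin, phase = p),
      gtv_centroid = ctr,
      marker_positions = markers
    )
  }
  structure(list(phases = phases, spec = spec, reference_phase = 0L),
            class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  cat(sprintf(
    "phantom4d: %d phases, grid %s @ %s mm, GTV %.2f cm^3, motion %.1f mm, %d markers\n",
    x$spec$n_phases, paste(x$spec$grid_shape, collapse = "x"),
    paste(x$spec$spacing, collapse = "x"),
    4 / 3 * pi * prod(x$spec$tumor_semi_axes) / 1000,
    sqrt(sum(x$spec$motion_vector^2)), length(x$spec$marker_offsets)))
  invisible(x)
}

#' Analytic ground-truth track for a phase sequence
#'
#' @param phantom a `phantom4d`
#' @param phase_sequence data frame with columns `timestamp` and `phase`
#'   (0-based), timestamps strictly increasing
#' @return a `track3d` data frame: `timestamp`, `x`, `y`, `z` (mm),
#'   `source = "analytic"`
#' @export
ground_truth_track <- function(phantom, phase_sequence) {
  stopifnot(inherits(phantom, "phantom4d"),
            all(c("timestamp", "phase") %in% names(phase_sequence)))
  ph <- phase_sequence$phase
  stopifnot(all(ph >= 0), all(ph < phantom$spec$n_phases),
            !is.unsorted(phase_sequence$timestamp, strictly = TRUE))
  pos <- t(vapply(ph, function(p) phantom$phases[[p + 1]]$gtv_centroid,
                  numeric(3)))
  track3d(phase_sequence$timestamp, pos, source = "analytic")
}

#' Timestamped 3D track
#' @param timestamp numeric, strictly increasing
#' @param positions n x 3 matrix of mm positions
#' @param source provenance tag (`"markerless"`, `"marker"`, `"analytic"`)
#' @return data frame of class `track3d`
#' @export
track3d <- function(timestamp, positions, source = "markerless") {
  positions <- matrix(positions, ncol = 3)
  stopifnot(length(timestamp) == nrow(positions),
            !is.unsorted(timestamp, strictly = TRUE))
  structure(data.frame(timestamp = timestamp,
                       x = positions[, 1], y = positions[, 2],
                       z = positions[, 3], source = source),
            class = c("track3d", "data.frame"))
}

#' Cohort-like random phantom specification
#'
#' Samples a spec within the reported cohort's ranges: GTV volume in
#' `[1.18, 25.74]` cm^3, 3D motion range in `[11, 28]` mm, mean GTV HU in
#' `[-346, -20]`, 2-5 markers.
#'
#' @param seed RNG seed
#' @param ... overrides passed on to [phantom_spec()]
#' @return a `phantom_spec`
#' @export
table1_like_spec <- function(seed = 1L, ...) {
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  vol <- runif(1, 1.18, 25.74)                       # cm^3
  r <- (3 * vol * 1000 / (4 * pi))^(1 / 3)           # mm, sphere
  motion <- runif(1, 11, 28)
  dir <- unitize(c(runif(1, -0.2, 0.2), runif(1, -0.4, 0.4), 1))
  hu <- runif(1, -346, -20)
  n_mark <- sample(2:5, 1)
  offs <- lapply(seq_len(n_mark), function(i) {
    u <- unitize(stats::rnorm(3))
    u * runif(1, r + 3, r + 15)
  })
  phantom_spec(tumor_semi_axes_mm = rep(r, 3),
               motion_vector_mm = motion * dir,
               tumor_hu = hu, marker_offsets_mm = offs,
               rng_seed = seed, ...)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
}
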