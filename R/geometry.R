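#' @useDynLib orthotrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Room frame convention: origin at isocenter, +x patient-left (LR),
# +y posterior-to-anterior (AP), +z inferior-to-superior (SI).
# All lengths in mm, all interface angles in degrees.

deg2rad <- function(d) d * pi / 180

vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(v) == 3, all(is.finite(v)))
  v
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("zero-length vector cannot be normalized")
  v / n
}

#' Normalize an angle to [0, 360)
#' @param a angle in degrees
#' @return equivalent angle in `[0, 360)`
#' @keywords internal
normalize_angle <- function(a) ((a %% 360) + 360) %% 360

# Rodrigues rotation of vector v about unit axis k by angle (radians)
rotate_about_axis <- function(v, k, angle) {
  k <- unitize(k)
  v * cos(angle) + pracma::cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

#' Flat-panel / source geometry parameters
#'
#' Defaults reproduce the clinical orthogonal kV system: source-to-isocenter
#' distance 1000 mm, source-to-detector distance 1836 mm, a 1024 x 768 panel
#' whose pixel pitch is chosen so that the pixel scale projected to the
#' isocenter plane is 0.211 mm (pitch = 0.211 * 1836 / 1000 mm at the panel).
#'
#' @param sid_mm source-to-isocenter distance (mm)
#' @param sdd_mm source-to-detector distance (mm); must exceed `sid_mm`
#' @param pixel_pitch_mm physical pixel pitch at the panel (mm)
#' @param n_u,n_v panel pixel counts along the two panel axes
#' @return a `panel_spec` list
#' @export
panel_spec <- function(sid_mm = 1000, sdd_mm = 1836,
                       pixel_pitch_mm = 0.211 * 1836 / 1000,
                       n_u = 1024L, n_v = 768L) {
  if (pixel_pitch_mm <= 0 || n_u < 1 || n_v < 1)
    stop("invalid panel spec: non-positive pitch or pixel counts")
  if (sid_mm <= 0 || sdd_mm <= sid_mm)
    stop("invalid panel spec: require 0 < sid < sdd")
  structure(list(sid = sid_mm, sdd = sdd_mm, pixel_pitch = pixel_pitch_mm,
                 n_u = as.integer(n_u), n_v = as.integer(n_v)),
            class = "panel_spec")
}

#' Clockwise / counterclockwise tube angles for a gantry angle
#'
#' The two kV tubes ride with the gantry at gantry angle plus and minus 45
#' degrees, giving beam axes 90 degrees apart (orthogonal imaging).
#'
#' @param gantry_angle gantry angle in degrees (any real value)
#' @return named numeric vector `c(cw =, ccw =)`, each normalized to `[0, 360)`
#' @export
#' @examples
#' tube_angles_for_gantry(0)   # 45, 315
#' tube_angles_for_gantry(350) # 35, 305
tube_angles_for_gantry <- function(gantry_angle) {
  stopifnot(is.numeric(gantry_angle), length(gantry_angle) == 1,
            is.finite(gantry_angle))
  c(cw = normalize_angle(gantry_angle + 45),
    ccw = normalize_angle(gantry_angle - 45))
}

#' Distinct tube angles for a multi-port plan
#'
#' Each treatment port (gantry angle) contributes two tube angles; a
#' seven-to-nine-port plan therefore needs 14-18 per-angle models.
#'
#' @param gantry_angles numeric vector of port gantry angles (degrees)
#' @return sorted unique tube angles in degrees
#' @export
tube_angles_for_plan <- function(gantry_angles) {
  sort(unique(as.numeric(vapply(gantry_angles, tube_angles_for_gantry,
                                numeric(2)))))
}

#' Build an imaging geometry for one kV tube
#'
#' The nominal source lies in the axial (z = 0) plane at azimuth
#' `tube_angle` and radius `sid`; at tube angle 0 the source is at
#' (0, -sid, 0) with the beam axis pointing +y. The rigid source + panel
#' assembly is then rotated about the isocenter, first tilting the beam
#' toward SI (rotation about the panel's horizontal u axis) by
#' `perturb_si`, then toward AP (rotation about the room z axis) by
#' `perturb_ap`. These small perturbations are the augmentation used to
#' multiply a training set.
#'
#' @param tube_angle beam azimuth in the axial plane, degrees
#' @param perturb_si,perturb_ap rigid tilt angles in degrees, |angle| <= 10
#' @param panel a [panel_spec()]
#' @param tube_label `"CW"` or `"CCW"` tag carried along for bookkeeping
#' @return an `imaging_geometry` object with fields `source`,
#'   `detector_center`, `u_axis`, `v_axis`, `sid`, `sdd`, `pixel_pitch`,
#'   `n_u`, `n_v`, `tube_angle`, `perturb_si`, `perturb_ap`, `tube_label`
#' @export
build_geometry <- function(tube_angle, perturb_si = 0, perturb_ap = 0,
                           panel = panel_spec(), tube_label = "CW") {
  stopifnot(inherits(panel, "panel_spec"))
  if (abs(perturb_si) > 10 || abs(perturb_ap) > 10)
    stop("perturbation angles must satisfy |angle| <= 10 degrees")
  th <- deg2rad(tube_angle)
  source <- c(panel$sid * sin(th), -panel$sid * cos(th), 0)
  beam <- unitize(-source)                       # toward isocenter
  u_axis <- c(cos(th), sin(th), 0)               # panel horizontal, axial plane
  v_axis <- c(0, 0, 1)                           # panel vertical = SI

  # rigid rotation of the whole assembly about the isocenter:
  # SI tilt about the (pre-tilt) u axis first, then AP tilt about room z
  si_axis <- u_axis      # the pre-tilt horizontal axis, fixed for both calls
  rot <- function(p) {
    p1 <- rotate_about_axis(p, si_axis, deg2rad(perturb_si))
    rotate_about_axis(p1, c(0, 0, 1), deg2rad(perturb_ap))
  }
  source <- rot(source)
  beam <- rot(beam)
  u_axis <- rot(u_axis)
  v_axis <- rot(v_axis)
  detector_center <- source + panel$sdd * beam

  structure(list(
    tube_angle = normalize_angle(tube_angle),
    perturb_si = perturb_si, perturb_ap = perturb_ap,
    source = source, detector_center = detector_center,
    u_axis = u_axis, v_axis = v_axis,
    sid = panel$sid, sdd = panel$sdd,
    pixel_pitch = panel$pixel_pitch,
    n_u = panel$n_u, n_v = panel$n_v,
    tube_label = match.arg(tube_label, c("CW", "CCW"))
  ), class = "imaging_geometry")
}

#' Beam axis of a geometry (unit vector, source toward detector)
#' @param geom an `imaging_geometry`
#' @return unit 3-vector
#' @export
beam_axis <- function(geom) unitize(geom$detector_center - geom$source)

#' Pixel scale projected to the isocenter plane
#' @param geom an `imaging_geometry`
#' @return mm per pixel at the isocenter
#' @export
isocenter_pixel_scale <- function(geom) geom$pixel_pitch * geom$sid / geom$sdd

# physical panel point of continuous pixel coordinates (u, v);
# pixel centers, (0,0) at one corner
panel_point <- function(geom, u, v) {
  geom$detector_center +
    (u - (geom$n_u - 1) / 2) * geom$pixel_pitch * geom$u_axis +
    (v - (geom$n_v - 1) / 2) * geom$pixel_pitch * geom$v_axis
}

#' Ray from the source through a detector pixel
#'
#' @param geom an `imaging_geometry`
#' @param u,v continuous pixel coordinates (pixel centers, 0-based)
#' @param margin pixels beyond the physical panel edge that are still accepted
#' @return a `ray` list with `origin` and unit `direction`
#' @export
ray_through_pixel <- function(geom, u, v, margin = 0) {
  stopifnot(inherits(geom, "imaging_geometry"))
  if (u < -0.5 - margin || u > geom$n_u - 0.5 + margin ||
      v < -0.5 - margin || v > geom$n_v - 0.5 + margin)
    stop("pixel coordinates outside the panel (beyond margin)")
  p <- panel_point(geom, u, v)
  structure(list(origin = geom$source, direction = unitize(p - geom$source)),
            class = "ray")
}

#' Construct a ray from an origin and direction
#' @param origin 3-vector (mm)
#' @param direction 3-vector; normalized internally
#' @return a `ray`
#' @export
make_ray <- function(origin, direction) {
  structure(list(origin = vec3(origin), direction = unitize(vec3(direction))),
            class = "ray")
}

#' Geometry pair for one gantry pose
#'
#' @param gantry_angle gantry angle in degrees
#' @param panel a [panel_spec()]
#' @return list with elements `cw` and `ccw`, the two `imaging_geometry`
#'   objects whose beam axes are 90 degrees apart
#' @export
orthogonal_pair <- function(gantry_angle, panel = panel_spec()) {
  a <- tube_angles_for_gantry(gantry_angle)
  list(cw = build_geometry(a[["cw"]], panel = panel, tube_label = "CW"),
       ccw = build_geometry(a[["ccw"]], panel = panel, tube_label = "CCW"))
}
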