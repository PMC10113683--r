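# 3D positioning from orthogonal projections. Both the markerless method
# (contour centroids) and the marker-based clinical reference use the same
# stereo primitive: the midpoint of the shortest segment between the two
# source-to-detector-centroid rays.

#' Sub-pixel centroid of a predicted contour mask
#'
#' Arithmetic mean of the mask's pixel centers, in 0-based continuous
#' (u, v) pixel coordinates of the projection it was predicted on.
#'
#' @param prediction a `contour_prediction` (or any list with a logical
#'   `mask` matrix)
#' @return numeric `c(u, v)`
#' @export
prediction_centroid <- function(prediction) {
  m <- prediction$mask
  if (!any(m)) stop("empty prediction mask")
  idx <- which(m, arr.ind = TRUE)
  c(u = mean(idx[, 1]) - 1, v = mean(idx[, 2]) - 1)
}

#' Midpoint triangulation of two skew rays
#'
#' Closed-form closest points on the two lines (from perpendicularity of
#' the connecting segment to both directions); returns their midpoint.
#' Near-parallel rays are an error.
#'
#' @param ray_a,ray_b `ray` objects
#' @param parallel_tol minimum norm of the direction cross product
#' @return 3-vector, mm
#' @export
triangulate_midpoint <- function(ray_a, ray_b, parallel_tol = 1e-9) {
  stopifnot(inherits(ray_a, "ray"), inherits(ray_b, "ray"))
  da <- ray_a$direction; db <- ray_b$direction
  if (vnorm(pracma::cross(da, db)) <= parallel_tol)
    stop(structure(class = c("orthotrack_parallel_rays", "error", "condition"),
                   list(message = "rays are (near-)parallel: no unique midpoint",
                        call = sys.call())))
  w <- ray_b$origin - ray_a$origin
  # solve [ da.da  -da.db ; da.db  -db.db ] (t, s)' = (w.da, w.db)'
  A <- matrix(c(sum(da * da), sum(da * db),
                -sum(da * db), -sum(db * db)), 2, 2)
  ts <- solve(A, c(sum(w * da), sum(w * db)))
  pa <- ray_a$origin + ts[1] * da
  pb <- ray_b$origin + ts[2] * db
  (pa + pb) / 2
}

# ray through a centroid given in a projection image's (possibly
# downsampled) pixel coordinates
centroid_ray <- function(image, uv) {
  g <- image$geometry
  d <- image$downsample
  # map rendered-pixel coordinates back to physical panel coordinates
  ray_through_pixel(g, uv[1] * d + (d - 1) / 2, uv[2] * d + (d - 1) / 2)
}

#' 3D position from an orthogonal prediction pair
#'
#' `NULL` if either view has no prediction (the frame yields no 3D
#' position); otherwise the midpoint triangulation of the two centroid
#' rays. Requires the two geometries to be roughly orthogonal.
#'
#' @param pred_cw,pred_ccw `contour_prediction` or `NULL`
#' @param img_cw,img_ccw the `projection_image`s the predictions live on
#' @return 3-vector (mm) or `NULL`
#' @export
position_from_pair <- function(pred_cw, pred_ccw, img_cw, img_ccw) {
  if (is.null(pred_cw) || is.null(pred_ccw)) return(NULL)
  ax <- beam_axis(img_cw$geometry); bx <- beam_axis(img_ccw$geometry)
  if (abs(sum(ax * bx)) > 0.5)
    stop("geometries are not an orthogonal pair (beam axes < 60 deg apart)")
  ra <- centroid_ray(img_cw, prediction_centroid(pred_cw))
  rb <- centroid_ray(img_ccw, prediction_centroid(pred_ccw))
  tryCatch(triangulate_midpoint(ra, rb),
           orthotrack_parallel_rays = function(e) {
             warning("triangulation failed: ", conditionMessage(e))
             NULL
           })
}

#' Forward-project a 3D point to panel pixel coordinates
#'
#' @param geom an `imaging_geometry`
#' @param point 3-vector, mm
#' @param downsample report coordinates on the downsampled pixel grid
#' @return continuous 0-based `c(u, v)` pixel coordinates
#' @export
project_point <- function(geom, point, downsample = 1L) {
  s <- geom$source
  b <- beam_axis(geom)
  d <- point - s
  # intersection of the source->point ray with the detector plane
  t <- geom$sdd / sum(d * b)
  p <- s + t * d
  rel <- p - geom$detector_center
  u <- sum(rel * geom$u_axis) / geom$pixel_pitch + (geom$n_u - 1) / 2
  v <- sum(rel * geom$v_axis) / geom$pixel_pitch + (geom$n_v - 1) / 2
  c(u = (u - (downsample - 1) / 2) / downsample,
    v = (v - (downsample - 1) / 2) / downsample)
}

#' Simulated marker detections for one view
#'
#' Forward projection of known marker positions, optionally quantized to
#' whole pixels and/or jittered, standing in for the clinical marker
#' detector.
#'
#' @param geom an `imaging_geometry`
#' @param marker_positions list of 3-vectors (mm)
#' @param quantize round detections to whole pixels
#' @param jitter_px Gaussian jitter sigma in pixels (0 = none)
#' @return n x 2 matrix of (u, v) detector centroids
#' @export
detect_markers <- function(geom, marker_positions, quantize = FALSE,
                           jitter_px = 0) {
  stopifnot(length(marker_positions) >= 1)
  uv <- t(vapply(marker_positions, function(p) project_point(geom, p),
                 numeric(2)))
  if (jitter_px > 0) uv <- uv + matrix(stats::rnorm(length(uv), 0, jitter_px),
                                       ncol = 2)
  if (quantize) uv <- round(uv)
  colnames(uv) <- c("u", "v")
  uv
}

#' Marker-based 3D position (clinical reference method)
#'
#' Per view, the 2D centroid of the marker polyhedron is the mean of the
#' marker detections; the two centroid rays are triangulated and the stored
#' reference offset (marker center-of-mass to GTV at the reference phase)
#' is added.
#'
#' @param markers_cw,markers_ccw n x 2 matrices of marker (u, v) detections
#'   (>= 1 marker each; clinically 2-5)
#' @param geom_cw,geom_ccw the two `imaging_geometry` objects
#' @param reference_offset 3-vector, mm (default 0)
#' @return 3-vector, mm
#' @export
marker_ground_truth <- function(markers_cw, markers_ccw, geom_cw, geom_ccw,
                                reference_offset = c(0, 0, 0)) {
  markers_cw <- matrix(markers_cw, ncol = 2)
  markers_ccw <- matrix(markers_ccw, ncol = 2)
  if (nrow(markers_cw) < 1 || nrow(markers_ccw) < 1)
    stop("need at least one marker detection per view")
  ca <- colMeans(markers_cw); cb <- colMeans(markers_ccw)
  ra <- ray_through_pixel(geom_cw, ca[1], ca[2])
  rb <- ray_through_pixel(geom_ccw, cb[1], cb[2])
  triangulate_midpoint(ra, rb) + reference_offset
}

#' Write a track to CSV
#' @param track a `track3d`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read a track from CSV
#' @param path CSV written by [write_track_csv()]
#' @return a `track3d`
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  track3d(df$timestamp, as.matrix(df[, c("x", "y", "z")]),
          source = df$source)
}
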