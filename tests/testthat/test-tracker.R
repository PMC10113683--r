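test_that("mask centroids are sub-pixel means of pixel centers", {
  m <- matrix(FALSE, 40, 60)
  m[11, 21] <- TRUE   # 0-based (10, 20)
  expect_equal(prediction_centroid(list(mask = m)), c(u = 10, v = 20))
  m2 <- matrix(FALSE, 40, 60); m2[1:2, 1:2] <- TRUE
  expect_equal(prediction_centroid(list(mask = m2)), c(u = 0.5, v = 0.5))
  expect_error(prediction_centroid(list(mask = m & FALSE)), "empty")

  # rasterized disc centered off-grid
  cu <- 30.25; cv <- 40.75; r <- 8.4
  uu <- matrix(0:59, 60, 60); vv <- t(uu)
  disc <- (uu - cu)^2 + (vv - cv)^2 <= r^2
  cen <- prediction_centroid(list(mask = disc))
  expect_lt(max(abs(cen - c(cu, cv))), 0.1)
})

test_that("midpoint triangulation solves the closest-point system in closed form", {
  ra <- make_ray(c(-1000, 0, 0), c(1, 0, 0))
  rb <- make_ray(c(0, -1000, 0), c(0, 1, 0))
  expect_equal(triangulate_midpoint(ra, rb), c(0, 0, 0))

  # skew pair: x-axis and {(t, 1, 2 - t)}; brute-force grid-search oracle
  l1 <- make_ray(c(0, 0, 0), c(1, 0, 0))
  l2 <- make_ray(c(0, 1, 2), c(1, 0, -1))
  got <- triangulate_midpoint(l1, l2)
  ts <- seq(-5, 5, by = 1e-3)
  best <- c(Inf, NA, NA)
  p2u <- l2$direction
  for (s in seq(-5, 5, by = 0.5)) {
    p2 <- l2$origin + s * p2u
    d2 <- (ts - p2[1])^2 + p2[2]^2 + p2[3]^2
    i <- which.min(d2)
    if (d2[i] < best[1]) best <- c(d2[i], ts[i], s)
  }
  # refine s on a fine grid around the winner
  for (s in seq(best[3] - 1, best[3] + 1, by = 1e-3)) {
    p2 <- l2$origin + s * p2u
    d2 <- (ts - p2[1])^2 + p2[2]^2 + p2[3]^2
    i <- which.min(d2)
    if (d2[i] < best[1]) best <- c(d2[i], ts[i], s)
  }
  p2 <- l2$origin + best[3] * p2u
  oracle_mid <- (c(best[2], 0, 0) + p2) / 2
  expect_equal(got, oracle_mid, tolerance = 1e-2)

  expect_equal(triangulate_midpoint(rb, ra), triangulate_midpoint(ra, rb))
  expect_error(triangulate_midpoint(l1, make_ray(c(0, 5, 0), c(1, 0, 0))),
               class = "orthotrack_parallel_rays")
})

test_that("noiseless projected point targets are recovered to sub-micron accuracy", {
  pair <- orthogonal_pair(20)
  set.seed(31)
  errs <- vapply(1:200, function(i) {
    pt <- runif(3, -30, 30)
    ua <- project_point(pair$cw, pt)
    ub <- project_point(pair$ccw, pt)
    est <- triangulate_midpoint(ray_through_pixel(pair$cw, ua[1], ua[2]),
                                ray_through_pixel(pair$ccw, ub[1], ub[2]))
    sqrt(sum((est - pt)^2))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("whole-pixel quantization bounds the 3D error by sqrt(2) times the isocenter pixel scale", {
  pair <- orthogonal_pair(0)
  bound <- sqrt(2) * isocenter_pixel_scale(pair$cw)
  set.seed(32)
  errs <- vapply(1:1000, function(i) {
    pt <- runif(3, -30, 30)
    ua <- round(project_point(pair$cw, pt))
    ub <- round(project_point(pair$ccw, pt))
    est <- triangulate_midpoint(ray_through_pixel(pair$cw, ua[1], ua[2]),
                                ray_through_pixel(pair$ccw, ub[1], ub[2]))
    sqrt(sum((est - pt)^2))
  }, numeric(1))
  expect_lt(max(errs), bound)
})

test_that("a missing prediction on either view yields no 3D position", {
  ph <- generate_phantom(tiny_phantom_spec())
  pair <- orthogonal_pair(0)
  img_cw <- render_drr(ph$phases[[1]]$volume, pair$cw, 64L)
  img_ccw <- render_drr(ph$phases[[1]]$volume, pair$ccw, 64L)
  some <- list(mask = img_cw$path > 0.5)
  expect_null(position_from_pair(NULL, some, img_cw, img_ccw))
  expect_null(position_from_pair(some, NULL, img_cw, img_ccw))
  expect_error(position_from_pair(some, some, img_cw, img_cw),
               "not an orthogonal pair")
})

test_that("marker-based positioning recovers the tumor from projected marker centroids", {
  pair <- orthogonal_pair(0)
  tumor <- c(4, -7, 11)
  offs <- list(c(10, 0, 0), c(-10, 0, 0), c(0, 8, 0), c(0, -8, 0))
  markers <- lapply(offs, function(o) tumor + o)
  det <- function(geom, q) detect_markers(geom, markers, quantize = q)

  # sub-pixel detections, zero offset: near-exact (perspective asymmetry only)
  est <- marker_ground_truth(det(pair$cw, FALSE), det(pair$ccw, FALSE),
                             pair$cw, pair$ccw)
  expect_lt(sqrt(sum((est - tumor)^2)), 0.05)

  # reference offset is purely additive
  est2 <- marker_ground_truth(det(pair$cw, FALSE), det(pair$ccw, FALSE),
                              pair$cw, pair$ccw, reference_offset = c(0, 0, 5))
  expect_equal(est2 - est, c(0, 0, 5))

  # pixel-quantized detections stay within twice the isocenter pixel scale
  estq <- marker_ground_truth(det(pair$cw, TRUE), det(pair$ccw, TRUE),
                              pair$cw, pair$ccw)
  expect_lt(sqrt(sum((estq - est)^2)), 2 * isocenter_pixel_scale(pair$cw))

  expect_error(marker_ground_truth(matrix(numeric(0), ncol = 2),
                                   det(pair$ccw, FALSE), pair$cw, pair$ccw),
               "at least one marker")
})

test_that("tracks round-trip through CSV", {
  tr <- track3d(0:4, matrix(rnorm(15), 5, 3), source = "markerless")
  f <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, f)
  tr2 <- read_track_csv(f)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$timestamp, tr$timestamp)
})
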