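# Shared fixtures: everything is generated in code at test time.

# coarse phantom for fast rendering tests (8 mm voxels, 16x12 px projections
# at downsample 64)
tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 24L), spacing_mm = c(8, 8, 8), ...)
}

# mid-resolution phantom (4 mm voxels) for tracking tests
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(64L, 64L, 48L), spacing_mm = c(4, 4, 4), ...)
}

# random HU volume for ray-tracing oracles
random_hu_volume <- function(n = 16, spacing = c(2, 2, 2), hu_range = c(-1000, 2000)) {
  vox <- array(stats::runif(n^3, hu_range[1], hu_range[2]), c(n, n, n))
  ct_volume(vox, spacing, -(c(n, n, n) - 1) * spacing / 2)
}

# dense-sampling oracle for the radiological path: midpoint rule at fixed
# step (mm), independent of the Siddon traversal
dense_path_oracle <- function(volume, ray, step = 0.01, mu_water = 0.02) {
  d <- dim(volume$voxels)
  lo <- volume$origin - volume$spacing / 2
  hi <- volume$origin + (d - 0.5) * volume$spacing
  t0 <- 0; t1 <- Inf
  for (a in 1:3) {
    if (abs(ray$direction[a]) < 1e-12) {
      if (ray$origin[a] < lo[a] || ray$origin[a] >= hi[a]) return(0)
    } else {
      ta <- (lo[a] - ray$origin[a]) / ray$direction[a]
      tb <- (hi[a] - ray$origin[a]) / ray$direction[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(0)
  # midpoint rule over the exact chord, step as close to `step` as divides it
  n_steps <- max(1, round((t1 - t0) / step))
  step <- (t1 - t0) / n_steps
  ts <- t0 + (seq_len(n_steps) - 0.5) * step
  px <- outer(ts, ray$direction[1]) + ray$origin[1]
  py <- outer(ts, ray$direction[2]) + ray$origin[2]
  pz <- outer(ts, ray$direction[3]) + ray$origin[3]
  ix <- pmin(pmax(floor((px - lo[1]) / volume$spacing[1]), 0), d[1] - 1)
  iy <- pmin(pmax(floor((py - lo[2]) / volume$spacing[2]), 0), d[2] - 1)
  iz <- pmin(pmax(floor((pz - lo[3]) / volume$spacing[3]), 0), d[3] - 1)
  mu <- hu_to_mu(volume$voxels, mu_water)
  sum(mu[cbind(ix + 1, iy + 1, iz + 1)]) * step
}
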