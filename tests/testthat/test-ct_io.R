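test_that("a CT volume survives a DICOM series round trip voxel-for-voxel", {
  set.seed(11)
  vox <- array(sample(-1000:2000, 16 * 12 * 5, TRUE), c(16, 12, 5))
  vol <- ct_volume(vox, c(1.5, 2, 2.5), c(-10, -12, -5), phase = 0L)
  d <- withr::local_tempdir()
  write_ct_series(vol, d)
  v2 <- read_ct_series(d, phase = 0L)
  expect_identical(v2$voxels, vox + 0)
  expect_equal(v2$spacing, vol$spacing)
  expect_equal(v2$origin, vol$origin)
})

test_that("our DICOM writer is readable by an independent implementation", {
  vol <- ct_volume(array(0, c(8, 6, 2)), c(1, 1, 2), c(0, 0, 0))
  d <- withr::local_tempdir()
  f <- write_ct_series(vol, d)[1]
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; ds = pydicom.dcmread('", f, "'); ",
    "print(ds.Rows, ds.Columns, float(ds.RescaleIntercept), ",
    "int(ds.pixel_array[0, 0]))"))), stdout = TRUE)
  # HU 0 with intercept -1024 must be stored as 1024
  expect_equal(out, "6 8 -1024.0 1024")
})

test_that("a missing slice and mixed series are detected", {
  vol <- ct_volume(array(0, c(8, 8, 5)), c(2, 2, 2), c(0, 0, 0))
  d <- withr::local_tempdir()
  files <- write_ct_series(vol, d)
  file.remove(files[3])
  expect_error(read_ct_series(d), "missing slice")

  d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_ct_series(vol, d2)
  other <- write_ct_series(vol, d3)   # fresh series UID
  file.copy(other, file.path(d2, paste0("b_", basename(other))))
  expect_error(read_ct_series(d2), "mixed series")
})

test_that("RT-STRUCT polygons rasterize by the voxel-center even-odd rule", {
  vol <- ct_volume(array(0, c(32, 32, 4)), c(2, 2, 2), c(-31, -31, -3))
  # 20 x 20 mm square on the z = -1 slice: voxel centers strictly inside
  # span a 10 x 10 block
  sq <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10), rep(-1, 4))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(GTV = list(sq)), f)
  m <- extract_gtv_mask(f, vol, "GTV")
  expect_equal(sum(m$mask), 100)

  # two disjoint polygons on one slice are both rasterized
  sq2 <- cbind(c(20, 28, 28, 20), c(20, 20, 28, 28), rep(-1, 4))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(GTV = list(sq, sq2)), f2)
  m2 <- extract_gtv_mask(f2, vol, "GTV")
  expect_gt(sum(m2$mask), 100)
  k <- which(apply(m2$mask, 3, any))
  expect_length(k, 1)
  expect_equal(max(EBImage::bwlabel(m2$mask[, , k])), 2)
})

test_that("structure-set error paths: empty ROI, missing ROI, off-slice contour", {
  vol <- ct_volume(array(0, c(16, 16, 2)), c(2, 2, 2), c(0, 0, 0))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(GTV = list()), f)
  expect_error(extract_gtv_mask(f, vol, "GTV"), "no contours")

  sq <- cbind(c(2, 6, 6, 2), c(2, 2, 6, 6), rep(0, 4))
  write_rtstruct(list(GTV = list(sq)), f)
  expect_error(extract_gtv_mask(f, vol, "PTV"), "not found")

  off <- sq; off[, 3] <- 7.3   # slices are at z = 0, 2
  write_rtstruct(list(GTV = list(off)), f)
  expect_error(extract_gtv_mask(f, vol, "GTV"), "no slice")
})

test_that("GTV-only volumes keep HU inside the mask, air everything else, idempotently", {
  ph <- generate_phantom(tiny_phantom_spec())
  p <- ph$phases[[1]]
  g <- gtv_only_volume(p$volume, p$mask)
  expect_true(all(g$voxels[!p$mask$mask] == -1000))
  expect_identical(g$voxels[p$mask$mask], p$volume$voxels[p$mask$mask])
  expect_equal(mean(g$voxels[g$voxels > -1000]), ph$spec$tumor_hu)
  expect_identical(gtv_only_volume(g, p$mask), g)

  allmask <- gtv_mask(array(TRUE, dim(p$volume$voxels)),
                      p$volume$spacing, p$volume$origin)
  expect_identical(gtv_only_volume(p$volume, allmask)$voxels, p$volume$voxels)
  wrong <- gtv_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1), c(0, 0, 0))
  expect_error(gtv_only_volume(p$volume, wrong), "shapes differ")
})

test_that("an ellipsoid ROI rasterized from contours matches the analytic volume within 2%", {
  # circle contours of a 12.1 mm sphere on 1 mm slices
  vol <- ct_volume(array(0, c(40, 40, 30)), c(1, 1, 1), c(-19.5, -19.5, -14.5))
  r0 <- 12.1
  zs <- seq(-14.5, 14.5, by = 1)
  zs <- zs[abs(zs) < r0]
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  contours <- lapply(zs, function(z) {
    rz <- sqrt(r0^2 - z^2)
    cbind(rz * cos(th), rz * sin(th), z)
  })
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(list(GTV = contours), f)
  m <- extract_gtv_mask(f, vol, "GTV")
  expect_equal(mask_volume_cm3(m), 4 / 3 * pi * r0^3 / 1000, tolerance = 0.02)
})
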