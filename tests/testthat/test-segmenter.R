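# shared training set for the template backend tests
local_training_samples <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(small_phantom_spec())
      cache <<- build_training_set(ph$phases, 45, make_grid(0.5, 0.5),
                                   downsample = 16L)
    }
    cache
  }
})

test_that("fitting builds a deterministic template bank with stride subsampling", {
  smp <- local_training_samples()
  m1 <- fit_segmenter(backend_config(), smp[1])
  expect_length(m1$templates, 1)
  # the stored patch is the mask's dilated bounding-box crop of the image
  tpl <- m1$templates[[1]]
  o <- tpl$origin
  expect_equal(tpl$patch,
               smp[[1]]$image$display[(o["u"] + 1):(o["u"] + nrow(tpl$patch)),
                                      (o["v"] + 1):(o["v"] + ncol(tpl$patch))] + 0,
               ignore_attr = TRUE)

  m10 <- fit_segmenter(backend_config(template_stride = 10L), smp)
  expect_length(m10$templates, length(seq(1, length(smp), by = 10)))

  expect_identical(fit_segmenter(backend_config(), smp),
                   fit_segmenter(backend_config(), smp))

  bad <- smp
  bad[[2]]$tube_angle <- 90
  expect_error(fit_segmenter(backend_config(), bad), "mixed tube angles")
  expect_error(fit_segmenter(backend_config(), list()), "length")
})

test_that("a training image self-matches at zero offset with confidence 1", {
  smp <- local_training_samples()
  model <- fit_segmenter(backend_config(template_stride = 5L), smp)
  preds <- predict_contours(model, smp[[1]]$image)
  top <- select_prediction(preds)
  expect_equal(top$confidence, 1.0, tolerance = 1e-12)
  expect_true(all(diff(vapply(preds, function(p) p$confidence,
                              numeric(1))) <= 0))
  expect_equal(sum(top$mask & smp[[1]]$gtv_mask) /
               sum(top$mask | smp[[1]]$gtv_mask), 1.0)
})

test_that("template matching is translation-equivariant on noiseless shifts", {
  smp <- local_training_samples()
  model <- fit_segmenter(backend_config(), smp[1])
  img <- smp[[1]]$image
  du <- 3L; dv <- -2L
  shifted <- img
  nu <- nrow(img$display); nv <- ncol(img$display)
  sh <- matrix(min(img$display), nu, nv)
  ur <- max(1, 1 + du):min(nu, nu + du)
  vr <- max(1, 1 + dv):min(nv, nv + dv)
  sh[ur, vr] <- img$display[ur - du, vr - dv]   # content moves by (+du, +dv)
  shifted$display <- sh
  p0 <- select_prediction(predict_contours(model, img))
  p1 <- select_prediction(predict_contours(model, shifted))
  expect_equal(prediction_centroid(p1) - prediction_centroid(p0),
               c(u = du, v = dv))
  expect_equal(p1$confidence, 1.0, tolerance = 1e-12)
})

test_that("pure noise scores far below a true match and is dropped at a null-calibrated threshold", {
  smp <- local_training_samples()
  model <- fit_segmenter(backend_config(), smp[1])
  set.seed(77)
  null_conf <- vapply(1:10, function(i) {
    noise <- smp[[1]]$image
    noise$display <- matrix(sample(0:255, length(noise$display), TRUE),
                            nrow(noise$display), ncol(noise$display))
    p <- predict_contours(model, noise)
    if (length(p) == 0) 0 else p[[1]]$confidence
  }, numeric(1))
  expect_lt(max(null_conf), 0.85)   # well separated from the self-match 1.0
  thr <- max(null_conf) + 0.01
  model2 <- fit_segmenter(backend_config(confidence_threshold = thr), smp[1])
  set.seed(77)
  noise <- smp[[1]]$image
  noise$display <- matrix(sample(0:255, length(noise$display), TRUE),
                          nrow(noise$display), ncol(noise$display))
  expect_length(predict_contours(model2, noise), 0)
  expect_null(select_prediction(predict_contours(model2, noise)))
})

test_that("every training sample self-predicts with high mask overlap", {
  smp <- local_training_samples()
  model <- fit_segmenter(backend_config(), smp)
  ious <- vapply(sample(seq_along(smp), 10), function(i) {
    p <- select_prediction(predict_contours(model, smp[[i]]$image))
    sum(p$mask & smp[[i]]$gtv_mask) / sum(p$mask | smp[[i]]$gtv_mask)
  }, numeric(1))
  expect_true(all(ious >= 0.9))
})

test_that("prediction selection takes the highest confidence with a stable tie-break", {
  mk <- function(conf) structure(list(confidence = conf, tag = conf),
                                 class = "contour_prediction")
  expect_null(select_prediction(list()))
  expect_equal(select_prediction(list(mk(0.6), mk(0.9)))$confidence, 0.9)
  a <- mk(0.7); a$id <- "first"
  b <- mk(0.7); b$id <- "second"
  expect_equal(select_prediction(list(a, b))$id, "first")
})
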