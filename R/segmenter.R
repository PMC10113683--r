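# Per-patient, per-tube-angle GTV contour predictor. The reference backend is
# deterministic template matching: the bank stores mask-bounding-box crops of
# the training DRRs, and prediction maximizes zero-normalized cross-
# correlation (ZNCC) over a search window, translating the stored polygon and
# mask to the best offset. A learned instance-segmentation backend can be
# plugged in behind the same fit/predict contract; the pipeline does not
# depend on which backend produced a prediction.

#' Backend configuration
#'
#' @param kind `"template"` (deterministic reference backend)
#' @param confidence_threshold predictions below this are dropped (default
#'   0.5; template confidence is `(zncc + 1) / 2`)
#' @param search_window half-width in pixels of the offset search around the
#'   template's training location; `Inf` searches the whole image
#' @param template_stride keep every `stride`-th training sample as a
#'   template (1 = all)
#' @param margin_px bounding-box dilation of the template crop
#' @param seed RNG seed recorded for backends that need one
#' @return a `backend_config`
#' @export
backend_config <- function(kind = c("template", "neural"),
                           confidence_threshold = 0.5,
                           search_window = 20, template_stride = 1L,
                           margin_px = 2L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            template_stride >= 1)
  structure(list(kind = kind, confidence_threshold = confidence_threshold,
                 search_window = search_window,
                 template_stride = as.integer(template_stride),
                 margin_px = as.integer(margin_px), seed = as.integer(seed)),
            class = "backend_config")
}

#' Fit a contour-prediction model for one tube angle
#'
#' Template backend: every `template_stride`-th sample contributes one
#' template -- the display-image crop of the mask's bounding box dilated by
#' `margin_px`, plus the mask, polygon and crop origin. Deterministic.
#'
#' @param config a [backend_config()]
#' @param samples non-empty list of `labeled_sample`, all from one tube angle
#' @return a `trained_model`
#' @export
fit_segmenter <- function(config, samples) {
  stopifnot(inherits(config, "backend_config"), length(samples) >= 1)
  angles <- unique(vapply(samples, function(s) s$tube_angle, numeric(1)))
  if (length(angles) != 1)
    stop("samples from mixed tube angles: ", paste(angles, collapse = ", "))
  if (config$kind != "template")
    stop("only the template backend is implemented in this package")
  keep <- seq(1, length(samples), by = config$template_stride)
  shape <- dim(samples[[1]]$image$path)
  templates <- lapply(samples[keep], function(s) {
    idx <- which(s$gtv_mask, arr.ind = TRUE)
    u0 <- max(1L, min(idx[, 1]) - config$margin_px)
    u1 <- min(shape[1], max(idx[, 1]) + config$margin_px)
    v0 <- max(1L, min(idx[, 2]) - config$margin_px)
    v1 <- min(shape[2], max(idx[, 2]) + config$margin_px)
    list(patch = s$image$display[u0:u1, v0:v1] + 0,
         mask = s$gtv_mask[u0:u1, v0:v1],
         polygon = cbind(u = s$gtv_polygon[, "u"] - (u0 - 1),
                         v = s$gtv_polygon[, "v"] - (v0 - 1)),
         origin = c(u = u0 - 1L, v = v0 - 1L),   # 0-based crop origin
         phase = s$phase, perturbation = s$perturbation)
  })
  structure(list(config = config, templates = templates,
                 image_shape = shape, tube_angle = angles),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (%s backend): %d templates, tube %.1f deg, %dx%d px\n",
              x$config$kind, length(x$templates), x$tube_angle,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Predict GTV contours on a projection image
#'
#' For each template, the ZNCC against the display image is maximized over
#' integer offsets within the search window around the template's training
#' location; the template's polygon and mask are translated to the argmax.
#' Confidence is `(zncc + 1) / 2`; predictions below the configured
#' threshold are dropped and the rest returned sorted by confidence
#' (stable order, so ties keep template order).
#'
#' @param model a `trained_model`
#' @param image a `projection_image` with the training image shape
#' @return list of `contour_prediction`: `polygon` (0-based image (u, v)),
#'   `mask` (full image-shape logical), `confidence`, `offset`
#' @export
predict_contours <- function(model, image) {
  stopifnot(inherits(model, "trained_model"),
            inherits(image, "projection_image"))
  if (!identical(dim(image$path), model$image_shape))
    stop("image shape does not match the training shape")
  img <- image$display + 0
  w <- model$config$search_window
  preds <- list()
  for (tpl in model$templates) {
    if (is.finite(w)) {
      u0 <- tpl$origin["u"] - w; u1 <- tpl$origin["u"] + w
      v0 <- tpl$origin["v"] - w; v1 <- tpl$origin["v"] + w
    } else {
      u0 <- 0; u1 <- model$image_shape[1]; v0 <- 0; v1 <- model$image_shape[2]
    }
    hit <- .zncc_search_cpp(img, tpl$patch, u0, u1, v0, v1)
    if (is.na(hit$zncc)) next
    conf <- (hit$zncc + 1) / 2
    if (conf < model$config$confidence_threshold) next
    mask <- matrix(FALSE, model$image_shape[1], model$image_shape[2])
    idx <- which(tpl$mask, arr.ind = TRUE)
    mask[cbind(idx[, 1] + hit$u, idx[, 2] + hit$v)] <- TRUE
    preds[[length(preds) + 1L]] <- structure(list(
      polygon = cbind(u = tpl$polygon[, "u"] + hit$u,
                      v = tpl$polygon[, "v"] + hit$v),
      mask = mask, confidence = conf,
      offset = c(u = hit$u, v = hit$v)
    ), class = "contour_prediction")
  }
  if (length(preds) > 1) {
    conf <- vapply(preds, function(p) p$confidence, numeric(1))
    preds <- preds[order(-conf)]   # stable: ties keep template order
  }
  preds
}

#' Select the single prediction for a frame
#'
#' Highest-confidence prediction, or `NULL` for an empty list (the frame
#' then contributes "no prediction" to the prediction-rate denominator).
#'
#' @param predictions list from [predict_contours()]
#' @return a `contour_prediction` or `NULL`
#' @export
select_prediction <- function(predictions) {
  if (length(predictions) == 0) return(NULL)
  conf <- vapply(predictions, function(p) p$confidence, numeric(1))
  predictions[[which.max(conf)]]    # which.max: first maximum = stable
}
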