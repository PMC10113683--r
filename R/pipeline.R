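# End-to-end workflow: phantom -> per-tube-angle training sets -> fitted
# template backends -> simulated treatment frames -> per-frame orthogonal
# predictions -> triangulated 3D track -> evaluation report against the
# phantom's analytic ground truth, with the marker-based reference method
# simulated alongside. Fully reproducible from (config, seed).

#' Run configuration
#'
#' @param phantom a [phantom_spec()] (clinical 4DCT input goes through
#'   [read_ct_series()] / [extract_gtv_mask()] and the lower-level stage
#'   functions instead)
#' @param gantry_angle gantry angle of the simulated port, degrees
#' @param grid a [make_grid()] perturbation grid for training
#' @param panel a [panel_spec()]
#' @param downsample rendering downsample factor (default 8: 128 x 96 px)
#' @param backend a [backend_config()]
#' @param n_frames simulated treatment frames (timestamps 0, 1, ... at
#'   ~2 frames per phase so a full breathing cycle is covered)
#' @param noise_sd additive Gaussian display noise on treatment frames
#'   (8-bit counts; 0 = noiseless)
#' @param quantize_markers round simulated marker detections to whole pixels
#' @param thresholds evaluation cumulative thresholds, mm
#' @param seed global RNG seed, fanned out to per-stage streams
#' @param out_dir optional output directory for artifacts (tracks CSV,
#'   report JSON); `NULL` writes nothing
#' @return a `run_config`
#' @export
run_config <- function(phantom = phantom_spec(),
                       gantry_angle = 0,
                       grid = make_grid(1, 0.5),
                       panel = panel_spec(),
                       downsample = 8L,
                       backend = backend_config(),
                       n_frames = 20L,
                       noise_sd = 0,
                       quantize_markers = TRUE,
                       thresholds = c(1, 2, 3, 5),
                       seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "perturbation_grid"),
            inherits(backend, "backend_config"), n_frames >= 1)
  structure(list(phantom = phantom, gantry_angle = gantry_angle, grid = grid,
                 panel = panel, downsample = as.integer(downsample),
                 backend = backend, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, quantize_markers = quantize_markers,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# stable per-stage seed derived from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  (as.integer(seed) * 7919L + as.integer(h %% 1000003)) %% 2147483647L
}

#' Run the pipeline end to end
#'
#' @param config a [run_config()]
#' @return an `orthotrack_run`: list with `report`
#'   (`evaluation_report`), `track_markerless`, `track_marker`,
#'   `track_truth` (`track3d`), `models` (per tube angle), `frames`
#'   (per-frame outcome log), `config`
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ph <- generate_phantom(config$phantom)
  angles <- tube_angles_for_gantry(config$gantry_angle)

  models <- list()
  for (lab in c("cw", "ccw")) {
    samples <- build_training_set(ph$phases, angles[[lab]], config$grid,
                                  config$panel, config$downsample)
    if (length(samples) == 0) stop("training-set stage produced no samples")
    models[[lab]] <- fit_segmenter(config$backend, samples)
  }

  # simulated treatment: cycle through phases at ~2 frames per phase
  n_ph <- config$phantom$n_phases
  phase_seq <- data.frame(
    timestamp = seq_len(config$n_frames) - 1,
    phase = rep(rep(seq_len(n_ph) - 1, each = 2),
                length.out = config$n_frames))
  truth <- ground_truth_track(ph, phase_seq)

  set.seed(stage_seed(config$seed, "treatment_noise"))
  geoms <- list(cw = build_geometry(angles[["cw"]], panel = config$panel,
                                    tube_label = "CW"),
                ccw = build_geometry(angles[["ccw"]], panel = config$panel,
                                     tube_label = "CCW"))
  frames <- vector("list", config$n_frames)
  pos_less <- matrix(NA_real_, config$n_frames, 3)
  pos_mark <- matrix(NA_real_, config$n_frames, 3)
  for (f in seq_len(config$n_frames)) {
    p <- phase_seq$phase[f]
    imgs <- list()
    preds <- list()
    for (lab in c("cw", "ccw")) {
      img <- render_drr(ph$phases[[p + 1]]$volume, geoms[[lab]],
                        config$downsample)
      if (config$noise_sd > 0) {
        img$display <- matrix(
          as.integer(pmin(255, pmax(0, round(
            img$display + stats::rnorm(length(img$display), 0,
                                       config$noise_sd))))),
          nrow(img$display), ncol(img$display))
      }
      imgs[[lab]] <- img
      preds[[lab]] <- select_prediction(predict_contours(models[[lab]], img))
    }
    p3 <- position_from_pair(preds$cw, preds$ccw, imgs$cw, imgs$ccw)
    if (!is.null(p3)) pos_less[f, ] <- p3

    mk <- ph$phases[[p + 1]]$marker_positions
    det_cw <- detect_markers(geoms$cw, mk, quantize = config$quantize_markers)
    det_ccw <- detect_markers(geoms$ccw, mk, quantize = config$quantize_markers)
    ref_off <- ph$phases[[ph$reference_phase + 1]]$gtv_centroid -
      Reduce(`+`, ph$phases[[ph$reference_phase + 1]]$marker_positions) /
        length(mk)
    pos_mark[f, ] <- marker_ground_truth(det_cw, det_ccw, geoms$cw, geoms$ccw,
                                         reference_offset = ref_off)
    frames[[f]] <- data.frame(
      timestamp = phase_seq$timestamp[f], phase = p,
      patient = 1L, fraction = 1L,
      marker_detected = TRUE,
      markerless_predicted = !is.null(p3))
  }
  frames <- do.call(rbind, frames)

  tr_truth <- truth
  keep <- !is.na(pos_less[, 1])
  tr_less <- track3d(phase_seq$timestamp[keep], pos_less[keep, , drop = FALSE],
                     source = "markerless")
  tr_mark <- track3d(phase_seq$timestamp, pos_mark, source = "marker")

  dev_vs_truth <- rep(NA_real_, config$n_frames)
  dev_vs_truth[keep] <- sqrt(rowSums(
    (pos_less[keep, , drop = FALSE] -
       as.matrix(tr_truth[keep, c("x", "y", "z")]))^2))
  frames$deviation <- dev_vs_truth

  report <- build_report(frames, thresholds = config$thresholds)

  run <- structure(list(report = report, track_markerless = tr_less,
                        track_marker = tr_mark, track_truth = tr_truth,
                        models = models, frames = frames, config = config),
                   class = "orthotrack_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_track_csv(run$track_markerless, file.path(out_dir, "track_markerless.csv"))
  write_track_csv(run$track_marker, file.path(out_dir, "track_marker.csv"))
  write_track_csv(run$track_truth, file.path(out_dir, "track_truth.csv"))
  utils::write.csv(run$frames, file.path(out_dir, "frames.csv"),
                   row.names = FALSE)
  rep <- run$report
  rep$deviations <- as.numeric(rep$deviations)
  jsonlite::write_json(
    list(n_pairs_total = rep$n_pairs_total,
         n_marker_detected = rep$n_marker_detected,
         n_markerless_predicted = rep$n_markerless_predicted,
         n_compared = rep$n_compared,
         median_mm = rep$median, iqr_low_mm = rep$iqr_low,
         iqr_high_mm = rep$iqr_high,
         cumulative = rep$cumulative,
         markerless_prediction_rate_pct = rep$markerless_prediction_rate_pct,
         marker_detection_rate_pct = rep$marker_detection_rate_pct),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(out_dir)
}

#' Load a run configuration from YAML
#'
#' Scalar fields of [run_config()] plus nested `phantom`, `grid`, `panel`
#' and `backend` blocks mapping to the corresponding constructors.
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$grid)) args$grid <- do.call(make_grid, y$grid)
  if (!is.null(y$panel)) args$panel <- do.call(panel_spec, y$panel)
  if (!is.null(y$backend)) args$backend <- do.call(backend_config, y$backend)
  for (k in c("gantry_angle", "downsample", "n_frames", "noise_sd",
              "quantize_markers", "thresholds", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}
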