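# Evaluation statistics for tracking runs: 3D deviation distributions
# (median, IQR, cumulative percentage curve), prediction/detection rates with
# the clinical accounting (a "prediction" needs valid contours on BOTH
# orthogonal views; a comparison additionally needs ground truth for that
# frame), and Pearson correlation of per-group summaries against cohort
# covariates.

#' Per-timestamp 3D deviations between two tracks
#'
#' Inner join on timestamp; Euclidean norm of the position difference at
#' each common timestamp. Timestamps present in only one track are excluded.
#'
#' @param pred,truth `track3d` data frames
#' @return numeric vector of deviations, mm
#' @export
track_deviations <- function(pred, truth) {
  common <- intersect(pred$timestamp, truth$timestamp)
  if (length(common) == 0) stop("tracks share no timestamps")
  a <- pred[match(common, pred$timestamp), c("x", "y", "z")]
  b <- truth[match(common, truth$timestamp), c("x", "y", "z")]
  unname(sqrt(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Median, IQR and cumulative percentages of a deviation sample
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); `cumulative(t) = 100 * #\{d <= t\} / n`.
#'
#' @param devs non-empty numeric vector, mm
#' @param thresholds cumulative-curve thresholds, mm (3 and 5 mm are the
#'   conventionally reported points)
#' @return list with `median`, `iqr_low`, `iqr_high`, `cumulative`
#'   (data frame `threshold_mm`, `percent`), `n`
#' @export
summarize_deviations <- function(devs, thresholds = c(1, 2, 3, 5)) {
  if (length(devs) == 0) stop("empty deviation sample")
  q <- unname(stats::quantile(devs, c(0.25, 0.5, 0.75), type = 7))
  cum <- vapply(thresholds, function(t) 100 * mean(devs <= t), numeric(1))
  list(median = q[2], iqr_low = q[1], iqr_high = q[3],
       cumulative = data.frame(threshold_mm = thresholds, percent = cum),
       n = length(devs))
}

#' Prediction (or detection) rate in percent
#' @param n_predicted frames with a 3D position
#' @param n_total stored frames
#' @return `100 * n_predicted / n_total`
#' @export
prediction_rate <- function(n_predicted, n_total) {
  stopifnot(n_total > 0, n_predicted >= 0, n_predicted <= n_total)
  100 * n_predicted / n_total
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over `stats::cor` with the degenerate cases made explicit.
#'
#' @param x,y equal-length numeric vectors, `length >= 3`, nonzero variance
#' @return r in `[-1, 1]`
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) input to Pearson correlation")
  stats::cor(x, y, method = "pearson")
}

#' Build the full evaluation report
#'
#' `frames` is the per-frame outcome log of a run: one row per stored
#' orthogonal image pair with logical columns `marker_detected` and
#' `markerless_predicted`, a `deviation` (mm; `NA` where either side is
#' missing), and group labels `patient` and `fraction`. The report carries
#' the frame accounting (total / marker-detected / markerless-predicted /
#' compared), the overall deviation summary and cumulative curve, per-group
#' tables, and Pearson correlations of the per-patient median deviation and
#' prediction rate against patient covariates (`patient_meta`: columns
#' `patient`, `gtv_volume_cm3`, `motion_range_mm`) and of the per-fraction
#' summaries against fraction index -- optionally recomputed with one
#' patient excluded (to probe a single outlier's leverage).
#'
#' @param frames data frame as described above
#' @param patient_meta optional per-patient covariates
#' @param thresholds cumulative thresholds, mm
#' @param exclude_patient optional patient label to exclude in the second
#'   correlation pass
#' @return an `evaluation_report` list
#' @export
build_report <- function(frames, patient_meta = NULL,
                         thresholds = c(1, 2, 3, 5),
                         exclude_patient = NULL) {
  need <- c("patient", "fraction", "marker_detected", "markerless_predicted",
            "deviation")
  if (!all(need %in% names(frames)))
    stop("frames is missing columns: ",
         paste(setdiff(need, names(frames)), collapse = ", "))
  compared <- frames$marker_detected & frames$markerless_predicted &
    !is.na(frames$deviation)
  devs <- frames$deviation[compared]
  overall <- summarize_deviations(devs, thresholds)

  group_table <- function(key) {
    do.call(rbind, lapply(split(frames, frames[[key]]), function(g) {
      gc <- g$marker_detected & g$markerless_predicted & !is.na(g$deviation)
      s <- if (any(gc)) summarize_deviations(g$deviation[gc], thresholds)
           else list(median = NA_real_, iqr_low = NA_real_, iqr_high = NA_real_)
      data.frame(group = g[[key]][1],
                 n_frames = nrow(g),
                 n_compared = sum(gc),
                 median_mm = s$median, iqr_low_mm = s$iqr_low,
                 iqr_high_mm = s$iqr_high,
                 prediction_rate_pct =
                   prediction_rate(sum(g$markerless_predicted), nrow(g)))
    }))
  }
  per_patient <- group_table("patient")
  per_fraction <- group_table("fraction")

  correlations <- NULL
  if (!is.null(patient_meta)) {
    correlations <- report_correlations(per_patient, per_fraction,
                                        patient_meta, frames, thresholds,
                                        exclude_patient)
  }

  rep <- list(
    n_pairs_total = nrow(frames),
    n_marker_detected = sum(frames$marker_detected),
    n_markerless_predicted = sum(frames$markerless_predicted),
    n_compared = sum(compared),
    deviations = devs,
    median = overall$median, iqr_low = overall$iqr_low,
    iqr_high = overall$iqr_high,
    cumulative = overall$cumulative,
    marker_detection_rate_pct =
      prediction_rate(sum(frames$marker_detected), nrow(frames)),
    markerless_prediction_rate_pct =
      prediction_rate(sum(frames$markerless_predicted), nrow(frames)),
    per_patient = per_patient, per_fraction = per_fraction,
    correlations = correlations
  )
  class(rep) <- "evaluation_report"
  rep
}

# correlation tables (all patients, and optionally one excluded)
report_correlations <- function(per_patient, per_fraction, patient_meta,
                                frames, thresholds, exclude_patient) {
  one_pass <- function(pp, pf) {
    meta <- patient_meta[match(pp$group, patient_meta$patient), ]
    data.frame(
      quantity = rep(c("median_deviation", "prediction_rate"), each = 3),
      covariate = rep(c("gtv_volume", "motion_range", "fraction_index"), 2),
      r = c(pearson(pp$median_mm, meta$gtv_volume_cm3),
            pearson(pp$median_mm, meta$motion_range_mm),
            pearson(pf$median_mm, as.numeric(pf$group)),
            pearson(pp$prediction_rate_pct, meta$gtv_volume_cm3),
            pearson(pp$prediction_rate_pct, meta$motion_range_mm),
            pearson(pf$prediction_rate_pct, as.numeric(pf$group))))
  }
  out <- list(all = one_pass(per_patient, per_fraction))
  if (!is.null(exclude_patient)) {
    sub <- frames[frames$patient != exclude_patient, ]
    pp <- per_patient[per_patient$group != exclude_patient, ]
    pf <- do.call(rbind, lapply(split(sub, sub$fraction), function(g) {
      gc <- g$marker_detected & g$markerless_predicted & !is.na(g$deviation)
      data.frame(group = g$fraction[1],
                 median_mm = if (any(gc))
                   stats::median(g$deviation[gc]) else NA_real_,
                 prediction_rate_pct =
                   prediction_rate(sum(g$markerless_predicted), nrow(g)))
    }))
    out$excluded <- one_pass(pp, pf)
    out$excluded_patient <- exclude_patient
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("evaluation_report: %d frame pairs, %d marker-detected (%.1f%%), ",
           "%d predicted (%.1f%%), %d compared\n"),
    x$n_pairs_total, x$n_marker_detected, x$marker_detection_rate_pct,
    x$n_markerless_predicted, x$markerless_prediction_rate_pct, x$n_compared))
  cat(sprintf("  3D deviation: median %.2f (IQR %.2f-%.2f) mm\n",
              x$median, x$iqr_low, x$iqr_high))
  for (i in seq_len(nrow(x$cumulative)))
    cat(sprintf("  <= %g mm: %.1f%%\n",
                x$cumulative$threshold_mm[i], x$cumulative$percent[i]))
  invisible(x)
}

#' Cumulative percentage curve plot
#'
#' Empirical cumulative curve of the 3D deviation, in percent.
#'
#' @param report an `evaluation_report`
#' @param path output PNG path
#' @return invisibly, `path`
#' @export
plot_cumulative_curve <- function(report, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  d <- sort(report$deviations)
  plot(d, 100 * seq_along(d) / length(d), type = "s",
       xlab = "3D deviation [mm]", ylab = "cumulative percentage [%]",
       main = "Cumulative percentage curve of 3D deviation")
  graphics::abline(v = c(3, 5), lty = 3)
  invisible(path)
}
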