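# Published summary tables of a ten-patient lung-cancer cohort treated with
# marker-implanted real-time tumor tracking (seven-to-nine-port non-coplanar
# static beams, 50 Gy in four fractions), shipped as plain-text inputs for
# the statistics machinery: patient characteristics (GTV volume, mean GTV
# HU, 3D motion range, marker count), per-patient and per-fraction tracking
# results (median/IQR of the 3D deviation, prediction rate), and the frame
# accounting of the stored orthogonal image pairs.

#' Load the packaged clinical cohort summary
#'
#' @return list with data frames `patients`, `per_patient`, `per_fraction`
#'   and the list `frame_counts` (`n_pairs_stored`, `n_marker_detected`,
#'   `n_markerless_predicted`, `n_compared`)
#' @export
cohort_summary <- function() {
  p <- function(f) system.file("extdata", f, package = "orthotrack")
  list(
    patients = utils::read.csv(p("cohort_patients.csv")),
    per_patient = utils::read.csv(p("cohort_per_patient.csv")),
    per_fraction = utils::read.csv(p("cohort_per_fraction.csv")),
    frame_counts = jsonlite::read_json(p("cohort_frame_counts.json"),
                                       simplifyVector = TRUE)
  )
}

#' Correlations of cohort tracking results with cohort covariates
#'
#' Pearson r of the per-patient median 3D deviation and prediction rate
#' against GTV volume and motion range, and of the per-fraction summaries
#' against fraction index; optionally recomputed with one patient excluded
#' (an outlier-leverage check -- fraction-level rows cannot be recomputed
#' from the summary tables, so the excluded pass covers the patient-level
#' covariates only).
#'
#' @param cohort a [cohort_summary()] result
#' @param exclude_patient optional patient index to drop
#' @return data frame with columns `quantity`, `covariate`, `r` (and `r_excl`
#'   where computable)
#' @export
cohort_correlations <- function(cohort = cohort_summary(),
                                exclude_patient = NULL) {
  pp <- cohort$per_patient
  meta <- cohort$patients[match(pp$patient, cohort$patients$patient), ]
  pf <- cohort$per_fraction
  out <- data.frame(
    quantity = rep(c("median_deviation", "prediction_rate"), each = 3),
    covariate = rep(c("gtv_volume", "motion_range", "fraction_index"), 2),
    r = c(pearson(pp$median_mm, meta$gtv_volume_cm3),
          pearson(pp$median_mm, meta$motion_range_mm),
          pearson(pf$median_mm, pf$fraction),
          pearson(pp$prediction_rate_pct, meta$gtv_volume_cm3),
          pearson(pp$prediction_rate_pct, meta$motion_range_mm),
          pearson(pf$prediction_rate_pct, pf$fraction)))
  if (!is.null(exclude_patient)) {
    k <- pp$patient != exclude_patient
    out$r_excl <- c(pearson(pp$median_mm[k], meta$gtv_volume_cm3[k]),
                    pearson(pp$median_mm[k], meta$motion_range_mm[k]),
                    NA_real_,
                    pearson(pp$prediction_rate_pct[k], meta$gtv_volume_cm3[k]),
                    pearson(pp$prediction_rate_pct[k], meta$motion_range_mm[k]),
                    NA_real_)
  }
  out
}
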