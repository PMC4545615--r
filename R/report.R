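## Matched-pair radionuclide simulation, tumor-to-marrow ratios, cohort
## summaries and the dose-toxicity separation analysis.

#' Rescale a serial activity map to a different radionuclide
#'
#' Matched-pair dosimetry: an activity series imaged with one nuclide is
#' converted to the series a chemically identical compound labeled with
#' another nuclide would have produced — same administered activity, same
#' biological kinetics, only the physical decay swapped. Each volume at
#' time t is multiplied by
#' \eqn{e^{-(\lambda_{to} - \lambda_{from}) t}}.
#'
#' @param activitySeries a \linkS4class{TimeSeriesVolumes}.
#' @param fromNuclide imaged \linkS4class{Nuclide} (e.g. 177Lu).
#' @param toNuclide simulated \linkS4class{Nuclide} (e.g. 90Y).
#' @return The rescaled \linkS4class{TimeSeriesVolumes}.
#' @export
rescaleActivityForNuclide <- function(activitySeries, fromNuclide,
                                      toNuclide) {
  dl <- decayConstantPerH(toNuclide) - decayConstantPerH(fromNuclide)
  vols <- lapply(seq_along(activitySeries@timesH), function(i) {
    v <- activitySeries@volumes[[i]]
    scalarVolume(v@values * exp(-dl * activitySeries@timesH[i]), v@grid,
                 v@quantity)
  })
  timeSeriesVolumes(activitySeries@timesH, vols)
}

#' Tumor-to-marrow dose ratio
#'
#' @param adTumorGy tumor absorbed dose (Gy).
#' @param adRbmGy marrow absorbed dose (Gy), positive.
#' @return The ratio.
#' @export
tumorRbmRatio <- function(adTumorGy, adRbmGy) {
  if (any(adRbmGy <= 0)) stop("marrow dose must be positive for a ratio")
  adTumorGy / adRbmGy
}

#' One matched-pair comparison row
#'
#' @param patientId patient identifier.
#' @param ratioLu tumor-to-marrow ratio under the imaged nuclide.
#' @param ratioY tumor-to-marrow ratio under the simulated nuclide.
#' @return data.frame row with the percentage difference computed against
#'   the imaged-nuclide ratio.
#' @export
matchedPairResult <- function(patientId, ratioLu, ratioY) {
  stopifnot(ratioLu > 0, ratioY > 0)
  data.frame(patient_id = patientId, ratio_lu = ratioLu, ratio_y = ratioY,
             percent_difference = 100 * (ratioY - ratioLu) / ratioLu)
}

#' Summarise a matched-pair table
#'
#' Arithmetic means of the two ratio columns and of the per-patient
#' percentage differences.
#'
#' @param results data.frame with columns \code{ratio_lu}, \code{ratio_y},
#'   \code{percent_difference} (e.g. the packaged fixture
#'   \code{matched_pair_ratios.csv}).
#' @return list(meanRatioLu, meanRatioY, meanPercentDifference).
#' @export
matchedPairSummary <- function(results) {
  stopifnot(nrow(results) >= 1L)
  list(meanRatioLu = mean(results$ratio_lu),
       meanRatioY = mean(results$ratio_y),
       meanPercentDifference = mean(results$percent_difference))
}

#' Dose-toxicity separation analysis
#'
#' Partitions the cohort by a toxicity rule — \code{"any_toxicity"}: either
#' hematologic grade >= 1; \code{"thrombocytopenia_only"}: platelet grade
#' >= 1 — and reports the extreme doses of each group, whether the dose
#' column fully separates the groups, and the midpoint threshold when it
#' does.
#'
#' @param cohort cohort data.frame (see \code{\link{loadCohort}}).
#' @param doseField name of the dose column to analyse.
#' @param toxicityRule "any_toxicity" or "thrombocytopenia_only".
#' @return A \linkS4class{SeparationReport}.
#' @export
toxicitySeparation <- function(cohort, doseField = "ad_rbm_3d_Gy",
                               toxicityRule = c("any_toxicity",
                                                "thrombocytopenia_only")) {
  toxicityRule <- match.arg(toxicityRule)
  stopifnot(nrow(cohort) >= 1L)
  if (!doseField %in% names(cohort))
    stop("dose column not present: ", doseField)
  tox <- if (toxicityRule == "any_toxicity")
    cohort$grade_thrombocytopenia >= 1L | cohort$grade_leucopenia >= 1L
  else cohort$grade_thrombocytopenia >= 1L
  d <- cohort[[doseField]]
  dTox <- d[tox]; dNo <- d[!tox]
  maxNo <- if (length(dNo)) max(dNo) else NA_real_
  minNo <- if (length(dNo)) min(dNo) else NA_real_
  minTox <- if (length(dTox)) min(dTox) else NA_real_
  maxTox <- if (length(dTox)) max(dTox) else NA_real_
  sep <- is.finite(maxNo) && is.finite(minTox) && maxNo < minTox
  new("SeparationReport", method = doseField,
      maxDoseNoToxicityGy = maxNo, minDoseToxicityGy = minTox,
      maxDoseToxicityGy = maxTox, minDoseNoToxicityGy = minNo,
      fullySeparated = sep,
      separatingThresholdGy = if (sep) (maxNo + minTox) / 2 else NA_real_)
}

#' Cohort column means
#'
#' Arithmetic means of the dose and volume columns, with a rounded
#' reporting copy at the conventional table precision (doses to 2 decimals,
#' volumes and ages to integers). Internal values stay full precision; the
#' rounding is a reporting-layer convention only.
#'
#' @param cohort cohort data.frame.
#' @return list(raw, rounded): named numeric vectors of column means.
#' @export
cohortSummary <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  cols <- intersect(c("age_years", "tumor_volume_mL",
                      "administered_activity_GBq", "ad_tumor_3d_Gy",
                      "ad_rbm_3d_Gy", "ad_tumor_sphere_Gy",
                      "ad_rbm_blood_Gy", "ad_rbm_cranium_Gy"),
                    names(cohort))
  raw <- vapply(cols, function(cn) mean(cohort[[cn]]), numeric(1))
  digits <- ifelse(grepl("_Gy$|_GBq$", cols), 2L, 0L)
  rounded <- round(raw, digits)
  list(raw = raw, rounded = rounded)
}
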