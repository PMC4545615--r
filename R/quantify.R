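#' SPECT calibration: counts to activity
#'
#' Calibration factor from a phantom acquisition with known activity (the
#' activity must already be decay-corrected to the acquisition time):
#' factor = activity / total counts over the calibration VOI.
#'
#' @param knownActivityMBq phantom activity at acquisition time (MBq).
#' @param countsVolume counts \linkS4class{ScalarVolume}.
#' @param mask optional \linkS4class{VoiMask} drawn around the phantom;
#'   defaults to the full grid.
#' @return A \linkS4class{CalibrationResult}.
#' @export
calibrate <- function(knownActivityMBq, countsVolume, mask = NULL) {
  stopifnot(is(countsVolume, "ScalarVolume"),
            countsVolume@quantity == "counts", knownActivityMBq > 0)
  total <- if (is.null(mask)) sum(countsVolume@values)
           else sum(countsVolume@values[mask@mask])
  if (total <= 0) stop("zero counts in the calibration VOI")
  new("CalibrationResult", factorMBqPerCount = knownActivityMBq / total,
      sourceActivityMBq = knownActivityMBq, totalCounts = total)
}

#' Apply a calibration factor to a counts volume
#'
#' @param countsVolume counts \linkS4class{ScalarVolume}.
#' @param factorMBqPerCount calibration factor (MBq per count), positive.
#' @return An activity \linkS4class{ScalarVolume} (MBq).
#' @export
applyCalibration <- function(countsVolume, factorMBqPerCount) {
  stopifnot(is(countsVolume, "ScalarVolume"),
            countsVolume@quantity == "counts", factorMBqPerCount > 0)
  scalarVolume(countsVolume@values * factorMBqPerCount, countsVolume@grid,
               "activity_MBq")
}

#' Paralyzable dead-time model
#'
#' Observed count rate of a paralyzable detector,
#' \eqn{m = n e^{-n \tau}}, for true rate \eqn{n} and dead time \eqn{\tau}.
#' The companion \code{deadtimeLossFraction} gives the lost fraction
#' \eqn{1 - e^{-n\tau}}. The model quantifies the error bound of leaving
#' images uncorrected; no image correction is applied anywhere in the
#' pipeline.
#'
#' @param trueRateCps true event rate (counts/s), >= 0.
#' @param tauS dead time (s), >= 0.
#' @return Observed rate (counts/s) / loss fraction.
#' @examples
#' deadtimeLossFraction(5e3, 2e-6)   # ~1% at the protocol's worst case
#' @export
deadtimeObservedRate <- function(trueRateCps, tauS) {
  stopifnot(all(trueRateCps >= 0), all(tauS >= 0))
  trueRateCps * exp(-trueRateCps * tauS)
}

#' @rdname deadtimeObservedRate
#' @export
deadtimeLossFraction <- function(trueRateCps, tauS) {
  stopifnot(all(trueRateCps >= 0), all(tauS >= 0))
  1 - exp(-trueRateCps * tauS)
}

#' Body contour by threshold
#'
#' Voxels above the threshold, reduced to the largest 6-connected component
#' (conservative body segmentation).
#'
#' @param volume a \linkS4class{ScalarVolume}.
#' @param threshold value above which a voxel belongs to the body, >= 0.
#' @return A \linkS4class{VoiMask} labeled "body".
#' @export
contourByThreshold <- function(volume, threshold) {
  stopifnot(is(volume, "ScalarVolume"), threshold >= 0)
  m <- volume@values > threshold
  if (!any(m))
    stop(sprintf("empty contour at threshold %g (volume max %g): reduce the threshold",
                 threshold, max(volume@values)))
  lab <- array(.labelComponents6(as.logical(m), gridShape(volume)),
               dim = dim(m))
  keep <- as.integer(names(which.max(table(lab[lab > 0L]))))
  voiMask(lab == keep, volume@grid, "body")
}

#' Match a body contour across scans
#'
#' Finds the threshold for a later (lower-count) scan whose contour volume
#' matches a reference contour, by bisection on the monotone voxel count
#' above threshold. Returns the chosen threshold and the resulting contour;
#' when the achievable volume differs from the reference by more than one
#' voxel (a step in the count function), the result carries a warning flag.
#'
#' @param reference the reference \linkS4class{VoiMask} (first scan).
#' @param volume the \linkS4class{ScalarVolume} to contour.
#' @return list(threshold, mask, volumeMismatchVoxels, warn).
#' @export
matchContour <- function(reference, volume) {
  stopifnot(is(reference, "VoiMask"), is(volume, "ScalarVolume"))
  target <- sum(reference@mask)
  if (target == 0L) stop("reference contour is empty")
  if (max(volume@values) <= 0) stop("volume has no positive values to contour")
  lo <- 0; hi <- max(volume@values)
  cnt <- function(th) sum(volume@values > th)
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (cnt(mid) > target) lo <- mid else hi <- mid
  }
  # lo gives count >= target, hi count <= target: pick the closer
  th <- if (abs(cnt(lo) - target) <= abs(cnt(hi) - target)) lo else hi
  mask <- contourByThreshold(volume, th)
  mismatch <- abs(sum(mask@mask) - target)
  list(threshold = th, mask = mask, volumeMismatchVoxels = mismatch,
       warn = mismatch > 1L)
}
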