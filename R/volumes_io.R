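## NIfTI I/O with a JSON sidecar: NIfTI has no slot for the physical
## quantity, so it rides in "<stem>.json" next to the volume, together with
## the world origin.

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a scalar volume from NIfTI
#'
#' Grid spacing comes from the NIfTI header (isotropic within 1e-6 mm
#' relative tolerance; anisotropic volumes are rejected with the offending
#' spacing triple). The quantity is taken from the JSON sidecar written by
#' \code{\link{writeVolume}}, or from the \code{quantity} argument which
#' overrides it.
#'
#' @param path a .nii or .nii.gz file.
#' @param quantity optional quantity tag overriding the sidecar.
#' @return A \linkS4class{ScalarVolume}.
#' @export
readVolume <- function(path, quantity = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (diff(range(spacing)) > 1e-6 * mean(spacing))
    stop(sprintf("anisotropic voxels not supported: spacing (%g, %g, %g) mm",
                 spacing[1], spacing[2], spacing[3]))
  side <- .sidecarPath(path)
  origin <- c(0, 0, 0)
  if (is.null(quantity)) {
    if (!file.exists(side))
      stop("no sidecar and no quantity argument for ", path)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    quantity <- meta$quantity
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
  } else if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
  }
  vals <- array(as.numeric(img), dim = dim(img))
  grid <- voxelGrid(dim(img), voxelSizeMm = mean(spacing), originMm = origin)
  scalarVolume(vals, grid, quantity)
}

#' Write a scalar volume to NIfTI (+ JSON sidecar)
#'
#' @param volume a \linkS4class{ScalarVolume}.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- rep(volume@grid@voxelSizeMm, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(quantity = volume@quantity,
                            voxel_size_mm = volume@grid@voxelSizeMm,
                            origin_mm = volume@grid@originMm),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.COHORT_NUMERIC <- c("administered_activity_GBq", "tumor_volume_mL",
                     "ad_tumor_3d_Gy", "ad_rbm_3d_Gy", "ad_tumor_sphere_Gy",
                     "ad_rbm_blood_Gy", "ad_rbm_cranium_Gy")
.COHORT_GRADES <- c("grade_thrombocytopenia", "grade_leucopenia")

#' Load a patient cohort table
#'
#' Reads the per-patient CSV (administered activity, tumor VOI volume, the
#' method-wise absorbed doses and the hematologic toxicity grades) and
#' validates every row: grades must be integers 0-4 and doses non-negative.
#' The packaged cohort fixture is available via
#' \code{system.file("extdata", "cohort_doses.csv", package = "voxdose")}.
#'
#' @param path CSV path with the cohort columns.
#' @return A validated data.frame, one row per patient.
#' @examples
#' cohort <- loadCohort(system.file("extdata", "cohort_doses.csv",
#'                                  package = "voxdose"))
#' nrow(cohort)   # 13
#' @export
loadCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort file has no data rows: ", path)
  need <- c("patient_id", .COHORT_GRADES,
            setdiff(.COHORT_NUMERIC, c("ad_rbm_blood_Gy", "ad_rbm_cranium_Gy")))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  for (g in .COHORT_GRADES) {
    bad <- which(is.na(df[[g]]) | df[[g]] %% 1 != 0 | df[[g]] < 0 | df[[g]] > 4)
    if (length(bad))
      stop(sprintf("row %d: %s must be an integer grade 0-4", bad[1L], g))
    df[[g]] <- as.integer(df[[g]])
  }
  for (d in intersect(.COHORT_NUMERIC, names(df))) {
    bad <- which(!is.na(df[[d]]) & df[[d]] < 0)
    if (length(bad))
      stop(sprintf("row %d: %s must be non-negative", bad[1L], d))
  }
  df
}

#' Write a cohort table to CSV
#'
#' Round-trips with \code{\link{loadCohort}}.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
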