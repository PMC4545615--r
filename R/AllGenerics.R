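#' Construct a voxel grid
#'
#' @param shape integer triple (nx, ny, nz).
#' @param voxelSizeMm isotropic voxel edge length in mm (default 4.795, the
#'   reconstructed SPECT voxel size of the serial-imaging protocol).
#' @param originMm world coordinate of the first voxel centre.
#' @return A \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(shape, voxelSizeMm = 4.795, originMm = c(0, 0, 0)) {
  new("VoxelGrid", shape = as.integer(shape), voxelSizeMm = voxelSizeMm,
      originMm = as.numeric(originMm))
}

#' Construct a scalar volume
#'
#' @param values numeric 3D array (or a scalar, recycled over the grid).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param quantity the physical quantity of the values.
#' @return A \linkS4class{ScalarVolume}.
#' @export
scalarVolume <- function(values, grid, quantity) {
  if (length(values) == 1L)
    values <- array(values, dim = grid@shape)
  new("ScalarVolume", grid = grid, values = values, quantity = quantity)
}

#' Construct a VOI mask
#' @param mask logical 3D array.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param label VOI name.
#' @return A \linkS4class{VoiMask}.
#' @export
voiMask <- function(mask, grid, label = "VOI") {
  new("VoiMask", grid = grid, mask = mask, label = label)
}

#' Construct a serial volume set
#' @param timesH acquisition times in hours.
#' @param volumes list of \linkS4class{ScalarVolume}.
#' @return A \linkS4class{TimeSeriesVolumes}.
#' @export
timeSeriesVolumes <- function(timesH, volumes) {
  new("TimeSeriesVolumes", timesH = as.numeric(timesH), volumes = volumes)
}

#' Construct a blood time-activity series
#' @param timesH sample times (h).
#' @param concentrationMBqPerMl measured concentrations (MBq/mL).
#' @param wholeBodyMBq optional parallel whole-body activity series (MBq).
#' @return A \linkS4class{BloodSeries}.
#' @export
bloodSeries <- function(timesH, concentrationMBqPerMl,
                        wholeBodyMBq = numeric(0)) {
  new("BloodSeries", timesH = as.numeric(timesH),
      concentrationMBqPerMl = as.numeric(concentrationMBqPerMl),
      wholeBodyMBq = as.numeric(wholeBodyMBq))
}

## ---- accessors ----

#' @describeIn voxelGrid grid dimensions.
#' @param x object carrying a grid.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @export
setMethod("gridShape", "ScalarVolume", function(x) x@grid@shape)
#' @export
setMethod("gridShape", "VoiMask", function(x) x@grid@shape)

#' @describeIn voxelGrid isotropic voxel edge length (mm).
#' @export
setGeneric("voxelSizeMm", function(x) standardGeneric("voxelSizeMm"))
#' @export
setMethod("voxelSizeMm", "VoxelGrid", function(x) x@voxelSizeMm)
#' @export
setMethod("voxelSizeMm", "ScalarVolume", function(x) x@grid@voxelSizeMm)

#' @describeIn voxelGrid derived voxel volume in mL, (voxelSizeMm/10)^3.
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @export
setMethod("voxelVolumeMl", "VoxelGrid", function(x) (x@voxelSizeMm / 10)^3)
#' @export
setMethod("voxelVolumeMl", "ScalarVolume", function(x) voxelVolumeMl(x@grid))
#' @export
setMethod("voxelVolumeMl", "VoiMask", function(x) voxelVolumeMl(x@grid))

#' Values array of a scalar volume
#' @param x a \linkS4class{ScalarVolume}.
#' @return The numeric 3D array.
#' @export
setGeneric("volumeValues", function(x) standardGeneric("volumeValues"))
#' @export
setMethod("volumeValues", "ScalarVolume", function(x) x@values)

#' Quantity tag of a scalar volume
#' @param x a \linkS4class{ScalarVolume}.
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))
#' @export
setMethod("quantity", "ScalarVolume", function(x) x@quantity)

#' Time axis (hours) of a serial object
#' @param x a \linkS4class{TimeSeriesVolumes}, \linkS4class{BloodSeries} or
#'   \linkS4class{HybridFit}.
#' @export
setGeneric("timesH", function(x) standardGeneric("timesH"))
#' @export
setMethod("timesH", "TimeSeriesVolumes", function(x) x@timesH)
#' @export
setMethod("timesH", "BloodSeries", function(x) x@timesH)
#' @export
setMethod("timesH", "HybridFit", function(x) x@timesH)

#' Absorbed dose (Gy) of a report
#' @param x a report object.
#' @export
setGeneric("adGy", function(x) standardGeneric("adGy"))
#' @export
setMethod("adGy", "RbmDoseReport", function(x) x@adGy)

#' Biologically effective dose (Gy) of a report
#' @param x a report object.
#' @export
setGeneric("bedGy", function(x) standardGeneric("bedGy"))
#' @export
setMethod("bedGy", "RbmDoseReport", function(x) x@bedGy)

#' Decay constant ln(2)/half-life (1/h)
#' @param x a \linkS4class{Nuclide}.
#' @export
setGeneric("decayConstantPerH", function(x) standardGeneric("decayConstantPerH"))
#' @export
setMethod("decayConstantPerH", "Nuclide", function(x) log(2) / x@halfLifeH)

## ---- show methods ----

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s at %.4g mm (voxel %.5g mL)\n",
              paste(object@shape, collapse = " x "), object@voxelSizeMm,
              voxelVolumeMl(object)))
})

setMethod("show", "ScalarVolume", function(object) {
  v <- object@values
  cat(sprintf("ScalarVolume <%s> %s at %.4g mm | total %.6g, max %.6g\n",
              object@quantity, paste(dim(v), collapse = " x "),
              object@grid@voxelSizeMm, sum(v), max(v)))
})

setMethod("show", "VoiMask", function(object) {
  cat(sprintf("VoiMask '%s': %d voxels (%.2f mL)\n", object@label,
              sum(object@mask), sum(object@mask) * voxelVolumeMl(object)))
})

setMethod("show", "TimeSeriesVolumes", function(object) {
  cat(sprintf("TimeSeriesVolumes <%s>: %d time points at %s h\n",
              object@volumes[[1L]]@quantity, length(object@timesH),
              paste(signif(object@timesH, 4), collapse = ", ")))
})

setMethod("show", "Nuclide", function(object) {
  cat(sprintf("Nuclide %s: T1/2 %.4g h, %d photon line(s), beta %s (mean %.4g MeV)\n",
              object@name, object@halfLifeH, nrow(object@photonLines),
              object@betaTransport, object@betaMeanEnergyMeV))
})

setMethod("show", "DosimetryConfig", function(object) {
  cat("DosimetryConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-26s %.6g\n", s, slot(object, s)))
})

setMethod("show", "HybridFit", function(object) {
  cat(sprintf("HybridFit: integral %.6g (value x h), tail rate %.5g /h%s, leading rule '%s'\n",
              object@integral, object@tailRatePerH,
              if (object@tailFallbackUsed) " [fallback]" else "",
              object@leadingRule))
})

setMethod("show", "DoseRateResult", function(object) {
  cat(sprintf("DoseRateResult: %d histories (seed %d)\n",
              as.integer(object@nHistories), as.integer(object@seed)))
  cat(sprintf("  energy MeV/decay: emitted %.6g = deposited %.6g + escaped %.6g\n",
              object@energyEmittedMeV, object@energyDepositedMeV,
              object@energyEscapedMeV))
})

setMethod("show", "RbmDoseReport", function(object) {
  cat(sprintf("RbmDoseReport [%s]: AD %.4g Gy%s\n", object@method, object@adGy,
              if (is.na(object@bedGy)) ""
              else sprintf(", BED %.4g Gy", object@bedGy)))
})

setMethod("show", "TumorDoseReport", function(object) {
  cat(sprintf("TumorDoseReport: 3D %.4g Gy vs sphere %.4g Gy (%+.2f%%), mass %.4g g\n",
              object@ad3dGy, object@adSphereGy,
              100 * object@fractionalDifference, object@massG))
})

setMethod("show", "SeparationReport", function(object) {
  cat(sprintf("SeparationReport [%s]: no-tox max %.3g Gy, tox range %.3g-%.3g Gy, %s\n",
              object@method, object@maxDoseNoToxicityGy,
              object@minDoseToxicityGy, object@maxDoseToxicityGy,
              if (object@fullySeparated)
                sprintf("separated (threshold %.3g Gy)",
                        object@separatingThresholdGy)
              else "not separated"))
})
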