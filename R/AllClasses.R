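#' @useDynLib voxdose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats approx integrate rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

VOLUME_QUANTITIES <- c("activity_MBq", "density_g_cm3", "doserate_Gy_h",
                       "dose_Gy", "counts")

COMPOSITION_LEVELS <- c(soft_tissue = 1L, lung = 2L, bone = 3L)

#' Voxel grid geometry
#'
#' Geometry shared by all volumes in a dosimetry study: an isotropic voxel
#' lattice defined by its dimensions, voxel edge length and world origin.
#' The voxel volume in mL is always derived as \code{(voxelSizeMm/10)^3},
#' never stored.
#'
#' @slot shape integer vector of length 3 (nx, ny, nz), all >= 1.
#' @slot voxelSizeMm positive isotropic voxel edge length in mm.
#' @slot originMm world coordinate (mm) of the centre of voxel (1,1,1).
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", voxelSizeMm = "numeric",
                 originMm = "numeric"),
  prototype(shape = c(64L, 64L, 48L), voxelSizeMm = 4.795,
            originMm = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@voxelSizeMm) != 1L || !is.finite(object@voxelSizeMm) ||
      object@voxelSizeMm <= 0)
    msg <- c(msg, "voxelSizeMm must be a single positive number")
  if (length(object@originMm) != 3L || any(!is.finite(object@originMm)))
    msg <- c(msg, "originMm must be three finite numbers")
  if (length(msg)) msg else TRUE
})

#' Scalar voxel field
#'
#' A 3D array of one physical quantity (activity, density, dose rate, dose or
#' raw counts) on a \linkS4class{VoxelGrid}. Non-negativity is enforced for
#' all supported quantities.
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot values numeric 3D array matching \code{gridShape(grid)}.
#' @slot quantity one of \code{"activity_MBq"}, \code{"density_g_cm3"},
#'   \code{"doserate_Gy_h"}, \code{"dose_Gy"}, \code{"counts"}.
#' @export
setClass("ScalarVolume",
  representation(grid = "VoxelGrid", values = "array", quantity = "character"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, sprintf("values dim (%s) does not match grid shape (%s)",
                          paste(dim(object@values), collapse = "x"),
                          paste(object@grid@shape, collapse = "x")))
  if (!(object@quantity %in% VOLUME_QUANTITIES))
    msg <- c(msg, sprintf("unknown quantity '%s'", object@quantity))
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, sprintf("%s values must be non-negative", object@quantity))
  if (length(msg)) msg else TRUE
})

#' Tissue composition labels
#'
#' Per-voxel material class used by the transport engine: soft tissue, lung
#' or bone, stored as integer codes 1/2/3.
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot labels integer 3D array with values in 1..3.
#' @export
setClass("CompositionVolume",
  representation(grid = "VoxelGrid", labels = "array"))

setValidity("CompositionVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "labels dim does not match grid shape")
  if (!all(object@labels %in% COMPOSITION_LEVELS))
    msg <- c(msg, "every voxel must be labeled soft_tissue, lung or bone")
  if (length(msg)) msg else TRUE
})

#' Volume-of-interest mask
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot mask logical 3D array.
#' @slot label free-text VOI name (e.g. "LV", "tumor").
#' @export
setClass("VoiMask",
  representation(grid = "VoxelGrid", mask = "array", label = "character"))

setValidity("VoiMask", function(object) {
  msg <- character()
  if (!identical(dim(object@mask), as.integer(object@grid@shape)))
    msg <- c(msg, "mask dim does not match grid shape")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' Serial volumes on one time axis
#'
#' Ordered acquisition times (hours post administration) with one
#' \linkS4class{ScalarVolume} each; all volumes share a grid and a quantity.
#' This is the dosimetric time axis: four time points for the standard
#' serial-SPECT protocol.
#'
#' @slot timesH strictly increasing acquisition times in hours, first >= 0.
#' @slot volumes list of \linkS4class{ScalarVolume}.
#' @export
setClass("TimeSeriesVolumes",
  representation(timesH = "numeric", volumes = "list"))

setValidity("TimeSeriesVolumes", function(object) {
  msg <- character()
  n <- length(object@timesH)
  if (n < 2L) msg <- c(msg, "need at least 2 time points")
  if (length(object@volumes) != n)
    msg <- c(msg, "times and volumes lengths differ")
  if (n >= 1L && (object@timesH[1L] < 0 || any(diff(object@timesH) <= 0)))
    msg <- c(msg, "times must be strictly increasing and start at >= 0")
  if (length(object@volumes)) {
    if (!all(vapply(object@volumes, is, logical(1), "ScalarVolume")))
      msg <- c(msg, "volumes must all be ScalarVolume")
    else {
      q <- vapply(object@volumes, function(v) v@quantity, character(1))
      if (length(unique(q)) != 1L)
        msg <- c(msg, "volumes must share one quantity")
      shp <- vapply(object@volumes, function(v)
        paste(v@grid@shape, collapse = "x"), character(1))
      if (length(unique(shp)) != 1L)
        msg <- c(msg, "volumes must share one grid")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Radionuclide decay and emission data
#'
#' Half-life plus the emission list that drives the Monte Carlo engine:
#' photon lines (energy, yield per decay) and a beta branch either deposited
#' locally (mean energy; appropriate when the mean beta range is sub-voxel,
#' as for 177Lu at 4.795 mm voxels) or transported along straight
#' continuous-slowing-down paths (\code{betaTransport = "csda"}; required for
#' 90Y whose range exceeds the voxel size). For csda transport the spectrum
#' is sampled from the allowed-transition Fermi shape defined by
#' \code{betaEndpointMeV} and \code{daughterZ}.
#'
#' @slot name nuclide name, e.g. "Lu-177".
#' @slot halfLifeH physical half-life in hours.
#' @slot photonLines numeric matrix with columns energy_MeV, yield_per_decay
#'   (zero rows for a pure beta emitter).
#' @slot betaMeanEnergyMeV mean beta energy per decay (MeV).
#' @slot betaYield beta yield per decay.
#' @slot betaTransport "local" or "csda".
#' @slot betaEndpointMeV spectrum endpoint (MeV); 0 when unused.
#' @slot daughterZ atomic number of the daughter (Coulomb correction); 0 when
#'   unused.
#' @export
setClass("Nuclide",
  representation(name = "character", halfLifeH = "numeric",
                 photonLines = "matrix", betaMeanEnergyMeV = "numeric",
                 betaYield = "numeric", betaTransport = "character",
                 betaEndpointMeV = "numeric", daughterZ = "numeric"))

setValidity("Nuclide", function(object) {
  msg <- character()
  if (object@halfLifeH <= 0) msg <- c(msg, "halfLifeH must be positive")
  if (ncol(object@photonLines) != 2L)
    msg <- c(msg, "photonLines needs columns energy_MeV, yield_per_decay")
  if (nrow(object@photonLines) &&
      (any(object@photonLines[, 1L] <= 0) || any(object@photonLines[, 2L] < 0)))
    msg <- c(msg, "photon energies must be positive, yields non-negative")
  if (object@betaYield < 0 || object@betaMeanEnergyMeV < 0)
    msg <- c(msg, "beta energy and yield must be non-negative")
  if (!(object@betaTransport %in% c("local", "csda")))
    msg <- c(msg, "betaTransport must be 'local' or 'csda'")
  if (object@betaTransport == "csda" && object@betaEndpointMeV <= 0)
    msg <- c(msg, "csda transport requires a positive betaEndpointMeV")
  if (length(msg)) msg else TRUE
})

#' Blood time-activity series
#'
#' Blood-sample concentrations (already decay-inclusive, i.e. as measured)
#' and an optional parallel whole-body activity series from conjugate-view
#' planar imaging.
#'
#' @slot timesH strictly increasing sample times (h).
#' @slot concentrationMBqPerMl non-negative concentrations (MBq/mL).
#' @slot wholeBodyMBq whole-body activities (MBq); length 0 when absent.
#' @export
setClass("BloodSeries",
  representation(timesH = "numeric", concentrationMBqPerMl = "numeric",
                 wholeBodyMBq = "numeric"))

setValidity("BloodSeries", function(object) {
  msg <- character()
  if (length(object@timesH) != length(object@concentrationMBqPerMl))
    msg <- c(msg, "times and concentrations lengths differ")
  if (any(diff(object@timesH) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@concentrationMBqPerMl)) ||
      any(object@concentrationMBqPerMl < 0))
    msg <- c(msg, "concentrations must be finite and non-negative")
  if (length(object@wholeBodyMBq) &&
      length(object@wholeBodyMBq) != length(object@timesH))
    msg <- c(msg, "whole-body series length differs from times")
  if (length(msg)) msg else TRUE
})

#' Study-wide dosimetry constants
#'
#' Every constant the pipeline fixes, in one validated container: the SPECT
#' calibration factor, the broad-beam attenuation coefficient, the
#' cranium-to-total red-marrow mass fraction, the marrow-to-blood activity
#' concentration ratio, linear-quadratic parameters for the biologically
#' effective dose, Monte Carlo history count and seed, and reference-phantom
#' placeholders (red-marrow mass and S-values) that a site should override
#' with model- or patient-specific values.
#'
#' Construct with \code{\link{dosimetryConfig}} rather than \code{new()}.
#'
#' @slot calibrationMBqPerCount SPECT calibration factor (MBq per count).
#' @slot attenuationCmInv broad-beam attenuation coefficient (1/cm).
#' @slot craniumRbmFraction cranium share of total skeletal red marrow.
#' @slot rbmToBloodRatio red-marrow-to-blood activity concentration ratio.
#' @slot alphaOverBetaGy linear-quadratic alpha/beta (Gy).
#' @slot repairRateMuPerH sublethal-damage repair rate mu (1/h).
#' @slot nHistories Monte Carlo histories per run.
#' @slot rngSeed Monte Carlo seed.
#' @slot rbmMassG red bone marrow mass (g), reference-phantom placeholder.
#' @slot sRbmSelfMGyPerMBqH red-marrow self S-value (mGy per MBq h).
#' @slot sRbmRemainderMGyPerMBqH remainder-of-body-to-marrow S-value
#'   (mGy per MBq h), reference-phantom placeholder.
#' @slot photonCutoffMeV photon transport cutoff energy (MeV).
#' @slot lungMaxGCm3 density below which a voxel is labeled lung (g/cm3).
#' @slot boneMinGCm3 density above which a voxel is labeled bone (g/cm3).
#' @slot densityFloorGCm3 density floor for mass division (g/cm3).
#' @export
setClass("DosimetryConfig",
  representation(calibrationMBqPerCount = "numeric",
                 attenuationCmInv = "numeric",
                 craniumRbmFraction = "numeric",
                 rbmToBloodRatio = "numeric",
                 alphaOverBetaGy = "numeric",
                 repairRateMuPerH = "numeric",
                 nHistories = "numeric",
                 rngSeed = "numeric",
                 rbmMassG = "numeric",
                 sRbmSelfMGyPerMBqH = "numeric",
                 sRbmRemainderMGyPerMBqH = "numeric",
                 photonCutoffMeV = "numeric",
                 lungMaxGCm3 = "numeric",
                 boneMinGCm3 = "numeric",
                 densityFloorGCm3 = "numeric"))

setValidity("DosimetryConfig", function(object) {
  msg <- character()
  pos <- c("calibrationMBqPerCount", "attenuationCmInv", "alphaOverBetaGy",
           "repairRateMuPerH", "nHistories", "rbmMassG",
           "sRbmSelfMGyPerMBqH", "sRbmRemainderMGyPerMBqH",
           "photonCutoffMeV", "lungMaxGCm3", "boneMinGCm3",
           "densityFloorGCm3")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  for (s in c("craniumRbmFraction", "rbmToBloodRatio")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v > 1 + 1e-12)
      if (s == "craniumRbmFraction")
        msg <- c(msg, sprintf("%s must lie in (0, 1]", s))
  }
  if (object@rbmToBloodRatio <= 0)
    msg <- c(msg, "rbmToBloodRatio must be positive")
  if (object@nHistories < 1)
    msg <- c(msg, "nHistories must be >= 1")
  if (object@boneMinGCm3 <= object@lungMaxGCm3)
    msg <- c(msg, "boneMinGCm3 must exceed lungMaxGCm3")
  if (length(msg)) msg else TRUE
})

#' Hybrid trapezoidal-exponential fit of a 4-point time series
#'
#' The serial-imaging integration rule: a leading segment from injection to
#' the first sample (rectangle at the first value, or zero), trapezoids
#' between the first three samples, and an exponential tail anchored at the
#' third sample with rate fitted to the final two samples (falling back to a
#' supplied physical decay constant when the series does not decrease).
#'
#' @slot timesH the four sample times (h).
#' @slot values the four sampled values.
#' @slot tailRatePerH exponential tail rate (1/h).
#' @slot integral integral of the piecewise function over [0, Inf).
#' @slot leadingRule "rectangle" or "zero".
#' @slot tailFallbackUsed TRUE when the physical-decay fallback replaced a
#'   non-decreasing tail.
#' @export
setClass("HybridFit",
  representation(timesH = "numeric", values = "numeric",
                 tailRatePerH = "numeric", integral = "numeric",
                 leadingRule = "character", tailFallbackUsed = "logical"))

setValidity("HybridFit", function(object) {
  msg <- character()
  if (object@tailRatePerH <= 0) msg <- c(msg, "tailRatePerH must be positive")
  if (!is.finite(object@integral) || object@integral < 0)
    msg <- c(msg, "integral must be finite and non-negative")
  if (!(object@leadingRule %in% c("rectangle", "zero")))
    msg <- c(msg, "leadingRule must be 'rectangle' or 'zero'")
  if (length(msg)) msg else TRUE
})

#' Monte Carlo dose-rate result
#'
#' Per-voxel dose rate with the run's energy ledger. The ledger closes
#' exactly: emitted = deposited + escaped (relative tolerance 1e-9).
#'
#' @slot doserate \linkS4class{ScalarVolume}, Gy/h.
#' @slot energyEmittedMeV total emission energy per decay-weighted history
#'   sum (MeV).
#' @slot energyDepositedMeV energy tallied on the grid (MeV).
#' @slot energyEscapedMeV energy lost across grid boundaries (MeV).
#' @slot nHistories histories run.
#' @slot seed RNG seed used.
#' @export
setClass("DoseRateResult",
  representation(doserate = "ScalarVolume", energyEmittedMeV = "numeric",
                 energyDepositedMeV = "numeric", energyEscapedMeV = "numeric",
                 nHistories = "numeric", seed = "numeric"))

setValidity("DoseRateResult", function(object) {
  msg <- character()
  bal <- object@energyDepositedMeV + object@energyEscapedMeV
  tol <- 1e-9 * max(object@energyEmittedMeV, 1e-300)
  if (abs(object@energyEmittedMeV - bal) > tol)
    msg <- c(msg, "energy ledger does not balance (emitted != deposited + escaped)")
  if (length(msg)) msg else TRUE
})

#' SPECT calibration result
#'
#' @slot factorMBqPerCount calibration factor, activity / total counts.
#' @slot sourceActivityMBq known source activity at acquisition (MBq).
#' @slot totalCounts summed counts over the calibration VOI.
#' @export
setClass("CalibrationResult",
  representation(factorMBqPerCount = "numeric", sourceActivityMBq = "numeric",
                 totalCounts = "numeric"))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (any(c(object@factorMBqPerCount, object@sourceActivityMBq,
            object@totalCounts) <= 0))
    msg <- c(msg, "all calibration fields must be positive")
  expect <- object@sourceActivityMBq / object@totalCounts
  if (abs(object@factorMBqPerCount - expect) > 1e-12 * expect)
    msg <- c(msg, "factor must equal activity / counts")
  if (length(msg)) msg else TRUE
})

#' Cumulative dose-volume histogram
#'
#' Volume fraction receiving at least each dose level; monotone
#' non-increasing from 1 at dose 0 to 0 beyond the maximum dose.
#'
#' @slot doseBinEdgesGy ordered bin edges (Gy), first = 0.
#' @slot volumeFractionAtLeast fraction of VOI volume with dose >= edge.
#' @export
setClass("Dvh",
  representation(doseBinEdgesGy = "numeric", volumeFractionAtLeast = "numeric"))

setValidity("Dvh", function(object) {
  msg <- character()
  if (length(object@doseBinEdgesGy) != length(object@volumeFractionAtLeast))
    msg <- c(msg, "edges and fractions lengths differ")
  if (any(diff(object@doseBinEdgesGy) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  f <- object@volumeFractionAtLeast
  if (any(f < -1e-12) || any(f > 1 + 1e-12) || any(diff(f) > 1e-12))
    msg <- c(msg, "fractions must be non-increasing within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Red bone marrow dose report
#'
#' One marrow dose estimate under a common interface, whichever of the three
#' competing routes produced it: 3D lumbar-vertebrae Monte Carlo
#' (\code{"lv_3d"}), blood-based (\code{"blood"}) or 2D cranium-based
#' conjugate-view (\code{"cranium_2d"}). Method-specific intermediates
#' (time-integrated activities, tail rates, G-factor, S-values used) are
#' embedded so every reported dose is reproducible.
#'
#' @slot method "lv_3d", "blood" or "cranium_2d".
#' @slot adGy mean absorbed dose (Gy).
#' @slot bedGy biologically effective dose (Gy); NA when not computed.
#' @slot intermediates named list of method-specific intermediates.
#' @export
setClass("RbmDoseReport",
  representation(method = "character", adGy = "numeric", bedGy = "numeric",
                 intermediates = "list"))

setValidity("RbmDoseReport", function(object) {
  msg <- character()
  if (!(object@method %in% c("lv_3d", "blood", "cranium_2d")))
    msg <- c(msg, "unknown method")
  if (!is.finite(object@adGy) || object@adGy < 0)
    msg <- c(msg, "adGy must be finite and non-negative")
  if (!is.na(object@bedGy) && object@bedGy < object@adGy - 1e-12)
    msg <- c(msg, "bedGy must be >= adGy")
  if (length(msg)) msg else TRUE
})

#' Tumor dose report
#'
#' Mean absorbed dose by full voxel Monte Carlo, the sphere-model dose for
#' the same VOI mass, their fractional difference, and the DVH.
#'
#' @slot ad3dGy mass-weighted mean VOI dose from the voxel dose map (Gy).
#' @slot adSphereGy sphere-model dose for the VOI mass (Gy).
#' @slot massG VOI mass from the density map (g).
#' @slot dvh the \linkS4class{Dvh}.
#' @slot fractionalDifference (ad3d - adSphere) / adSphere.
#' @export
setClass("TumorDoseReport",
  representation(ad3dGy = "numeric", adSphereGy = "numeric", massG = "numeric",
                 dvh = "Dvh", fractionalDifference = "numeric"))

setValidity("TumorDoseReport", function(object) {
  if (object@massG <= 0) "massG must be positive" else TRUE
})

#' Digital phantom specification
#'
#' Everything the synthetic-data generator needs to emulate a serial
#' quantitative-SPECT study: the grid, geometric compartments with densities
#' and biological kinetics, the administered activity and nuclide, the
#' acquisition schedule and a biexponential blood model.
#'
#' Each compartment is a named list with elements \code{name},
#' \code{shape} ("sphere", "box" or "ellipsoid"), \code{center_mm},
#' \code{size_mm} (radius, half-widths or semi-axes), \code{density_g_cm3}
#' and \code{kinetics}. Kinetics are the biological retention
#' \eqn{r(t) = a [f e^{-\lambda_1 t} + (1-f) e^{-\lambda_2 t}] +
#' u (1 - e^{-\lambda_u t})} expressed as the list
#' \code{list(amplitude, f, lambda1, lambda2, uptake = 0, lambda_u = 0)};
#' the amplitude is the compartment's share of the administered activity at
#' t = 0 and the uptake term models late marrow accumulation. Overlaps are
#' resolved by list order (earlier compartments win).
#'
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot compartments list of compartment definitions (see Details).
#' @slot administeredActivityMBq administered activity (MBq).
#' @slot nuclide the \linkS4class{Nuclide}.
#' @slot acquisitionTimesH acquisition times (h).
#' @slot bloodKinetics list(c0_MBq_per_mL, f, lambda1, lambda2): biexponential
#'   biological blood concentration, multiplied by physical decay when
#'   sampled.
#' @slot backgroundDensityGCm3 density outside all compartments (g/cm3).
#' @export
setClass("PhantomSpec",
  representation(grid = "VoxelGrid", compartments = "list",
                 administeredActivityMBq = "numeric", nuclide = "Nuclide",
                 acquisitionTimesH = "numeric", bloodKinetics = "list",
                 backgroundDensityGCm3 = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@administeredActivityMBq <= 0)
    msg <- c(msg, "administered activity must be positive")
  if (length(object@acquisitionTimesH) < 2L ||
      any(diff(object@acquisitionTimesH) <= 0) ||
      object@acquisitionTimesH[1L] < 0)
    msg <- c(msg, "acquisition times must be increasing and non-negative")
  r0 <- 0
  for (cp in object@compartments) {
    k <- cp$kinetics
    need <- c("amplitude", "f", "lambda1", "lambda2")
    if (!all(need %in% names(k))) {
      msg <- c(msg, sprintf("compartment '%s': incomplete kinetics", cp$name))
      next
    }
    if (k$f < 0 || k$f > 1)
      msg <- c(msg, sprintf("compartment '%s': f outside [0,1]", cp$name))
    if (k$lambda1 < 0 || k$lambda2 < 0)
      msg <- c(msg, sprintf("compartment '%s': negative rate", cp$name))
    r0 <- r0 + k$amplitude
  }
  if (r0 > 1 + 1e-9)
    msg <- c(msg, "compartment amplitudes sum to more than 1 at t = 0")
  if (length(msg)) msg else TRUE
})

#' Dose-to-toxicity label model
#'
#' Synthetic label generator for separation analyses: a noisy threshold on
#' marrow dose, with grades 1-4 assigned from breakpoints above the
#' threshold.
#'
#' @slot thresholdGy dose below which (after noise) the grade is 0.
#' @slot noiseSdGy standard deviation of the Gaussian dose perturbation.
#' @slot gradeBreakpointsGy strictly increasing upper bounds of grades 1-3;
#'   above the last breakpoint the grade is 4.
#' @export
setClass("ToxicityModel",
  representation(thresholdGy = "numeric", noiseSdGy = "numeric",
                 gradeBreakpointsGy = "numeric"))

setValidity("ToxicityModel", function(object) {
  msg <- character()
  if (object@thresholdGy < 0) msg <- c(msg, "threshold must be >= 0")
  if (object@noiseSdGy < 0) msg <- c(msg, "noise sd must be >= 0")
  if (any(diff(object@gradeBreakpointsGy) <= 0))
    msg <- c(msg, "breakpoints must be strictly increasing")
  if (length(object@gradeBreakpointsGy) &&
      object@gradeBreakpointsGy[1L] <= object@thresholdGy)
    msg <- c(msg, "breakpoints must exceed the threshold")
  if (length(msg)) msg else TRUE
})

#' Dose-toxicity separation report
#'
#' @slot method label of the dose column analysed.
#' @slot maxDoseNoToxicityGy highest dose among patients without toxicity.
#' @slot minDoseToxicityGy lowest dose among patients with toxicity.
#' @slot maxDoseToxicityGy highest dose among patients with toxicity.
#' @slot minDoseNoToxicityGy lowest dose among patients without toxicity.
#' @slot fullySeparated TRUE iff maxDoseNoToxicity < minDoseToxicity.
#' @slot separatingThresholdGy midpoint of the gap when fully separated, else
#'   NA.
#' @export
setClass("SeparationReport",
  representation(method = "character", maxDoseNoToxicityGy = "numeric",
                 minDoseToxicityGy = "numeric", maxDoseToxicityGy = "numeric",
                 minDoseNoToxicityGy = "numeric", fullySeparated = "logical",
                 separatingThresholdGy = "numeric"))

setValidity("SeparationReport", function(object) {
  ok <- isTRUE(object@fullySeparated) ==
    (is.finite(object@maxDoseNoToxicityGy) &&
     is.finite(object@minDoseToxicityGy) &&
     object@maxDoseNoToxicityGy < object@minDoseToxicityGy)
  if (!ok) "fullySeparated flag inconsistent with group extremes" else TRUE
})
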