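## Synthetic digital phantom: everything the serial-imaging protocol
## measures on a patient, generated with analytic ground truth.

#' Construct a phantom specification
#'
#' The default specification encodes the study conditions the generator
#' emulates: a 64 x 64 x 48 grid at 4.795 mm voxels (the full-protocol
#' matrix is 128 x 128 x 78), acquisitions at 0.5, 3, 24 and 72 h, an
#' administered activity of 5600 MBq of 177Lu, an elliptical body of
#' unit-density soft tissue with fast biexponential washout, a retaining
#' tumor sphere, and a lumbar-vertebrae block whose kinetics include a slow
#' uptake term producing the late marrow accumulation seen on 24-72 h
#' scans.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param compartments compartment list; see \linkS4class{PhantomSpec}.
#' @param administeredActivityMBq administered activity (MBq).
#' @param nuclide a \linkS4class{Nuclide}.
#' @param acquisitionTimesH acquisition times (h); the 0.5 h first scan is a
#'   declared convention for "immediately after administration".
#' @param bloodKinetics list(c0_MBq_per_mL, f, lambda1, lambda2).
#' @param backgroundDensityGCm3 density outside all compartments.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(grid = voxelGrid(c(64, 64, 48)),
                        compartments = defaultCompartments(grid),
                        administeredActivityMBq = 5600,
                        nuclide = loadNuclide("Lu-177"),
                        acquisitionTimesH = c(0.5, 3, 24, 72),
                        bloodKinetics = list(
                          c0_MBq_per_mL = administeredActivityMBq / 5000,
                          f = 0.85, lambda1 = 1.2, lambda2 = 0.08),
                        backgroundDensityGCm3 = 0.001) {
  new("PhantomSpec", grid = grid, compartments = compartments,
      administeredActivityMBq = administeredActivityMBq, nuclide = nuclide,
      acquisitionTimesH = acquisitionTimesH, bloodKinetics = bloodKinetics,
      backgroundDensityGCm3 = backgroundDensityGCm3)
}

#' @rdname phantomSpec
#' @param marrowUptake amplitude of the late marrow-accumulation term.
#' @export
defaultCompartments <- function(grid, marrowUptake = 2.5e-4) {
  ext <- grid@shape * grid@voxelSizeMm
  ctr <- ext / 2
  list(
    list(name = "tumor", shape = "sphere",
         center_mm = ctr + c(ext[1] * 0.18, 0, 0), size_mm = 22,
         density_g_cm3 = 1.05,
         kinetics = list(amplitude = 4e-3, f = 0.30, lambda1 = 0.30,
                         lambda2 = 0.004, uptake = 0, lambda_u = 0)),
    list(name = "LV", shape = "box",
         center_mm = ctr - c(ext[1] * 0.12, 0, 0), size_mm = c(18, 18, 55),
         density_g_cm3 = 1.30,
         kinetics = list(amplitude = 1.2e-3, f = 1, lambda1 = 0.5,
                         lambda2 = 0, uptake = marrowUptake,
                         lambda_u = 0.2)),
    list(name = "body", shape = "ellipsoid", center_mm = ctr,
         size_mm = ext * c(0.42, 0.38, 0.46), density_g_cm3 = 1.0,
         kinetics = list(amplitude = 0.90, f = 0.95, lambda1 = 0.60,
                         lambda2 = 0.050, uptake = 0, lambda_u = 0)))
}

## biological retention r(t) of one compartment
.retention <- function(k, t) {
  u <- if (is.null(k$uptake)) 0 else k$uptake
  lu <- if (is.null(k$lambda_u)) 0 else k$lambda_u
  k$amplitude * (k$f * exp(-k$lambda1 * t) +
                 (1 - k$f) * exp(-k$lambda2 * t)) +
    u * (1 - exp(-lu * t))
}

## analytic integral of retention x physical decay over [0, Inf)
.retentionIntegral <- function(k, lambdaPhys) {
  u <- if (is.null(k$uptake)) 0 else k$uptake
  lu <- if (is.null(k$lambda_u)) 0 else k$lambda_u
  k$amplitude * (k$f / (k$lambda1 + lambdaPhys) +
                 (1 - k$f) / (k$lambda2 + lambdaPhys)) +
    (if (u > 0) u / lambdaPhys - u / (lu + lambdaPhys) else 0)
}

.compartmentMask <- function(cp, grid) {
  ax <- lapply(1:3, function(i)
    grid@originMm[i] + (seq_len(grid@shape[i]) - 0.5) * grid@voxelSizeMm)
  c1 <- cp$center_mm[1]; c2 <- cp$center_mm[2]; c3 <- cp$center_mm[3]
  switch(cp$shape,
    sphere = {
      r2 <- cp$size_mm[1]^2
      outer(outer((ax[[1]] - c1)^2, (ax[[2]] - c2)^2, "+"),
            (ax[[3]] - c3)^2, "+") <= r2
    },
    box = {
      h <- cp$size_mm / 2
      outer(outer(abs(ax[[1]] - c1) <= h[1], abs(ax[[2]] - c2) <= h[2], "&"),
            abs(ax[[3]] - c3) <= h[3], "&")
    },
    ellipsoid = {
      s <- cp$size_mm
      outer(outer(((ax[[1]] - c1) / s[1])^2, ((ax[[2]] - c2) / s[2])^2, "+"),
            ((ax[[3]] - c3) / s[3])^2, "+") <= 1
    },
    stop("unknown compartment shape: ", cp$shape))
}

#' Build the digital phantom
#'
#' Generates the full synthetic study: density and composition volumes,
#' serial activity volumes at the acquisition times (compartment activity =
#' administered activity x biological retention x physical decay, uniform
#' over the compartment's voxels), one VOI mask per compartment, and a
#' truth ledger holding each compartment's exact analytic time-integrated
#' activity for parameter-recovery tests. Overlapping compartments resolve
#' by list order (earlier wins); a compartment with no voxels on the grid is
#' an error.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed reserved for optional stochastic texture; the default phantom
#'   is deterministic.
#' @return list(density, composition, activity, masks, truth): the truth
#'   ledger has one row per compartment with voxel counts, masses and
#'   analytic time-integrated activities (MBq h).
#' @export
buildPhantom <- function(spec, seed = 1L) {
  validObject(spec)
  grid <- spec@grid
  lambdaPhys <- decayConstantPerH(spec@nuclide)
  density <- array(spec@backgroundDensityGCm3, dim = grid@shape)
  owner <- array(0L, dim = grid@shape)
  masks <- list()
  for (i in seq_along(spec@compartments)) {
    cp <- spec@compartments[[i]]
    m <- .compartmentMask(cp, grid) & owner == 0L
    if (!any(.compartmentMask(cp, grid)))
      stop(sprintf("compartment '%s' contains no voxels on the grid", cp$name))
    owner[m] <- i
    density[m] <- cp$density_g_cm3
    masks[[cp$name]] <- voiMask(m, grid, cp$name)
  }
  vols <- lapply(spec@acquisitionTimesH, function(t) {
    a <- array(0, dim = grid@shape)
    for (i in seq_along(spec@compartments)) {
      cp <- spec@compartments[[i]]
      m <- owner == i
      n <- sum(m)
      if (n == 0L) next
      a[m] <- spec@administeredActivityMBq * .retention(cp$kinetics, t) *
        exp(-lambdaPhys * t) / n
    }
    scalarVolume(a, grid, "activity_MBq")
  })
  truth <- do.call(rbind, lapply(seq_along(spec@compartments), function(i) {
    cp <- spec@compartments[[i]]
    n <- sum(owner == i)
    tt <- spec@acquisitionTimesH
    yy <- spec@administeredActivityMBq * .retention(cp$kinetics, tt) *
      exp(-lambdaPhys * tt)
    # the serial-imaging integration rule applied to the analytic samples,
    # written out directly so pipeline tests have an independent target
    tiaHybrid <- if (length(tt) == 4L) {
      kk <- if (yy[4L] > 0 && yy[4L] < yy[3L])
        log(yy[3L] / yy[4L]) / (tt[4L] - tt[3L]) else lambdaPhys
      tt[1L] * yy[1L] +
        0.5 * (yy[1L] + yy[2L]) * (tt[2L] - tt[1L]) +
        0.5 * (yy[2L] + yy[3L]) * (tt[3L] - tt[2L]) +
        (if (yy[3L] > 0) yy[3L] / kk else 0)
    } else NA_real_
    data.frame(name = cp$name, n_voxels = n,
               volume_mL = n * voxelVolumeMl(grid),
               mass_g = n * voxelVolumeMl(grid) * cp$density_g_cm3,
               tia_MBq_h = spec@administeredActivityMBq *
                 .retentionIntegral(cp$kinetics, lambdaPhys),
               tia_hybrid_MBq_h = tiaHybrid)
  }))
  list(density = scalarVolume(density, grid, "density_g_cm3"),
       composition = deriveComposition(
         scalarVolume(density, grid, "density_g_cm3")),
       activity = timeSeriesVolumes(spec@acquisitionTimesH, vols),
       masks = masks, truth = truth)
}

#' Attenuated planar projection of an activity volume
#'
#' Emulates anterior/posterior whole-body planar acquisition: each detector
#' pixel is the line integral of activity along the projection (y) axis,
#' attenuated by \eqn{e^{-\mu d}} where d is the path length through body
#' voxels (density above the config density floor) to the corresponding
#' surface. Anterior and posterior views use opposite path directions, so a
#' source at depth d in a body of thickness T is attenuated by
#' \eqn{e^{-\mu d}} and \eqn{e^{-\mu (T - d)}} — the conjugate-view
#' geometric-mean identity. Optional Poisson noise models counting
#' statistics on an idealised unit-sensitivity detector.
#'
#' @param activity activity \linkS4class{ScalarVolume}.
#' @param density density \linkS4class{ScalarVolume} on the same grid.
#' @param config a \linkS4class{DosimetryConfig}
#'   (\code{attenuationCmInv}, \code{densityFloorGCm3}).
#' @param view "anterior" or "posterior".
#' @param poissonSeed optional integer; when given, pixel values are Poisson
#'   resampled with this seed.
#' @return A numeric matrix (nx x nz) of detector pixel values.
#' @export
projectPlanar <- function(activity, density, config = dosimetryConfig(),
                          view = c("anterior", "posterior"),
                          poissonSeed = NULL) {
  view <- match.arg(view)
  stopifnot(identical(gridShape(activity), gridShape(density)))
  mu <- config@attenuationCmInv
  voxCm <- activity@grid@voxelSizeMm / 10
  A <- activity@values
  B <- density@values > config@densityFloorGCm3
  ny <- dim(A)[2L]
  cb <- array(0, dim = dim(A))
  cb[, 1L, ] <- B[, 1L, ]
  for (j in seq_len(ny)[-1L]) cb[, j, ] <- cb[, j - 1L, ] + B[, j, ]
  tot <- aperm(array(cb[, ny, ], dim = c(dim(A)[1L], dim(A)[3L], ny)),
               c(1L, 3L, 2L))
  depth <- if (view == "anterior") (cb - 0.5 * B) * voxCm
           else (tot - cb + 0.5 * B) * voxCm
  img <- apply(A * exp(-mu * depth), c(1L, 3L), sum)
  if (!is.null(poissonSeed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(poissonSeed)
    img[] <- stats::rpois(length(img), img)
  }
  img
}

#' Sample the phantom's blood curve
#'
#' Evaluates the spec's biexponential biological blood model times physical
#' decay at the requested draw times, and derives the parallel whole-body
#' series from the phantom compartment totals.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param timesH draw times (h); default the 7-sample schedule
#'   (2 min, 30 min, 1, 2, 4, 24, 72 h).
#' @return A \linkS4class{BloodSeries}.
#' @export
sampleBlood <- function(spec, timesH = c(2 / 60, 0.5, 1, 2, 4, 24, 72)) {
  stopifnot(all(timesH >= 0))
  bk <- spec@bloodKinetics
  lambdaPhys <- decayConstantPerH(spec@nuclide)
  conc <- bk$c0_MBq_per_mL *
    (bk$f * exp(-bk$lambda1 * timesH) +
     (1 - bk$f) * exp(-bk$lambda2 * timesH)) * exp(-lambdaPhys * timesH)
  wb <- spec@administeredActivityMBq * exp(-lambdaPhys * timesH) *
    Reduce(`+`, lapply(spec@compartments,
                       function(cp) .retention(cp$kinetics, timesH)))
  bloodSeries(timesH, conc, wb)
}

#' Construct a toxicity label model
#'
#' @param thresholdGy dose threshold (default 0.4 Gy, the separation level
#'   the cohort analysis reproduces).
#' @param noiseSdGy Gaussian dose perturbation SD.
#' @param gradeBreakpointsGy upper bounds of grades 1-3.
#' @return A \linkS4class{ToxicityModel}.
#' @export
toxicityModel <- function(thresholdGy = 0.4, noiseSdGy = 0.05,
                          gradeBreakpointsGy = c(0.55, 0.7, 0.85)) {
  new("ToxicityModel", thresholdGy = thresholdGy, noiseSdGy = noiseSdGy,
      gradeBreakpointsGy = gradeBreakpointsGy)
}

#' Assign synthetic toxicity grades from a marrow dose
#'
#' Deterministic given the seed: the dose is perturbed with Gaussian noise
#' (independently for the two endpoints), grade 0 below the threshold,
#' otherwise graded by the breakpoints (grade 4 above the last).
#'
#' @param doseGy marrow absorbed dose (Gy), >= 0.
#' @param model a \linkS4class{ToxicityModel}.
#' @param seed integer seed.
#' @return Named integer vector: grade_thrombocytopenia, grade_leucopenia.
#' @export
assignToxicity <- function(doseGy, model = toxicityModel(), seed = 1L) {
  stopifnot(doseGy >= 0)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  noisy <- doseGy + rnorm(2L, 0, model@noiseSdGy)
  gradeOf <- function(x) {
    if (x < model@thresholdGy) 0L
    else min(4L, 1L + findInterval(x, model@gradeBreakpointsGy))
  }
  c(grade_thrombocytopenia = gradeOf(noisy[1L]),
    grade_leucopenia = gradeOf(noisy[2L]))
}
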