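.JOULE_PER_MEV <- 1.602176634e-13

#' Derive tissue composition from a density map
#'
#' Mirrors CT-driven material assignment: lung below the lung density
#' threshold, bone above the bone threshold, soft tissue between.
#'
#' @param density a density \linkS4class{ScalarVolume} (g/cm3).
#' @param config a \linkS4class{DosimetryConfig} (thresholds
#'   \code{lungMaxGCm3}, \code{boneMinGCm3}).
#' @return A \linkS4class{CompositionVolume}.
#' @export
deriveComposition <- function(density, config = dosimetryConfig()) {
  stopifnot(is(density, "ScalarVolume"), density@quantity == "density_g_cm3")
  d <- density@values
  lab <- array(COMPOSITION_LEVELS[["soft_tissue"]], dim = dim(d))
  lab[d < config@lungMaxGCm3] <- COMPOSITION_LEVELS[["lung"]]
  lab[d > config@boneMinGCm3] <- COMPOSITION_LEVELS[["bone"]]
  new("CompositionVolume", grid = density@grid, labels = lab)
}

#' Run the Monte Carlo voxel dose-rate engine
#'
#' Samples \code{nHistories} decays from the activity map, transports the
#' nuclide's emissions through the density/composition maps and tallies
#' absorbed dose rate per voxel (Gy/h) at the imaging time the activity map
#' represents. Beta particles are deposited locally for sub-voxel-range
#' emitters (177Lu) or transported along straight continuous-slowing-down
#' paths (90Y); photons undergo Woodcock-tracked photoelectric/Compton
#' transport with kerma-style local deposition of Compton electron energy.
#' The returned energy ledger closes exactly
#' (emitted = deposited + escaped).
#'
#' Voxel masses use the density map floored at
#' \code{config@densityFloorGCm3} so that near-void voxels cannot acquire
#' unbounded dose.
#'
#' @param activity activity \linkS4class{ScalarVolume} (MBq).
#' @param density density \linkS4class{ScalarVolume} (g/cm3).
#' @param composition a \linkS4class{CompositionVolume}; derived from the
#'   density map when NULL.
#' @param nuclide a \linkS4class{Nuclide}.
#' @param nHistories number of histories (default from \code{config}).
#' @param seed engine RNG seed (default from \code{config}).
#' @param config a \linkS4class{DosimetryConfig}.
#' @return A \linkS4class{DoseRateResult}.
#' @export
runMC <- function(activity, density, composition = NULL, nuclide,
                  nHistories = config@nHistories, seed = config@rngSeed,
                  config = dosimetryConfig()) {
  stopifnot(is(activity, "ScalarVolume"), activity@quantity == "activity_MBq",
            is(density, "ScalarVolume"), density@quantity == "density_g_cm3",
            identical(gridShape(activity), gridShape(density)))
  if (is.null(composition)) composition <- deriveComposition(density, config)
  stopifnot(identical(gridShape(activity), composition@grid@shape))
  if (nHistories < 1) stop("nHistories must be >= 1")
  grid <- activity@grid
  totalMBq <- sum(activity@values)
  if (totalMBq == 0) {
    zero <- scalarVolume(array(0, dim = grid@shape), grid, "doserate_Gy_h")
    return(new("DoseRateResult", doserate = zero, energyEmittedMeV = 0,
               energyDepositedMeV = 0, energyEscapedMeV = 0,
               nHistories = nHistories, seed = seed))
  }
  icdf <- if (nuclide@betaTransport == "csda") .betaInverseCdf(nuclide)
          else matrix(0, nrow = 2, ncol = 2)
  res <- .mcEngine(as.numeric(activity@values), as.numeric(density@values),
                   as.integer(composition@labels), grid@shape,
                   grid@voxelSizeMm / 10, as.integer(nHistories),
                   as.numeric(seed), nuclide@betaMeanEnergyMeV,
                   nuclide@betaYield,
                   as.integer(nuclide@betaTransport == "csda"),
                   icdf, .rangeTable(max(2.5, nuclide@betaEndpointMeV)),
                   nuclide@photonLines, .attenuationTables(),
                   config@photonCutoffMeV, config@densityFloorGCm3)
  # tallied MeV per history -> Gy/h: each history stands for
  # (total decay rate)/nHistories decays per unit time
  decaysPerHour <- totalMBq * 1e6 * 3600
  weight <- decaysPerHour / nHistories
  voxelMassKg <- pmax(density@values, config@densityFloorGCm3) *
    voxelVolumeMl(grid) / 1000
  doserate <- array(res$energy_MeV, dim = grid@shape) * .JOULE_PER_MEV *
    weight / voxelMassKg
  new("DoseRateResult",
      doserate = scalarVolume(doserate, grid, "doserate_Gy_h"),
      energyEmittedMeV = res$emitted_MeV,
      energyDepositedMeV = res$deposited_MeV,
      energyEscapedMeV = res$escaped_MeV,
      nHistories = nHistories, seed = seed)
}

#' Sphere self-dose table (sphere-model S-values)
#'
#' For each mass, a unit-density sphere in a cold soft-tissue background is
#' filled with uniform activity and the engine's mean sphere dose rate per
#' unit contained activity gives the sphere S-value in Gy per MBq h. This is
#' the sphere-model coefficient used for the isolated-sphere tumor dose,
#' computed with the same physics as the full voxel dose so that the
#' 3D-versus-sphere comparison isolates geometry.
#'
#' @param nuclide a \linkS4class{Nuclide}.
#' @param massesG sphere masses in grams.
#' @param config a \linkS4class{DosimetryConfig}; \code{nHistories} and
#'   \code{rngSeed} drive each run.
#' @param voxelSizeMm grid resolution for the sphere runs (default 4.795).
#' @return data.frame with columns \code{mass_g}, \code{s_Gy_per_MBq_h}.
#' @export
sphereSelfDoseTable <- function(nuclide, massesG, config = dosimetryConfig(),
                                voxelSizeMm = 4.795) {
  s <- vapply(massesG, function(m) {
    rCm <- (3 * m / (4 * pi * 1.0))^(1 / 3)
    vox <- voxelSizeMm / 10
    if (rCm < vox / 2)
      stop(sprintf("sphere of %g g is below one voxel at %g mm", m,
                   voxelSizeMm))
    margin <- if (nuclide@betaTransport == "csda") 8L else 4L
    n <- 2L * (as.integer(ceiling(rCm / vox)) + margin) + 1L
    grid <- voxelGrid(c(n, n, n), voxelSizeMm = voxelSizeMm)
    ctr <- (n / 2) * vox
    ax <- ((seq_len(n) - 0.5) * vox - ctr)
    dist2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    inside <- dist2 <= rCm^2
    act <- array(0, dim = c(n, n, n))
    act[inside] <- 1 / sum(inside)          # 1 MBq total
    density <- scalarVolume(array(1, dim = c(n, n, n)), grid, "density_g_cm3")
    res <- runMC(scalarVolume(act, grid, "activity_MBq"), density,
                 nuclide = nuclide, config = config)
    mean(res@doserate@values[inside])       # Gy/h per 1 MBq
  }, numeric(1))
  data.frame(mass_g = massesG, s_Gy_per_MBq_h = s)
}

#' Interpolate a sphere S-value at a mass
#'
#' Log-log interpolation in a \code{\link{sphereSelfDoseTable}}; values
#' outside the tabulated mass range are extrapolated with a warning.
#'
#' @param table data.frame from \code{\link{sphereSelfDoseTable}}.
#' @param massG query mass (g).
#' @return S-value in Gy per MBq h.
#' @export
interpSphereS <- function(table, massG) {
  if (massG < min(table$mass_g) || massG > max(table$mass_g))
    warning(sprintf("mass %g g outside sphere table range [%g, %g]: extrapolating",
                    massG, min(table$mass_g), max(table$mass_g)))
  lm_ <- log(table$mass_g); ls <- log(table$s_Gy_per_MBq_h)
  if (nrow(table) == 1L) return(table$s_Gy_per_MBq_h)
  exp(approx(lm_, ls, xout = log(massG), rule = 2)$y +
        ifelse(massG > max(table$mass_g) || massG < min(table$mass_g), {
          # linear log-log extrapolation from the nearest segment
          i <- if (massG > max(table$mass_g)) nrow(table) - 1L else 1L
          sl <- (ls[i + 1L] - ls[i]) / (lm_[i + 1L] - lm_[i])
          xq <- log(massG)
          edge <- if (massG > max(table$mass_g)) lm_[length(lm_)] else lm_[1L]
          sl * (xq - edge)
        }, 0))
}
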