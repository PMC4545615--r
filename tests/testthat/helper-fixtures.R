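# Shared builders for small in-code fixtures.

uniformVolume <- function(value, shape = c(12, 12, 12), quantity,
                          voxelSizeMm = 4.795) {
  g <- voxelGrid(shape, voxelSizeMm = voxelSizeMm)
  scalarVolume(array(value, dim = shape), g, quantity)
}

# strip photon lines: the locally-deposited beta branch has an exact
# analytic dose, which makes it the oracle branch for recovery tests
betaOnly <- function(nuclide) {
  nuclide@photonLines <- matrix(numeric(0), ncol = 2)
  nuclide
}

JOULE_PER_MEV <- 1.602176634e-13
DECAYS_PER_MBQ_H <- 3.6e9

# Gy per MBq h per kg for a locally deposited mean energy
localBetaConv <- function(energyMeV) energyMeV * JOULE_PER_MEV * DECAYS_PER_MBQ_H

# run the MC engine at the 4 acquisition times of a phantom
doseRateSeries <- function(ph, nuclide, config, seed0) {
  timeSeriesVolumes(ph$activity@timesH, lapply(seq_len(4L), function(i)
    runMC(ph$activity@volumes[[i]], ph$density, ph$composition, nuclide,
          config = config, seed = seed0 + i)@doserate))
}

cohortFixture <- function() {
  loadCohort(system.file("extdata", "cohort_doses.csv", package = "voxdose"))
}

matchedPairFixture <- function() {
  read.csv(system.file("extdata", "matched_pair_ratios.csv",
                       package = "voxdose"))
}
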