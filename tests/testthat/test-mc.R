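luFull <- loadNuclide("Lu-177")
y90 <- loadNuclide("Y-90")
cfgFast <- dosimetryConfig(n_histories = 2e4, rng_seed = 3)

test_that("composition derivation follows the density thresholds", {
  g <- voxelGrid(c(3, 3, 3))
  d <- array(1.0, dim = c(3, 3, 3)); d[1, 1, 1] <- 0.3; d[3, 3, 3] <- 1.6
  comp <- deriveComposition(scalarVolume(d, g, "density_g_cm3"))
  expect_equal(comp@labels[2, 2, 2], 1L)  # soft tissue
  expect_equal(comp@labels[1, 1, 1], 2L)  # lung
  expect_equal(comp@labels[3, 3, 3], 3L)  # bone
})

test_that("zero activity yields a zero dose-rate map and empty ledger", {
  act <- uniformVolume(0, c(6, 6, 6), "activity_MBq")
  den <- uniformVolume(1, c(6, 6, 6), "density_g_cm3")
  res <- runMC(act, den, nuclide = luFull, config = cfgFast)
  expect_equal(sum(volumeValues(res@doserate)), 0)
  expect_equal(res@energyEmittedMeV, 0)
})

test_that("energy ledger closes exactly for every emission model", {
  act <- uniformVolume(0.5, c(10, 10, 10), "activity_MBq")
  den <- uniformVolume(1, c(10, 10, 10), "density_g_cm3")
  for (nuc in list(luFull, betaOnly(luFull), y90)) {
    res <- runMC(act, den, nuclide = nuc, config = cfgFast)
    expect_lt(abs(res@energyEmittedMeV - res@energyDepositedMeV -
                    res@energyEscapedMeV),
              1e-9 * res@energyEmittedMeV)
  }
  # transported emissions leak from a finite phantom; local betas cannot
  expect_gt(runMC(act, den, nuclide = luFull,
                  config = cfgFast)@energyEscapedMeV, 0)
  expect_gt(runMC(act, den, nuclide = y90,
                  config = cfgFast)@energyEscapedMeV, 0)
  expect_equal(runMC(act, den, nuclide = betaOnly(luFull),
                     config = cfgFast)@energyEscapedMeV, 0)
})

test_that("a fixed seed reproduces the run bit for bit", {
  act <- uniformVolume(1, c(8, 8, 8), "activity_MBq")
  den <- uniformVolume(1, c(8, 8, 8), "density_g_cm3")
  a <- runMC(act, den, nuclide = luFull, nHistories = 5e3, seed = 9,
             config = cfgFast)
  b <- runMC(act, den, nuclide = luFull, nHistories = 5e3, seed = 9,
             config = cfgFast)
  c <- runMC(act, den, nuclide = luFull, nHistories = 5e3, seed = 10,
             config = cfgFast)
  expect_identical(volumeValues(a@doserate), volumeValues(b@doserate))
  expect_false(identical(volumeValues(a@doserate), volumeValues(c@doserate)))
})

test_that("uniform beta-only phantom reaches the secular-equilibrium dose rate", {
  n <- 1e5
  shape <- c(20, 20, 20)
  act <- uniformVolume(1, shape, "activity_MBq")
  den <- uniformVolume(1, shape, "density_g_cm3")
  res <- runMC(act, den, nuclide = betaOnly(luFull), nHistories = n,
               seed = 17, config = cfgFast)
  vox <- voxelVolumeMl(act)
  aConc <- 1 / vox                                   # MBq per cm^3
  closed <- aConc * 1e6 * 0.1333 * 1.602176634e-13 * 3600 / 1e-3  # Gy/h
  ctr <- volumeValues(res@doserate)[8:13, 8:13, 8:13]
  # histories land multinomially: binomial SE for the central-region mean
  p <- length(ctr) / prod(shape)
  se <- closed * sqrt((1 - p) / (n * p))
  expect_lt(abs(mean(ctr) - closed), 3 * se)
})

test_that("photons escape a vacuum-like medium leaving only the beta share", {
  g <- voxelGrid(c(9, 9, 9))
  a <- array(0, dim = c(9, 9, 9)); a[5, 5, 5] <- 1
  den <- uniformVolume(1e-9, c(9, 9, 9), "density_g_cm3")
  res <- runMC(scalarVolume(a, g, "activity_MBq"), den, nuclide = luFull,
               nHistories = 2e3, seed = 2, config = cfgFast)
  perHist <- 0.1333 + sum(luFull@photonLines[, 1] * luFull@photonLines[, 2])
  expect_equal(res@energyEmittedMeV, 2e3 * perHist, tolerance = 1e-9)
  expect_equal(res@energyDepositedMeV, 2e3 * 0.1333, tolerance = 1e-9)
  expect_equal(res@energyEscapedMeV,
               2e3 * sum(luFull@photonLines[, 1] * luFull@photonLines[, 2]),
               tolerance = 1e-9)
})

test_that("doubling histories shrinks the tally standard error about root-2", {
  act <- uniformVolume(1, c(12, 12, 12), "activity_MBq")
  den <- uniformVolume(1, c(12, 12, 12), "density_g_cm3")
  centre <- function(res) mean(volumeValues(res@doserate)[5:8, 5:8, 5:8])
  est <- function(n) vapply(1:12, function(s)
    centre(runMC(act, den, nuclide = luFull, nHistories = n, seed = 100 + s,
                 config = cfgFast)), numeric(1))
  r <- sd(est(2000)) / sd(est(8000))
  # theoretical ratio 2; wide band for a 12-replicate SD estimate
  expect_gt(r, 1.25)
  expect_lt(r, 3.2)
})

test_that("the mean 177Lu beta range is far below the voxel size", {
  rangeMm <- voxdose:::.csdaRangeGCm2(0.1333) * 10  # mm in unit density
  expect_lt(rangeMm, 4.795 / 10)
})

test_that("90Y spectrum shape reproduces the reference mean beta energy", {
  expect_equal(betaSpectrumMeanMeV(y90), 0.9337, tolerance = 0.02)
  e <- seq(0.01, 2.27, length.out = 200)
  dens <- betaSpectrumShape(e, y90@betaEndpointMeV, y90@daughterZ)
  expect_true(all(dens >= 0))
  expect_equal(betaSpectrumShape(2.3, y90@betaEndpointMeV, y90@daughterZ), 0)
})

test_that("sphere self-dose table matches the pure-beta closed form and scaling", {
  cfg <- dosimetryConfig(n_histories = 1e4, rng_seed = 5)
  tab <- sphereSelfDoseTable(betaOnly(luFull), c(20, 40, 80), cfg)
  expect_true(all(diff(tab$s_Gy_per_MBq_h) < 0))
  # local beta deposition: absorbed fraction exactly 1 over the voxelised mass
  for (i in seq_len(3)) {
    rCm <- (3 * tab$mass_g[i] / (4 * pi))^(1 / 3)
    vox <- 0.4795
    nvox <- {
      n <- 2L * (as.integer(ceiling(rCm / vox)) + 4L) + 1L
      ax <- (seq_len(n) - 0.5) * vox - n / 2 * vox
      sum(outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= rCm^2)
    }
    massVox <- nvox * vox^3  # grams at unit density
    expect_equal(tab$s_Gy_per_MBq_h[i], localBetaConv(0.1333) / (massVox / 1000),
                 tolerance = 1e-9)
  }
  # with photons, doubling the mass at least halves nothing: S still decreases
  tabG <- sphereSelfDoseTable(luFull, c(30, 60), cfg)
  expect_lt(tabG$s_Gy_per_MBq_h[2], tabG$s_Gy_per_MBq_h[1])
  expect_error(sphereSelfDoseTable(luFull, 0.01, cfg), "below one voxel")
})

test_that("sphere S estimates from different seeds agree within Monte Carlo error", {
  reps <- vapply(1:6, function(s)
    sphereSelfDoseTable(luFull, 40,
                        dosimetryConfig(n_histories = 8e3,
                                        rng_seed = s))$s_Gy_per_MBq_h,
    numeric(1))
  se <- sd(reps)
  expect_lt(abs(reps[1] - reps[2]), 3 * sqrt(2) * se + 1e-15)
})
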