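test_that("generated activity conserves the analytic compartment totals", {
  spec <- phantomSpec(grid = voxelGrid(c(24, 24, 18)))
  ph <- buildPhantom(spec)
  lam <- decayConstantPerH(spec@nuclide)
  for (i in seq_along(spec@acquisitionTimesH)) {
    t <- spec@acquisitionTimesH[i]
    # analytic total, written out from the kinetics definition
    total <- sum(vapply(spec@compartments, function(cp) {
      k <- cp$kinetics
      r <- k$amplitude * (k$f * exp(-k$lambda1 * t) +
                          (1 - k$f) * exp(-k$lambda2 * t)) +
        k$uptake * (1 - exp(-k$lambda_u * t))
      spec@administeredActivityMBq * r * exp(-lam * t)
    }, numeric(1)))
    expect_equal(sum(volumeValues(ph$activity@volumes[[i]])), total,
                 tolerance = 1e-6)
  }
  # total at t = 0 cannot exceed the administered activity
  r0 <- sum(vapply(spec@compartments,
                   function(cp) cp$kinetics$amplitude, numeric(1)))
  expect_lte(r0, 1)
})

test_that("truth-ledger integrals match adaptive quadrature of the kinetics", {
  spec <- phantomSpec(grid = voxelGrid(c(24, 24, 18)))
  ph <- buildPhantom(spec)
  lam <- decayConstantPerH(spec@nuclide)
  for (j in seq_along(spec@compartments)) {
    k <- spec@compartments[[j]]$kinetics
    quad <- integrate(function(t)
      spec@administeredActivityMBq *
        (k$amplitude * (k$f * exp(-k$lambda1 * t) +
                        (1 - k$f) * exp(-k$lambda2 * t)) +
         k$uptake * (1 - exp(-k$lambda_u * t))) * exp(-lam * t),
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(ph$truth$tia_MBq_h[j], quad, tolerance = 1e-6)
  }
})

test_that("phantom builds are deterministic and validate geometry", {
  spec <- phantomSpec(grid = voxelGrid(c(20, 20, 16)))
  a <- buildPhantom(spec); b <- buildPhantom(spec)
  expect_identical(volumeValues(a$activity@volumes[[4]]),
                   volumeValues(b$activity@volumes[[4]]))
  expect_identical(a$truth, b$truth)
  # a sphere too small to claim any voxel centre is an error
  bad <- spec
  bad@compartments[[1]]$size_mm <- 0.4
  bad@compartments[[1]]$center_mm <- c(0, 0, 0)  # off every voxel centre
  expect_error(buildPhantom(bad), "no voxels")
})

test_that("frozen kinetics give identical volumes at every time point", {
  grid <- voxelGrid(c(16, 16, 12))
  still <- new("Nuclide", name = "stable", halfLifeH = 1e12,
               photonLines = matrix(numeric(0), ncol = 2),
               betaMeanEnergyMeV = 0.1, betaYield = 1,
               betaTransport = "local", betaEndpointMeV = 0, daughterZ = 0)
  spec <- phantomSpec(grid = grid, nuclide = still,
                      compartments = list(list(
                        name = "blob", shape = "sphere",
                        center_mm = grid@shape * grid@voxelSizeMm / 2,
                        size_mm = 15, density_g_cm3 = 1,
                        kinetics = list(amplitude = 0.5, f = 1, lambda1 = 0,
                                        lambda2 = 0, uptake = 0,
                                        lambda_u = 0))))
  ph <- buildPhantom(spec)
  expect_equal(volumeValues(ph$activity@volumes[[1]]),
               volumeValues(ph$activity@volumes[[4]]), tolerance = 1e-9)
})

test_that("a marrow uptake term makes late activity exceed the 3 h activity", {
  grid <- voxelGrid(c(20, 20, 16))
  spec <- phantomSpec(grid = grid, compartments = list(list(
    name = "marrow", shape = "box",
    center_mm = grid@shape * grid@voxelSizeMm / 2,
    size_mm = c(20, 20, 40), density_g_cm3 = 1.3,
    kinetics = list(amplitude = 1e-4, f = 1, lambda1 = 0.3, lambda2 = 0,
                    uptake = 4e-4, lambda_u = 0.03))))
  ph <- buildPhantom(spec)
  a <- vapply(ph$activity@volumes,
              function(v) sum(volumeValues(v)[ph$masks$marrow@mask]),
              numeric(1))
  expect_gt(a[4], a[2])  # 72 h above 3 h despite physical decay
})

test_that("planar projection obeys the conjugate-view geometric-mean identity", {
  g <- voxelGrid(c(9, 21, 9), voxelSizeMm = 10)  # 1 cm voxels
  den <- array(0, dim = c(9, 21, 9))
  den[, 2:21, ] <- 1                             # 20 cm body slab
  cfg <- dosimetryConfig(attenuation_cm_inv = 0.13)
  A <- 7
  gms <- vapply(c(3, 8, 14, 20), function(depth) {
    act <- array(0, dim = c(9, 21, 9)); act[5, depth, 5] <- A
    ant <- projectPlanar(scalarVolume(act, g, "activity_MBq"),
                         scalarVolume(den, g, "density_g_cm3"), cfg,
                         "anterior")
    pos <- projectPlanar(scalarVolume(act, g, "activity_MBq"),
                         scalarVolume(den, g, "density_g_cm3"), cfg,
                         "posterior")
    sqrt(ant[5, 5] * pos[5, 5])
  }, numeric(1))
  expect_equal(gms, rep(A * exp(-0.13 * 20 / 2), 4), tolerance = 1e-9)
})

test_that("planar projection limits behave: no attenuation, no activity, noise", {
  g <- voxelGrid(c(7, 7, 7))
  act <- array(0, dim = c(7, 7, 7)); act[3, 4, 5] <- 2
  den <- array(1, dim = c(7, 7, 7))
  nearZeroMu <- dosimetryConfig(attenuation_cm_inv = 1e-12)
  ant <- projectPlanar(scalarVolume(act, g, "activity_MBq"),
                       scalarVolume(den, g, "density_g_cm3"), nearZeroMu,
                       "anterior")
  pos <- projectPlanar(scalarVolume(act, g, "activity_MBq"),
                       scalarVolume(den, g, "density_g_cm3"), nearZeroMu,
                       "posterior")
  expect_equal(sum(ant != 0), 1L)
  expect_equal(ant, pos, tolerance = 1e-9)
  zero <- projectPlanar(uniformVolume(0, c(7, 7, 7), "activity_MBq"),
                        scalarVolume(den, g, "density_g_cm3"),
                        dosimetryConfig(), "anterior")
  expect_equal(sum(zero), 0)
  n1 <- projectPlanar(scalarVolume(act * 500, g, "activity_MBq"),
                      scalarVolume(den, g, "density_g_cm3"),
                      dosimetryConfig(), "anterior", poissonSeed = 4)
  n2 <- projectPlanar(scalarVolume(act * 500, g, "activity_MBq"),
                      scalarVolume(den, g, "density_g_cm3"),
                      dosimetryConfig(), "anterior", poissonSeed = 4)
  expect_identical(n1, n2)
})

test_that("blood sampling evaluates the analytic model at the draw schedule", {
  spec <- phantomSpec(grid = voxelGrid(c(16, 16, 12)))
  b <- sampleBlood(spec)
  expect_length(timesH(b), 7L)      # 2 min to 72 h draws
  bk <- spec@bloodKinetics
  expect_equal(sampleBlood(spec, 0)@concentrationMBqPerMl, bk$c0_MBq_per_mL)
  # mono-exponential variant is log-linear including physical decay
  spec2 <- spec
  spec2@bloodKinetics$f <- 1
  tt <- c(1, 2, 4, 8)
  cc <- sampleBlood(spec2, tt)@concentrationMBqPerMl
  slopes <- diff(log(cc)) / diff(tt)
  expect_equal(slopes, rep(-(bk$lambda1 + decayConstantPerH(spec@nuclide)), 3),
               tolerance = 1e-9)
  # whole-body series tracks the phantom totals
  ph <- buildPhantom(spec)
  wb <- sampleBlood(spec, spec@acquisitionTimesH)@wholeBodyMBq
  expect_equal(wb, vapply(ph$activity@volumes,
                          function(v) sum(volumeValues(v)), numeric(1)),
               tolerance = 1e-6)
})

test_that("toxicity labels follow the noisy threshold model", {
  m <- toxicityModel(thresholdGy = 0.4, noiseSdGy = 0)
  expect_equal(unname(assignToxicity(0, m, seed = 1)), c(0L, 0L))
  expect_equal(unname(assignToxicity(5, m, seed = 1)), c(4L, 4L))
  expect_equal(unname(assignToxicity(0.6, m, seed = 1)[1]), 2L)
  mN <- toxicityModel(thresholdGy = 0.4, noiseSdGy = 0.05)
  expect_identical(assignToxicity(0.5, mN, seed = 7),
                   assignToxicity(0.5, mN, seed = 7))
  # at the threshold the grade>=1 fraction is one half, binomially
  hits <- vapply(1:1000, function(s)
    assignToxicity(0.4, mN, seed = s)[1] >= 1L, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 1000))
})
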