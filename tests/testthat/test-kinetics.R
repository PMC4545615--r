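lamLu <- log(2) / 161.04

# independent piecewise oracle: rectangle + linear interpolation + anchored
# exponential tail, integrated by adaptive quadrature
oracleIntegral <- function(t, y, k) {
  fn <- function(tt) {
    out <- numeric(length(tt))
    out[tt < t[1]] <- y[1]
    m <- tt >= t[1] & tt <= t[3]
    out[m] <- approx(t[1:3], y[1:3], xout = tt[m])$y
    g <- tt > t[3]
    out[g] <- y[3] * exp(-k * (tt[g] - t[3]))
    out
  }
  integrate(fn, 0, t[3], rel.tol = 1e-12)$value +
    integrate(function(tt) y[3] * exp(-k * (tt - t[3])), t[3], Inf,
              rel.tol = 1e-12)$value
}

test_that("hybrid integral matches the quadrature oracle on the worked series", {
  t <- c(0, 3, 24, 72); y <- c(100, 80, 40, 20)
  fit <- fitHybrid(t, y, fallbackRatePerH = lamLu)
  expect_equal(fit@tailRatePerH, log(2) / 48, tolerance = 1e-12)
  k <- log(y[3] / y[4]) / (t[4] - t[3])
  expect_equal(fit@integral, oracleIntegral(t, y, k), tolerance = 1e-6)
  expect_false(fit@tailFallbackUsed)
  # the fitted curve itself integrates to the reported value
  expect_equal(integrate(hybridFunction(fit), 0, Inf,
                         rel.tol = 1e-10)$value,
               fit@integral, tolerance = 1e-6)
})

test_that("hybrid fit handles degenerate series by rule", {
  expect_equal(fitHybrid(c(0, 3, 24, 72), rep(0, 4), lamLu)@integral, 0)
  # constant series: trapezoids to the anchor, then the physical-decay
  # fallback tail y3/lambda covering [t3, Inf)
  fit <- fitHybrid(c(0, 3, 24, 72), rep(5, 4), lamLu)
  expect_true(fit@tailFallbackUsed)
  expect_equal(fit@integral, 5 * 24 + 5 / lamLu, tolerance = 1e-12)
  expect_error(fitHybrid(c(0, 3, 24, 72), c(1, 1, 0, 1), lamLu),
               "growth from zero")
  # zero leading rule drops the head rectangle
  f2 <- fitHybrid(c(2, 3, 24, 72), c(10, 8, 4, 2), lamLu,
                  leadingRule = "zero")
  f1 <- fitHybrid(c(2, 3, 24, 72), c(10, 8, 4, 2), lamLu)
  expect_equal(f1@integral - f2@integral, 2 * 10)
})

test_that("hybrid integral is linear and bounded as specified", {
  set.seed(5)
  for (i in 1:25) {
    t <- sort(runif(4, 0, 80)); y <- sort(runif(4, 0.1, 50), decreasing = TRUE)
    f <- fitHybrid(t, y, lamLu)
    expect_equal(fitHybrid(t, 3.7 * y, lamLu)@integral, 3.7 * f@integral,
                 tolerance = 1e-12)
    trap <- 0.5 * (y[1] + y[2]) * (t[2] - t[1]) +
            0.5 * (y[2] + y[3]) * (t[3] - t[2])
    expect_gte(f@integral, trap)
    expect_lte(f@integral,
               t[1] * y[1] + trap + y[3] / min(f@tailRatePerH, lamLu) + 1e-9)
  }
})

test_that("voxel-wise integration reproduces scalar fits and closed forms", {
  t <- c(0, 3, 24, 72)
  g <- voxelGrid(c(5, 5, 5))
  mk <- function(v) scalarVolume(array(v, dim = c(5, 5, 5)), g,
                                 "doserate_Gy_h")
  # uniform field: every voxel equals the scalar fit
  s <- timeSeriesVolumes(t, lapply(c(10, 8, 4, 2), mk))
  dmap <- integrateDoseMap(s, lamLu)
  expect_equal(max(abs(volumeValues(dmap) -
                         fitHybrid(t, c(10, 8, 4, 2), lamLu)@integral)), 0)
  # a voxel that is always zero stays zero
  vols <- lapply(c(10, 8, 4, 2), mk)
  for (i in 1:4) vols[[i]]@values[1, 1, 1] <- 0
  expect_equal(volumeValues(integrateDoseMap(timeSeriesVolumes(t, vols),
                                             lamLu))[1, 1, 1], 0)
  # mono-exponential truth: integral D0/lambda
  d0 <- 2.5
  vols <- lapply(t, function(tt) mk(d0 * exp(-lamLu * tt)))
  dmap <- integrateDoseMap(timeSeriesVolumes(t, vols), lamLu)
  expect_equal(volumeValues(dmap)[3, 3, 3], d0 / lamLu, tolerance = 1e-3)
})

test_that("late-appearing voxels are an error unless the documented rule is chosen", {
  t <- c(0, 3, 24, 72)
  g <- voxelGrid(c(3, 3, 3))
  vols <- lapply(c(1, 1, 0, 0.5), function(v)
    scalarVolume(array(v, dim = c(3, 3, 3)), g, "doserate_Gy_h"))
  s <- timeSeriesVolumes(t, vols)
  expect_error(integrateDoseMap(s, lamLu), "growth from zero")
  dmap <- integrateDoseMap(s, lamLu, zeroAnchor = "late_tail")
  expect_equal(volumeValues(dmap)[1, 1, 1],
               0 + 0.5 * 2 * 3 + 0.5 * 21 * 1 + 0.5 * 0.5 * 48 + 0.5 / lamLu,
               tolerance = 1e-12)
})

test_that("VOI integration agrees with voxel integration where it must", {
  t <- c(0, 3, 24, 72)
  g <- voxelGrid(c(6, 6, 6))
  set.seed(9)
  base <- array(runif(216, 1, 3), dim = c(6, 6, 6))
  vols <- lapply(c(1, 0.8, 0.4, 0.2), function(sc)
    scalarVolume(base * sc, g, "doserate_Gy_h"))
  s <- timeSeriesVolumes(t, vols)
  # single-voxel mask equals that voxel of the dose map
  m1 <- array(FALSE, dim = c(6, 6, 6)); m1[2, 3, 4] <- TRUE
  expect_equal(integrateVoi(s, voiMask(m1, g), lamLu),
               volumeValues(integrateDoseMap(s, lamLu))[2, 3, 4],
               tolerance = 1e-12)
  # common scaling: VOI dose independent of mask size on a uniform field
  u <- timeSeriesVolumes(t, lapply(c(5, 4, 2, 1), function(v)
    scalarVolume(array(v, dim = c(6, 6, 6)), g, "doserate_Gy_h")))
  small <- array(FALSE, dim = c(6, 6, 6)); small[1:2, 1, 1] <- TRUE
  big <- array(TRUE, dim = c(6, 6, 6))
  expect_equal(integrateVoi(u, voiMask(small, g), lamLu),
               integrateVoi(u, voiMask(big, g), lamLu), tolerance = 1e-12)
  expect_error(integrateVoi(u, voiMask(array(FALSE, dim = c(6, 6, 6)), g),
                            lamLu), "empty")
})

test_that("time-integrated activity coefficients match closed forms and the ledger", {
  t <- c(0, 3, 24, 72)
  # pure physical decay of the administered activity: TIAC = 1/lambda
  a0 <- 800
  expect_equal(tiac(a0 * exp(-lamLu * t), administeredMBq = a0,
                    fallbackRatePerH = lamLu, timesH = t),
               1 / lamLu, tolerance = 1e-3)
  expect_equal(tiac(rep(0, 4), administeredMBq = a0,
                    fallbackRatePerH = lamLu, timesH = t), 0)
  # phantom compartment: volume-sum route equals the analytic ledger rule
  spec <- phantomSpec(grid = voxelGrid(c(24, 24, 18)))
  ph <- buildPhantom(spec)
  for (cp in c("tumor", "LV")) {
    got <- tiac(ph$activity, administeredMBq = spec@administeredActivityMBq,
                fallbackRatePerH = decayConstantPerH(spec@nuclide),
                mask = ph$masks[[cp]])
    want <- ph$truth$tia_hybrid_MBq_h[ph$truth$name == cp] /
      spec@administeredActivityMBq
    expect_equal(got, want, tolerance = 1e-6)
  }
})
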