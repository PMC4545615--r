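lamLu <- log(2) / 161.04

test_that("Lea-Catcheside G reproduces the mono-exponential closed form", {
  for (lam in c(lamLu, 0.01, 0.05))
    for (mu in c(0.1, 0.46, 1.0)) {
      g <- leaCatchesideG(function(t) exp(-lam * t), muPerH = mu)
      expect_equal(g, lam / (lam + mu), tolerance = 1e-4)
    }
})

test_that("G limits: instantaneous delivery, fast repair, zero dose", {
  pulse <- function(t) as.numeric(t >= 0 & t <= 0.01) * 100
  expect_gt(leaCatchesideG(pulse, muPerH = 0.46, upperH = 0.01), 0.99)
  expect_lt(leaCatchesideG(function(t) exp(-lamLu * t), muPerH = 1e3), 1e-5)
  expect_error(leaCatchesideG(function(t) 0 * t, muPerH = 0.46), "zero total dose")
})

test_that("G accepts a hybrid fit and stays in (0, 1]", {
  fit <- fitHybrid(c(0, 3, 24, 72), c(10, 8, 4, 2), lamLu)
  g <- leaCatchesideG(fit, muPerH = 0.46)
  expect_gt(g, 0); expect_lte(g, 1)
  # protracted delivery over days: G far below 1
  expect_lt(g, 0.1)
})

test_that("BED follows the linear-quadratic protraction formula", {
  expect_equal(bed(0, 0.5), 0)
  expect_equal(bed(0.46, 1, 10), 0.46 * 1.046, tolerance = 1e-12)
  # at realistic G the excess over AD is a few hundredths of a percent
  excess <- bed(0.46, 0.00927, 10) / 0.46 - 1
  expect_equal(excess, 0.00927 * 0.46 / 10, tolerance = 1e-12)
  expect_lt(excess, 0.0011)
  # BED >= AD over a parameter grid; equality as AD or G vanish
  for (ad in c(0, 0.1, 0.5, 2, 10))
    for (g in c(0, 0.01, 0.5, 1))
      expect_gte(bed(ad, g), ad)
  expect_equal(bed(1e-9, 1), 1e-9, tolerance = 1e-6)
})

test_that("LV-route marrow dose reduces to the VOI integral on clean input", {
  t <- c(0, 3, 24, 72)
  g <- voxelGrid(c(6, 6, 6))
  vols <- lapply(c(5, 4, 2, 1), function(v)
    scalarVolume(array(v, dim = c(6, 6, 6)), g, "doserate_Gy_h"))
  s <- timeSeriesVolumes(t, vols)
  big <- voiMask(array(TRUE, dim = c(6, 6, 6)), g, "LV")
  sm <- array(FALSE, dim = c(6, 6, 6)); sm[1:3, 1:2, 1] <- TRUE
  rep1 <- rbmDoseLv3d(s, list(big, big, big, big))
  expect_equal(adGy(rep1), integrateVoi(s, big, lamLu), tolerance = 1e-9)
  # per-time-point masks of different sizes leave a uniform field unchanged
  rep2 <- rbmDoseLv3d(s, list(big, voiMask(sm, g), big, voiMask(sm, g)))
  expect_equal(adGy(rep2), adGy(rep1), tolerance = 1e-12)
  expect_gte(bedGy(rep1), adGy(rep1))
  expect_error(rbmDoseLv3d(s, list(big, big)), "one LV mask per time point")
  # linear in the dose-rate scale
  s2 <- timeSeriesVolumes(t, lapply(vols, function(v)
    scalarVolume(v@values * 2, g, "doserate_Gy_h")))
  expect_equal(adGy(rbmDoseLv3d(s2, list(big, big, big, big))),
               2 * adGy(rep1), tolerance = 1e-9)
})

test_that("blood-route dose matches the mono-exponential closed form", {
  cfg <- dosimetryConfig()
  times <- c(2 / 60, 0.5, 1, 2, 4, 24, 72)
  lamEff <- 0.03
  c0 <- 0.8
  conc <- c0 * exp(-lamEff * times)
  wb <- 6000 * exp(-lamEff * times)
  rep <- rbmDoseBlood(bloodSeries(times, conc, wb), cfg,
                      administeredMBq = 6000)
  # trapezoid + tail approximates c0 * mass / lambda within rule tolerance
  want <- c0 * cfg@rbmMassG / lamEff
  expect_equal(rep@intermediates$tia_rbm_MBq_h, want, tolerance = 0.10)
  # dose decomposes into the S-value terms exactly
  expect_equal(adGy(rep),
               (rep@intermediates$tia_rbm_MBq_h * cfg@sRbmSelfMGyPerMBqH +
                rep@intermediates$tia_remainder_MBq_h *
                  cfg@sRbmRemainderMGyPerMBqH) / 1000,
               tolerance = 1e-12)
  # zero input gives zero dose
  z <- rbmDoseBlood(bloodSeries(times, 0 * conc, 0 * wb), cfg,
                    administeredMBq = 6000)
  expect_equal(adGy(z), 0)
})

test_that("blood-route dose is linear in the marrow-blood ratio and activity", {
  times <- c(2 / 60, 0.5, 1, 2, 4, 24, 72)
  conc <- 0.8 * exp(-0.05 * times)
  wb <- 9000 * exp(-0.05 * times)
  d1 <- adGy(rbmDoseBlood(bloodSeries(times, conc, wb),
                          dosimetryConfig(s_rbm_from_remainder_mGy_per_MBq_h = 1e-12),
                          administeredMBq = 6000))
  d2 <- adGy(rbmDoseBlood(bloodSeries(times, conc, wb),
                          dosimetryConfig(rbm_to_blood_ratio = 0.5,
                                          s_rbm_from_remainder_mGy_per_MBq_h = 1e-12),
                          administeredMBq = 6000))
  expect_equal(d1 / d2, 2, tolerance = 1e-6)
  d3 <- adGy(rbmDoseBlood(bloodSeries(times, 2 * conc, 2 * wb),
                          dosimetryConfig(s_rbm_from_remainder_mGy_per_MBq_h = 1e-12),
                          administeredMBq = 12000))
  expect_equal(d3 / d1, 2, tolerance = 1e-9)
  # marrow integral above whole body floors the remainder with a warning
  expect_warning(
    rbmDoseBlood(bloodSeries(times, conc, 0.01 * wb), dosimetryConfig(),
                 administeredMBq = 6000),
    "floored")
})

test_that("cranium route recovers a midline source exactly and scales by rule", {
  cfg <- dosimetryConfig()
  Tcm <- 20
  roi <- matrix(FALSE, 5, 5); roi[2:4, 2:4] <- TRUE
  lam <- 0.05
  mkPlanar <- function(t, depth) {
    a0 <- 400 * exp(-lam * t) / sum(roi)
    ant <- matrix(0, 5, 5); pos <- matrix(0, 5, 5)
    ant[roi] <- a0 * exp(-cfg@attenuationCmInv * depth) /
      cfg@calibrationMBqPerCount
    pos[roi] <- a0 * exp(-cfg@attenuationCmInv * (Tcm - depth)) /
      cfg@calibrationMBqPerCount
    list(time_h = t, anterior = ant, posterior = pos)
  }
  series <- lapply(c(0.5, 3, 24, 72), mkPlanar, depth = 7)  # off-centre source
  rep <- rbmDoseCranium(series, roi, Tcm, cfg, administeredMBq = 5600)
  # conjugate view cancels the unknown depth: activity recovered exactly
  expect_equal(rep@intermediates$cranium_activity_MBq,
               400 * exp(-lam * c(0.5, 3, 24, 72)), tolerance = 1e-9)
  # dose = total-marrow time-integrated activity times the self S-value
  expect_equal(adGy(rep),
               rep@intermediates$tiac_total_rbm_h * 5600 *
                 cfg@sRbmSelfMGyPerMBqH / 1000, tolerance = 1e-12)
  # halving the cranium fraction doubles the dose exactly
  rep2 <- rbmDoseCranium(series, roi, Tcm,
                         dosimetryConfig(cranium_rbm_fraction = 0.119 / 2),
                         administeredMBq = 5600)
  expect_equal(adGy(rep2) / adGy(rep), 2, tolerance = 1e-12)
  # zero counts: zero dose with a warning
  zl <- lapply(series, function(p) {
    p$anterior[] <- 0; p$posterior[] <- 0; p })
  expect_warning(z <- rbmDoseCranium(zl, roi, Tcm, cfg,
                                     administeredMBq = 5600),
                 "zero cranium counts")
  expect_equal(adGy(z), 0)
})
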