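## Hybrid trapezoidal-exponential integration of 4-point time series:
## rectangle (or zero) from injection to the first sample, trapezoids
## between the first three samples, exponential tail anchored at the third
## sample with rate fitted to the final two.

.hybridTailRate <- function(y3, y4, dt, fallbackRatePerH) {
  if (y3 == 0 && y4 > 0)
    stop("non-physical growth from zero at the tail anchor (y3 = 0, y4 > 0)")
  if (y3 > 0 && y4 > 0 && y4 < y3)
    list(k = log(y3 / y4) / dt, fallback = FALSE)
  else
    list(k = fallbackRatePerH, fallback = TRUE)
}

#' Hybrid trapezoidal-exponential fit of a 4-point series
#'
#' Integrates a sampled time-activity or dose-rate curve over \[0, Inf):
#' a leading segment from t = 0 to the first sample (rectangle holding the
#' first value, or zero), trapezoids over the first three samples, and an
#' exponential tail \eqn{y_3 e^{-k (t - t_3)}} anchored at the third sample
#' with \eqn{k = \ln(y_3/y_4) / (t_4 - t_3)}. When the series does not
#' decrease over the last two samples the physically most conservative
#' admissible tail — the supplied physical decay constant — is substituted
#' and flagged.
#'
#' @param timesH strictly increasing sample times, length 4 (h).
#' @param values non-negative sampled values, length 4.
#' @param fallbackRatePerH physical decay constant used when the tail cannot
#'   be fitted (1/h).
#' @param leadingRule "rectangle" (default) or "zero".
#' @return A \linkS4class{HybridFit}.
#' @examples
#' fit <- fitHybrid(c(0, 3, 24, 72), c(100, 80, 40, 20),
#'                  fallbackRatePerH = log(2) / 161.04)
#' fit@integral
#' @export
fitHybrid <- function(timesH, values, fallbackRatePerH,
                      leadingRule = c("rectangle", "zero")) {
  leadingRule <- match.arg(leadingRule)
  stopifnot(length(timesH) == 4L, length(values) == 4L,
            all(is.finite(timesH)), all(is.finite(values)),
            all(diff(timesH) > 0), all(values >= 0),
            fallbackRatePerH > 0)
  t <- timesH; y <- values
  tail <- .hybridTailRate(y[3L], y[4L], t[4L] - t[3L], fallbackRatePerH)
  leading <- if (leadingRule == "rectangle") t[1L] * y[1L] else 0
  trap <- 0.5 * (y[1L] + y[2L]) * (t[2L] - t[1L]) +
          0.5 * (y[2L] + y[3L]) * (t[3L] - t[2L])
  tailInt <- if (y[3L] > 0) y[3L] / tail$k else 0
  new("HybridFit", timesH = t, values = y, tailRatePerH = tail$k,
      integral = leading + trap + tailInt, leadingRule = leadingRule,
      tailFallbackUsed = tail$fallback)
}

#' Evaluate a hybrid fit as a function of time
#'
#' @param fit a \linkS4class{HybridFit}.
#' @return A vectorised function of time (h) returning the piecewise curve:
#'   leading value on \[0, t1), linear interpolation on \[t1, t3\],
#'   exponential tail beyond t3.
#' @export
hybridFunction <- function(fit) {
  t <- fit@timesH; y <- fit@values; k <- fit@tailRatePerH
  lead <- if (fit@leadingRule == "rectangle") y[1L] else 0
  function(tt) {
    out <- numeric(length(tt))
    out[tt < 0] <- 0
    e <- tt >= 0 & tt < t[1L]
    out[e] <- lead
    m <- tt >= t[1L] & tt <= t[3L]
    if (any(m))
      out[m] <- approx(t[1:3], y[1:3], xout = tt[m], ties = "ordered")$y
    g <- tt > t[3L]
    out[g] <- y[3L] * exp(-k * (tt[g] - t[3L]))
    out
  }
}

#' Integrate a serial dose-rate map into a dose map
#'
#' Applies the hybrid trapezoidal-exponential rule voxel by voxel to four
#' aligned dose-rate volumes, yielding the absorbed dose map in Gy.
#'
#' @param doserateSeries a 4-point \linkS4class{TimeSeriesVolumes} of
#'   quantity \code{doserate_Gy_h}.
#' @param fallbackRatePerH physical decay constant for non-decreasing tails.
#' @param leadingRule "rectangle" or "zero".
#' @param zeroAnchor what to do with voxels whose rate is zero at the tail
#'   anchor but positive at the last scan — a non-physical pattern for
#'   noise-free input (an error, the default) that sparse Monte Carlo
#'   sampling can legitimately produce: \code{"late_tail"} gives such
#'   voxels a trapezoid over \[t3, t4\] plus a fallback-rate tail from t4.
#' @return A dose \linkS4class{ScalarVolume} (Gy).
#' @export
integrateDoseMap <- function(doserateSeries, fallbackRatePerH,
                             leadingRule = c("rectangle", "zero"),
                             zeroAnchor = c("error", "late_tail")) {
  leadingRule <- match.arg(leadingRule)
  zeroAnchor <- match.arg(zeroAnchor)
  stopifnot(is(doserateSeries, "TimeSeriesVolumes"),
            length(doserateSeries@timesH) == 4L,
            fallbackRatePerH > 0)
  t <- doserateSeries@timesH
  y1 <- doserateSeries@volumes[[1L]]@values
  y2 <- doserateSeries@volumes[[2L]]@values
  y3 <- doserateSeries@volumes[[3L]]@values
  y4 <- doserateSeries@volumes[[4L]]@values
  badGrow <- y3 == 0 & y4 > 0
  if (any(badGrow) && zeroAnchor == "error") {
    idx <- which(badGrow, arr.ind = TRUE)[1L, ]
    stop(sprintf("voxel (%d, %d, %d): non-physical growth from zero at the tail anchor",
                 idx[1L], idx[2L], idx[3L]))
  }
  k <- array(fallbackRatePerH, dim = dim(y3))
  fit <- y3 > 0 & y4 > 0 & y4 < y3
  k[fit] <- log(y3[fit] / y4[fit]) / (t[4L] - t[3L])
  leading <- if (leadingRule == "rectangle") t[1L] * y1 else 0
  dose <- leading +
    0.5 * (y1 + y2) * (t[2L] - t[1L]) +
    0.5 * (y2 + y3) * (t[3L] - t[2L]) +
    ifelse(y3 > 0, y3 / k, 0)
  if (any(badGrow))  # zeroAnchor == "late_tail"
    dose[badGrow] <- dose[badGrow] +
      0.5 * y4[badGrow] * (t[4L] - t[3L]) + y4[badGrow] / fallbackRatePerH
  scalarVolume(dose, doserateSeries@volumes[[1L]]@grid, "dose_Gy")
}

#' Integrate a VOI mean dose rate over time
#'
#' The VOI route to an absorbed dose: the energy-weighted mean dose rate
#' over the mask at each time point (mass-weighted when a density map is
#' given, arithmetic otherwise), then the same hybrid trapezoidal-
#' exponential rule applied to the four scalars.
#'
#' @param doserateSeries a 4-point \linkS4class{TimeSeriesVolumes}.
#' @param mask a non-empty \linkS4class{VoiMask}.
#' @param fallbackRatePerH physical decay constant for non-decreasing tails.
#' @param density optional density \linkS4class{ScalarVolume} for
#'   mass weighting.
#' @param leadingRule "rectangle" or "zero".
#' @return Mean absorbed dose over the VOI (Gy).
#' @export
integrateVoi <- function(doserateSeries, mask, fallbackRatePerH,
                         density = NULL,
                         leadingRule = c("rectangle", "zero")) {
  leadingRule <- match.arg(leadingRule)
  stopifnot(is(mask, "VoiMask"))
  if (!any(mask@mask)) stop("empty VOI mask")
  w <- if (is.null(density)) rep(1, sum(mask@mask))
       else density@values[mask@mask]
  rates <- vapply(doserateSeries@volumes, function(v)
    sum(v@values[mask@mask] * w) / sum(w), numeric(1))
  fitHybrid(doserateSeries@timesH, rates, fallbackRatePerH,
            leadingRule)@integral
}

#' Time-integrated activity coefficient
#'
#' Integral of the activity-time curve divided by the administered activity;
#' unit hours (formerly "residence time"). For a
#' \linkS4class{TimeSeriesVolumes} the activity is summed over the mask (or
#' the whole grid) at each time point and integrated with the hybrid rule;
#' a plain numeric series of four activities is integrated directly.
#'
#' @param x a 4-point activity \linkS4class{TimeSeriesVolumes} or a numeric
#'   vector of four activities (MBq).
#' @param administeredMBq administered activity (MBq), positive.
#' @param fallbackRatePerH physical decay constant for non-decreasing tails.
#' @param mask optional \linkS4class{VoiMask} restricting the sum.
#' @param timesH sample times, required for the numeric method.
#' @param leadingRule "rectangle" or "zero".
#' @return TIAC in hours.
#' @export
setGeneric("tiac", function(x, administeredMBq, fallbackRatePerH, ...)
  standardGeneric("tiac"))

#' @rdname tiac
#' @export
setMethod("tiac", "TimeSeriesVolumes",
  function(x, administeredMBq, fallbackRatePerH, mask = NULL,
           leadingRule = "rectangle") {
    stopifnot(administeredMBq > 0)
    a <- vapply(x@volumes, function(v) {
      if (is.null(mask)) sum(v@values) else sum(v@values[mask@mask])
    }, numeric(1))
    fitHybrid(x@timesH, a, fallbackRatePerH, leadingRule)@integral /
      administeredMBq
  })

#' @rdname tiac
#' @export
setMethod("tiac", "numeric",
  function(x, administeredMBq, fallbackRatePerH, timesH,
           leadingRule = "rectangle") {
    stopifnot(administeredMBq > 0)
    fitHybrid(timesH, x, fallbackRatePerH, leadingRule)@integral /
      administeredMBq
  })

## Trapezoid-plus-tail integral for densely sampled curves (blood, planar):
## trapezoids over the samples, leading rectangle back to t = 0, and an
## exponential tail from the last sample with rate from the final two
## samples (physical-decay fallback when not decreasing).
.trapzTailIntegral <- function(timesH, values, fallbackRatePerH) {
  stopifnot(length(timesH) >= 2L, all(diff(timesH) > 0), all(values >= 0))
  n <- length(values)
  lead <- timesH[1L] * values[1L]
  trap <- sum(0.5 * (values[-1L] + values[-n]) * diff(timesH))
  yl <- values[n]; yp <- values[n - 1L]
  k <- if (yl > 0 && yl < yp)
    log(yp / yl) / (timesH[n] - timesH[n - 1L])
  else fallbackRatePerH
  lead + trap + if (yl > 0) yl / k else 0
}
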