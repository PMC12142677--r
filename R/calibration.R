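## CCS calibration for traveling-wave cyclic ion mobility.
##
## Two routes from drift measurements to CCS:
##   * instrument-default: drift bins -> ms (pusher period) -> EDC-corrected
##     drift time -> corrected CCS via a linear fit -> CCS via charge and
##     reduced mass;
##   * multipass: Gaussian fitting of per-pass arrival-time distributions,
##     linear regression of (t_nd - t_s)/n on t_s/n to obtain the perturbed
##     periodic drift time t_pp, then a power-law calibration of corrected CCS
##     against t_pp.
##
## All calibrations fit *corrected* CCS (charge and reduced-mass dependence
## removed); conversion to/from CCS proper is correctedToCcs()/ccsToCorrected().

#' @import methods
NULL

.rsq <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum((y - yhat)^2) / sst
}

setClass("LinearCalibration", representation(
  slope = "numeric", intercept = "numeric",
  edcCoefficient = "numeric", edcUnitFactor = "numeric",
  pusherPeriod = "numeric", gasMass = "numeric",
  rSquared = "numeric", residuals = "numeric"
))

setClass("MultipassFit", representation(
  tpp = "numeric", velocityRatio = "numeric",
  rSquared = "numeric", residuals = "numeric"
))

setClass("PowerLawCalibration", representation(
  A = "numeric", B = "numeric", gasMass = "numeric",
  logResiduals = "numeric", residuals = "numeric"
))

setValidity("LinearCalibration", function(object) {
  if (!is.finite(object@slope)) return("slope must be finite")
  TRUE
})
setValidity("MultipassFit", function(object) {
  if (object@tpp <= 0) return("tpp must be positive")
  TRUE
})
setValidity("PowerLawCalibration", function(object) {
  if (object@A <= 0) return("power-law scale A must be positive")
  TRUE
})

setMethod("show", "LinearCalibration", function(object) {
  cat("LinearCalibration (instrument-default)\n",
      "  corrected CCS = ", signif(object@slope, 6), " * t_c* + ",
      signif(object@intercept, 6), "\n",
      "  EDC coefficient: ", object@edcCoefficient,
      "  pusher period (us): ", object@pusherPeriod, "\n",
      "  R^2: ", signif(object@rSquared, 6), " on ",
      length(object@residuals), " calibrants\n", sep = "")
})
setMethod("show", "MultipassFit", function(object) {
  cat("MultipassFit\n  t_pp (ms): ", signif(object@tpp, 8),
      "   v_u/v_p: ", signif(object@velocityRatio, 8),
      "\n  R^2: ", signif(object@rSquared, 6), " on ",
      length(object@residuals), " pass settings\n", sep = "")
})
setMethod("show", "PowerLawCalibration", function(object) {
  cat("PowerLawCalibration\n  corrected CCS = ", signif(object@A, 6),
      " * t_pp ^ ", signif(object@B, 6), "\n  fitted on ",
      length(object@residuals), " calibrants\n", sep = "")
})

#' Accessors for calibration model parameters
#'
#' @param object A calibration model object.
#' @return The requested parameter(s).
#' @name calibration-accessors
NULL

#' @rdname calibration-accessors
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))
#' @rdname calibration-accessors
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))
#' @rdname calibration-accessors
#' @export
setGeneric("perturbedDriftTime", function(object) standardGeneric("perturbedDriftTime"))
#' @rdname calibration-accessors
#' @export
setGeneric("velocityRatio", function(object) standardGeneric("velocityRatio"))
#' @rdname calibration-accessors
#' @export
setGeneric("powerLawCoef", function(object) standardGeneric("powerLawCoef"))

#' @rdname calibration-accessors
setMethod("calSlope", "LinearCalibration", function(object) object@slope)
#' @rdname calibration-accessors
setMethod("calIntercept", "LinearCalibration", function(object) object@intercept)
#' @rdname calibration-accessors
setMethod("perturbedDriftTime", "MultipassFit", function(object) object@tpp)
#' @rdname calibration-accessors
setMethod("velocityRatio", "MultipassFit", function(object) object@velocityRatio)
#' @rdname calibration-accessors
setMethod("powerLawCoef", "PowerLawCalibration",
          function(object) c(A = object@A, B = object@B))

#' Convert drift bins to milliseconds
#'
#' `t_d(ms) = t_d(bins) * pusherPeriod / 1000`, with the ADC pusher period in
#' microseconds.
#'
#' @param bins Drift time in bins (>= 0).
#' @param pusherPeriod ADC pusher period in microseconds (>= 0).
#' @return Drift time in ms.
#' @export
#' @examples
#' binsToMs(100, 60)
binsToMs <- function(bins, pusherPeriod) {
  stopifnot(all(bins >= 0), all(pusherPeriod >= 0))
  bins * pusherPeriod / 1000
}

#' EDC-corrected drift time
#'
#' Removes the m/z-dependent transfer time: `t_c* = t_d(ms) - C * sqrt(m/z)`.
#' The instrument EDC coefficient's scale is configurable through
#' `unitFactor` (applied multiplicatively to `C`; default 1).
#'
#' @param tdMs Drift time in ms.
#' @param C EDC coefficient (instrument constant).
#' @param mz m/z of the ion (> 0).
#' @param unitFactor Scale applied to `C` before use.
#' @return Corrected drift time in ms; errors if non-positive.
#' @export
#' @examples
#' edcCorrect(10, 0.1, 400)
edcCorrect <- function(tdMs, C, mz, unitFactor = 1) {
  stopifnot(all(mz > 0))
  tc <- tdMs - C * unitFactor * sqrt(mz)
  if (any(tc <= 0)) {
    stop("EDC correction gives non-positive corrected drift time")
  }
  tc
}

#' Convert corrected CCS to CCS and back
#'
#' `CCS = correctedCCS * z * sqrt(1/mu)` with `mu` the ion-gas reduced mass;
#' `ccsToCorrected()` is the exact inverse, used by the simulator and the
#' power-law calibration.
#'
#' @param ccsCorrected,ccs CCS values in squared Angstrom.
#' @param z Charge (>= 1).
#' @param mu Reduced mass in Da (> 0).
#' @return CCS (or corrected CCS) in squared Angstrom.
#' @export
#' @examples
#' correctedToCcs(150, z = 1, mu = 26.5988)
correctedToCcs <- function(ccsCorrected, z, mu) {
  stopifnot(all(ccsCorrected > 0), all(z >= 1), all(mu > 0))
  ccsCorrected * z * sqrt(1 / mu)
}

#' @rdname correctedToCcs
#' @export
ccsToCorrected <- function(ccs, z, mu) {
  stopifnot(all(ccs > 0), all(z >= 1), all(mu > 0))
  ccs / (z * sqrt(1 / mu))
}

#' Fit the instrument-default linear CCS calibration
#'
#' Ordinary least squares of corrected CCS on EDC-corrected drift time,
#' `correctedCcs = m * tc + b`, as used by the instrument's manual calibration
#' with a calibrant mixture.
#'
#' @param tc Corrected drift times (ms) of the calibrants; >= 2 distinct.
#' @param ccsCorrected Corrected CCS values of the calibrants (same length).
#' @param edcCoefficient,edcUnitFactor,pusherPeriod Instrument constants
#'   stored in the model so that the full bins-to-CCS chain can run.
#' @param gas Drift gas, as from [driftGas()].
#' @return A `LinearCalibration` object.
#' @export
#' @examples
#' fitLinearCalibration(c(1, 2, 3), c(110, 210, 310))
fitLinearCalibration <- function(tc, ccsCorrected, edcCoefficient = 0,
                                 edcUnitFactor = 1, pusherPeriod = NA_real_,
                                 gas = driftGas()) {
  stopifnot(length(tc) == length(ccsCorrected))
  if (length(tc) < 2) stop("need at least 2 calibrant pairs")
  if (length(unique(tc)) < 2) stop("all corrected drift times identical")
  fit <- stats::lm(ccsCorrected ~ tc)
  cf <- stats::coef(fit)
  r2 <- .rsq(ccsCorrected, stats::fitted(fit))
  new("LinearCalibration",
      slope = unname(cf[2]), intercept = unname(cf[1]),
      edcCoefficient = edcCoefficient, edcUnitFactor = edcUnitFactor,
      pusherPeriod = pusherPeriod, gasMass = gas$mass,
      rSquared = r2, residuals = unname(stats::resid(fit)))
}

#' CCS from drift bins via the instrument-default chain
#'
#' Runs bins -> ms -> EDC correction -> linear calibration -> charge and
#' reduced-mass conversion, returning the final CCS.
#'
#' @param model A `LinearCalibration` carrying the instrument constants.
#' @param bins Drift time in bins.
#' @param mz m/z of the ion.
#' @param z Charge.
#' @param mIon Ion mass in Da (typically `mz * z` under the neutral-atom
#'   convention).
#' @return CCS in squared Angstrom.
#' @export
defaultCcs <- function(model, bins, mz, z, mIon = mz * z) {
  tdMs <- binsToMs(bins, model@pusherPeriod)
  tc <- edcCorrect(tdMs, model@edcCoefficient, mz, model@edcUnitFactor)
  omegaC <- model@slope * tc + model@intercept
  mu <- reducedMass(mIon, model@gasMass)
  correctedToCcs(omegaC, z, mu)
}

#' Invert the instrument-default chain (simulator support)
#'
#' Exact inverse of [defaultCcs()]: from a true CCS to the drift-bin reading
#' that would produce it.
#'
#' @inheritParams defaultCcs
#' @param ccs True CCS in squared Angstrom.
#' @return Drift time in bins.
#' @export
ccsToBins <- function(model, ccs, mz, z, mIon = mz * z) {
  mu <- reducedMass(mIon, model@gasMass)
  omegaC <- ccsToCorrected(ccs, z, mu)
  tc <- (omegaC - model@intercept) / model@slope
  tdMs <- tc + model@edcCoefficient * model@edcUnitFactor * sqrt(mz)
  tdMs * 1000 / model@pusherPeriod
}

#' Fit a Gaussian to an arrival-time distribution
#'
#' Nonlinear least-squares Gaussian fit used to locate calibrant arrival-time
#' apexes.  Initialisation: mean at the max-intensity point, sigma from the
#' full width at half maximum, amplitude from the maximum; the fit uses points
#' within 3 initial sigma of the initial mean.
#'
#' @param times Arrival times (ms), >= 5 points.
#' @param intensities Intensities (same length, non-constant).
#' @return List with `apex` (fitted mean, ms), `width` (fitted sigma, ms),
#'   `amplitude`, and the `nls` fit object.
#' @export
fitGaussianPeak <- function(times, intensities) {
  stopifnot(length(times) == length(intensities))
  if (length(times) < 5) stop("need at least 5 points for a Gaussian fit")
  if (diff(range(intensities)) == 0) stop("flat signal: cannot fit a peak")
  i0 <- which.max(intensities)
  mu0 <- times[i0]
  a0 <- intensities[i0]
  half <- a0 / 2
  above <- which(intensities >= half)
  fwhm <- diff(range(times[above]))
  s0 <- max(fwhm / 2.3548, diff(range(times)) / 50)
  keep <- abs(times - mu0) <= 3 * s0
  df <- data.frame(t = times[keep], y = intensities[keep])
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(t - m)^2 / (2 * s^2)), data = df,
    start = list(a = a0, m = mu0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(apex = unname(cf["m"]), width = abs(unname(cf["s"])),
       amplitude = unname(cf["a"]), fit = fit)
}

#' Fit the perturbed periodic drift time from multipass observations
#'
#' Linear regression of `(t_nd - t_s)/n` on `t_s/n` over pass settings: the
#' intercept is the perturbed periodic drift time t_pp, the slope is minus the
#' unperturbed-to-perturbed velocity ratio v_u/v_p.
#'
#' @param n Pass counts (positive integers).
#' @param ts Separation times (ms), same length.
#' @param tnd Total drift times (ms), same length.
#' @return A `MultipassFit` object.
#' @export
#' @examples
#' n <- 1:4; ts <- n * 20
#' tnd <- ts + n * 20 - 1.05 * ts  # t_pp = 20 ms, v_u/v_p = 1.05
#' fitTpp(n, ts, tnd)
fitTpp <- function(n, ts, tnd) {
  stopifnot(length(n) == length(ts), length(ts) == length(tnd), all(n >= 1))
  if (length(n) < 2) stop("need at least 2 multipass observations")
  x <- ts / n
  y <- (tnd - ts) / n
  if (length(unique(x)) < 2) stop("pass settings give identical t_s/n: underdetermined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r2 <- .rsq(y, stats::fitted(fit))
  new("MultipassFit",
      tpp = unname(cf[1]), velocityRatio = -unname(cf[2]),
      rSquared = r2, residuals = unname(stats::resid(fit)))
}

#' Fit the multipass power-law CCS calibration
#'
#' Fits `correctedCcs = A * t_pp ^ B` by ordinary least squares in log-log
#' space (deterministic, initialisation-free).  Reference CCS values are
#' supplied already reduced to corrected CCS (see [ccsToCorrected()]).
#'
#' @param tpp Perturbed periodic drift times of the calibrants (ms, > 0).
#' @param ccsCorrected Corrected reference CCS values (> 0, same length).
#' @param gas Drift gas stored for downstream conversion.
#' @return A `PowerLawCalibration` object.
#' @export
fitPowerLaw <- function(tpp, ccsCorrected, gas = driftGas()) {
  stopifnot(length(tpp) == length(ccsCorrected))
  if (length(tpp) < 2) stop("need at least 2 calibrants")
  if (any(tpp <= 0) || any(ccsCorrected <= 0)) {
    stop("power-law calibration needs positive drift times and CCS values")
  }
  fit <- stats::lm(log(ccsCorrected) ~ log(tpp))
  cf <- stats::coef(fit)
  A <- exp(unname(cf[1])); B <- unname(cf[2])
  pred <- A * tpp^B
  new("PowerLawCalibration", A = A, B = B, gasMass = gas$mass,
      logResiduals = unname(stats::resid(fit)),
      residuals = ccsCorrected - pred)
}

#' CCS of an ion from its perturbed periodic drift time
#'
#' Applies the multipass power-law calibration and converts corrected CCS to
#' CCS with the ion's charge and reduced mass.
#'
#' @param model A `PowerLawCalibration`.
#' @param tpp Perturbed periodic drift time (ms).
#' @param z Charge.
#' @param mIon Ion mass in Da.
#' @return CCS in squared Angstrom.
#' @export
multipassCcs <- function(model, tpp, z, mIon) {
  stopifnot(all(tpp > 0))
  omegaC <- model@A * tpp^model@B
  mu <- reducedMass(mIon, model@gasMass)
  correctedToCcs(omegaC, z, mu)
}

#' Percent CCS error against a reference value
#'
#' @param experimental,reference CCS values; `reference > 0`.
#' @param signed If `TRUE`, return the signed error; default is absolute.
#' @return Percent error.
#' @export
#' @examples
#' ccsPercentError(202, 200)
ccsPercentError <- function(experimental, reference, signed = FALSE) {
  stopifnot(all(reference > 0))
  err <- (experimental - reference) / reference * 100
  if (signed) err else abs(err)
}
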