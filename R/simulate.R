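## Ground-truth simulators for every analysis module: multipass cyclic-IM
## arrival-time spectra, imaging feature studies with planted effects,
## candidate lists with controlled CCS offsets, and synthetic predictor
## training data.  Every simulated artifact carries its truth so recovery
## tests compare against it, never against hard-coded numbers; all randomness
## flows from the explicit seed argument.

#' Default multipass acquisition settings
#'
#' Pass counts 1-6 with separation times that are not exact multiples of the
#' per-pass time (as in practice, where the user-set separation time lands
#' partway through a circuit): this keeps `ts/n` distinct across settings,
#' which the perturbed-drift regression requires.
#'
#' @param nPasses Pass counts (default 1:6).
#' @param tsPerPass Nominal circuit time in ms (default 15).
#' @param fillFraction Fraction of the final circuit covered by the
#'   separation time (default 0.85).
#' @return Data frame with columns `n` and `ts`.
#' @export
passSettings <- function(nPasses = 1:6, tsPerPass = 15, fillFraction = 0.85) {
  data.frame(n = nPasses, ts = (nPasses - 1 + fillFraction) * tsPerPass)
}

#' Simulate multipass cyclic-IM arrival-time data
#'
#' For each ion, the perturbed periodic drift time is derived from the true
#' CCS through the inverted power-law calibration; total drift times for each
#' pass setting follow the perturbed-drift model
#' `t_nd = t_s + n * t_pp - (v_u/v_p) * t_s`, optionally jittered; a Gaussian
#' arrival-time peak is sampled around each `t_nd` with width growing as the
#' square root of the drift time (diffusional broadening), plus additive
#' intensity noise.
#'
#' @param trueCcs Named numeric vector of true CCS values (squared Angstrom).
#' @param mz m/z of each ion (same length).
#' @param z Charge of each ion (default 1).
#' @param settings Pass settings, as from [passSettings()].
#' @param A,B True power-law coefficients (corrected CCS = A * t_pp^B).
#' @param velocityRatio True unperturbed/perturbed velocity ratio v_u/v_p.
#' @param apexJitterSd Gaussian jitter of each arrival apex in ms (default 0).
#' @param intensityNoiseSd Additive intensity noise as a fraction of the peak
#'   amplitude (default 0).
#' @param widthCoef Peak sigma = `widthCoef * sqrt(t_nd)` ms (default 0.03).
#' @param nPoints Samples per arrival histogram (default 81).
#' @param gas Drift gas (default N2).
#' @param seed Integer seed.
#' @return List with `ions` (per ion, a list of histograms: `n`, `ts`,
#'   `times`, `intensities`) and `truth` (`ccs`, `ccsCorrected`, `tpp`, `A`,
#'   `B`, `velocityRatio`, `mz`, `z`, `seed`).
#' @export
simulateMultipass <- function(trueCcs, mz, z = rep(1L, length(trueCcs)),
                              settings = passSettings(),
                              A = 370, B = 0.55, velocityRatio = 1.05,
                              apexJitterSd = 0, intensityNoiseSd = 0,
                              widthCoef = 0.03, nPoints = 81,
                              gas = driftGas(), seed = 1L) {
  stopifnot(length(trueCcs) == length(mz), length(mz) == length(z),
            all(trueCcs > 0), apexJitterSd >= 0, intensityNoiseSd >= 0)
  if (is.null(names(trueCcs))) names(trueCcs) <- paste0("ion", seq_along(trueCcs))
  set.seed(seed)
  mIon <- mz * z
  mu <- reducedMass(mIon, gas$mass)
  ccsCorr <- ccsToCorrected(trueCcs, z, mu)
  tpp <- (ccsCorr / A)^(1 / B)
  ions <- lapply(seq_along(trueCcs), function(i) {
    lapply(seq_len(nrow(settings)), function(k) {
      n <- settings$n[k]; ts <- settings$ts[k]
      tnd <- ts + n * tpp[i] - velocityRatio * ts
      if (tnd <= 0) stop("pass settings give non-positive drift time")
      center <- tnd + if (apexJitterSd > 0) stats::rnorm(1, 0, apexJitterSd) else 0
      sig <- widthCoef * sqrt(tnd)
      times <- seq(center - 4 * sig, center + 4 * sig, length.out = nPoints)
      y <- exp(-(times - center)^2 / (2 * sig^2))
      if (intensityNoiseSd > 0) y <- y + stats::rnorm(nPoints, 0, intensityNoiseSd)
      list(n = n, ts = ts, times = times, intensities = y)
    })
  })
  names(ions) <- names(trueCcs)
  list(ions = ions,
       truth = list(ccs = trueCcs, ccsCorrected = ccsCorr, tpp = tpp,
                    A = A, B = B, velocityRatio = velocityRatio,
                    mz = mz, z = z, gasMass = gas$mass, seed = seed))
}

#' Estimate the perturbed periodic drift time of one simulated ion
#'
#' Fits a Gaussian to each pass setting's arrival histogram and regresses the
#' apexes with [fitTpp()].
#'
#' @param histograms One element of a [simulateMultipass()] `ions` list.
#' @return A `MultipassFit`.
#' @export
estimateTpp <- function(histograms) {
  n <- vapply(histograms, `[[`, numeric(1), "n")
  ts <- vapply(histograms, `[[`, numeric(1), "ts")
  apex <- vapply(histograms, function(h) {
    fitGaussianPeak(h$times, h$intensities)$apex
  }, numeric(1))
  fitTpp(n, ts, apex)
}

#' Run the full multipass calibration workflow on simulated data
#'
#' Estimates every ion's t_pp from its arrival histograms, fits the power-law
#' calibration on the designated calibrant ions against their reference CCS
#' values (reduced to corrected CCS), and returns multipass CCS estimates for
#' all ions.  For comparison, a single-pass linear calibration fitted on the
#' same calibrants' one-pass arrival times is also applied.
#'
#' @param sim Output of [simulateMultipass()].
#' @param calibrants Names of the calibrant ions.
#' @param referenceCcs Reference CCS values for the calibrants (defaults to
#'   the simulation truth, i.e. perfectly known literature values).
#' @return Data frame per ion: `ion`, `tppHat`, `ccsMultipass`, `ccsLinear`,
#'   `trueCcs`, `isCalibrant`; the fitted `PowerLawCalibration` and
#'   `LinearCalibration` are attached as attributes.
#' @export
multipassWorkflow <- function(sim, calibrants,
                              referenceCcs = sim$truth$ccs[calibrants]) {
  ionNames <- names(sim$ions)
  stopifnot(all(calibrants %in% ionNames))
  tr <- sim$truth
  gas <- driftGas(tr$gasMass)
  tppHat <- vapply(sim$ions, function(h) perturbedDriftTime(estimateTpp(h)),
                   numeric(1))
  mIon <- tr$mz * tr$z
  mu <- reducedMass(mIon, tr$gasMass)
  names(mu) <- names(tppHat) <- ionNames

  calIdx <- match(calibrants, ionNames)
  refCorr <- ccsToCorrected(referenceCcs, tr$z[calIdx], mu[calIdx])
  pl <- fitPowerLaw(tppHat[calibrants], refCorr, gas = gas)
  ccsMp <- vapply(seq_along(ionNames), function(i) {
    multipassCcs(pl, tppHat[i], tr$z[i], mIon[i])
  }, numeric(1))

  # single-pass comparator: arrival time at n = 1 as the drift time,
  # linear fit of corrected CCS against it (no EDC term in this simulation)
  t1 <- vapply(sim$ions, function(h) {
    k <- which(vapply(h, `[[`, numeric(1), "n") == 1)[1]
    if (is.na(k)) return(NA_real_)
    fitGaussianPeak(h[[k]]$times, h[[k]]$intensities)$apex
  }, numeric(1))
  ccsLin <- rep(NA_real_, length(ionNames))
  if (!anyNA(t1[calibrants])) {
    lin <- fitLinearCalibration(t1[calibrants], refCorr, gas = gas)
    omegaC <- calSlope(lin) * t1 + calIntercept(lin)
    ccsLin <- correctedToCcs(pmax(omegaC, 1e-9), tr$z, mu)
  } else lin <- NULL

  out <- data.frame(ion = ionNames, tppHat = unname(tppHat),
                    ccsMultipass = ccsMp, ccsLinear = ccsLin,
                    trueCcs = unname(tr$ccs),
                    isCalibrant = ionNames %in% calibrants)
  attr(out, "powerLaw") <- pl
  attr(out, "linear") <- if (!is.null(lin)) lin else NULL
  out
}

#' Simulate an imaging feature study with planted ground truth
#'
#' Generates an aligned universe of features with log-normal intensities,
#' planted fold changes for a fraction of features, first-isotopologue
#' partners, doubly charged partner features, and per-run m/z and drift
#' jitter.  Defaults mirror a small two-group tissue study: 4 sections per
#' group, 1.5-fold minimum detectable change territory.
#'
#' @param nFeatures Number of true analyte features (default 200).
#' @param nPerGroup Samples (tissue sections) per group (default 4).
#' @param effectFraction Fraction of features with a planted group effect
#'   (default 0.1).
#' @param effectSize Planted fold change, applied in a random direction
#'   (default 4).
#' @param isotopeFraction Fraction of features given an isotope partner
#'   (default 0.15).
#' @param doublyChargedPairs Number of planted charge-state pairs (default 2).
#' @param mzJitterSd Per-run m/z jitter sd in Da (default 0.005).
#' @param driftJitterSd Per-run drift jitter sd in bins (default 0.4).
#' @param intensitySdLog Log-scale sd of multiplicative intensity noise
#'   (default 0.3).
#' @param seed Integer seed.
#' @return List with `runs` (per sample, data frame `mz`, `drift`,
#'   `intensity`), `samples` (sample/group map), `intensities` (true-feature
#'   by sample matrix of drawn intensities), and `truth` (per-feature m/z,
#'   drift, flags, planted FC, isotope parents, charge-pair ids, seed).
#' @export
simulateFeatureStudy <- function(nFeatures = 200, nPerGroup = 4,
                                 effectFraction = 0.1, effectSize = 4,
                                 isotopeFraction = 0.15,
                                 doublyChargedPairs = 2,
                                 mzJitterSd = 0.005, driftJitterSd = 0.4,
                                 intensitySdLog = 0.3, seed = 1L) {
  stopifnot(nFeatures >= 1, nPerGroup >= 1,
            effectFraction >= 0, effectFraction <= 1,
            isotopeFraction >= 0, isotopeFraction <= 1)
  set.seed(seed)
  nEff <- round(effectFraction * nFeatures)
  nIso <- round(isotopeFraction * nFeatures)

  mz <- sort(stats::runif(nFeatures, 150, 1000))
  drift <- stats::runif(nFeatures, 10, 190)
  base <- stats::rlnorm(nFeatures, log(1000), 0.8)
  fc <- rep(1, nFeatures)
  effIdx <- if (nEff > 0) sample.int(nFeatures, nEff) else integer(0)
  if (nEff > 0) {
    dirUp <- sample(c(TRUE, FALSE), nEff, replace = TRUE)
    fc[effIdx] <- ifelse(dirUp, effectSize, 1 / effectSize)
  }
  truth <- data.frame(feature = seq_len(nFeatures), mz = mz, drift = drift,
                      z = 1L, baseMean = base, fc = fc,
                      effect = seq_len(nFeatures) %in% effIdx,
                      kind = "analyte", parent = NA_integer_,
                      pair = NA_integer_)

  # isotope partners
  if (nIso > 0) {
    isoParent <- sample.int(nFeatures, nIso)
    ratio <- stats::runif(nIso, 0.2, 0.5)
    iso <- truth[isoParent, ]
    iso$feature <- nrow(truth) + seq_len(nIso)
    iso$mz <- isotopeMz(iso$mz, iso$z, 1L)
    iso$baseMean <- iso$baseMean * ratio
    iso$kind <- "isotope"
    iso$parent <- isoParent
    truth <- rbind(truth, iso)
  }
  # doubly charged partners of the first few analytes
  if (doublyChargedPairs > 0) {
    pIdx <- seq_len(min(doublyChargedPairs, nFeatures))
    dc <- truth[pIdx, ]
    dc$feature <- nrow(truth) + seq_along(pIdx)
    dc$mz <- (truth$mz[pIdx] + 1.00782503207) / 2
    dc$z <- 2L
    dc$drift <- truth$drift[pIdx] / 2
    dc$baseMean <- truth$baseMean[pIdx] * 0.5
    dc$kind <- "doubly_charged"
    dc$pair <- pIdx
    truth$pair[pIdx] <- dc$feature
    truth <- rbind(truth, dc)
  }
  rownames(truth) <- NULL
  nAll <- nrow(truth)

  samples <- data.frame(
    sample = c(paste0("control", seq_len(nPerGroup)),
               paste0("tumor", seq_len(nPerGroup))),
    group = rep(c("control", "tumor"), each = nPerGroup))
  # FC oriented control/tumor: tumor mean = control mean / fc
  groupMean <- cbind(control = truth$baseMean,
                     tumor = truth$baseMean / truth$fc)
  intensities <- sapply(seq_len(nrow(samples)), function(s) {
    m <- groupMean[, samples$group[s]]
    m * stats::rlnorm(nAll, -intensitySdLog^2 / 2, intensitySdLog)
  })
  colnames(intensities) <- samples$sample

  runs <- lapply(seq_len(nrow(samples)), function(s) {
    data.frame(mz = truth$mz + stats::rnorm(nAll, 0, mzJitterSd),
               drift = truth$drift + stats::rnorm(nAll, 0, driftJitterSd),
               intensity = intensities[, s])
  })
  names(runs) <- samples$sample
  truth$seed <- seed
  list(runs = runs, samples = samples, intensities = intensities, truth = truth)
}

.alkane <- function(i) {
  list(smiles = strrep("C", i + 1),
       formula = paste0("C", i + 1, "H", 2 * (i + 1) + 2))
}

#' Simulate an annotation candidate list with known truth
#'
#' Builds a rank-ordered candidate list: the true structure with a small CCS
#' offset, plus decoys whose offsets are drawn from a supplied sampler
#' (default: 2-5% in either direction, the mismatch scale typical of
#' wrong-structure candidates).
#'
#' @param nDecoys Number of decoy candidates.
#' @param trueOffset Signed percent CCS offset of the true candidate
#'   (default 0.3).
#' @param decoyOffsets Function of `n` returning signed percent offsets
#'   (default uniform 2-5%, random sign).
#' @param experimentalCcs Experimental CCS the offsets are relative to.
#' @param nDeNovo Number of decoys labeled `"de novo"` (default half).
#' @param seed Integer seed.
#' @return Data frame of candidates (`rank`, `structure`, `formula`,
#'   `adduct`, `source`, `predictedCcs`, `percentDiff`, `isTruth`) with the
#'   truth parameters attached as attribute `"truth"`.
#' @export
simulateCandidates <- function(nDecoys = 19, trueOffset = 0.3,
                               decoyOffsets = function(n)
                                 stats::runif(n, 2, 5) * sample(c(-1, 1), n, TRUE),
                               experimentalCcs = 280,
                               nDeNovo = floor(nDecoys / 2), seed = 1L) {
  set.seed(seed)
  offs <- c(trueOffset, decoyOffsets(nDecoys))
  nTot <- nDecoys + 1L
  structs <- lapply(seq_len(nTot), .alkane)
  src <- c("database",
           sample(rep(c("de novo", "database"),
                      c(nDeNovo, nDecoys - nDeNovo))))
  out <- data.frame(
    rank = seq_len(nTot),
    structure = vapply(structs, `[[`, character(1), "smiles"),
    formula = vapply(structs, `[[`, character(1), "formula"),
    adduct = "[M+H]+", source = src,
    predictedCcs = experimentalCcs * (1 + offs / 100),
    percentDiff = offs,
    isTruth = c(TRUE, rep(FALSE, nDecoys)))
  attr(out, "truth") <- list(trueOffset = trueOffset, offsets = offs,
                             experimentalCcs = experimentalCcs, seed = seed)
  out
}

#' Construct a candidate list with prescribed offset bands
#'
#' Builds a list in which a chosen number of candidates lie beyond each of two
#' nested thresholds; used to exercise the nesting of removal counts as the
#' threshold tightens (e.g. 108 candidates of which 78 exceed 1% and 91
#' exceed 0.5%).
#'
#' @param nTotal Total candidates (default 108).
#' @param nBeyond1 Candidates with |offset| > 1% (default 78).
#' @param nBeyond05 Candidates with |offset| > 0.5% (default 91; must be
#'   >= `nBeyond1`).
#' @param nDatabase Candidates labeled `"database"` (default 8; the rest are
#'   de novo).
#' @param experimentalCcs Experimental CCS (default 280).
#' @param seed Integer seed.
#' @return Candidate data frame as in [simulateCandidates()].
#' @export
simulateCandidateScenario <- function(nTotal = 108, nBeyond1 = 78,
                                      nBeyond05 = 91, nDatabase = 8,
                                      experimentalCcs = 280, seed = 1L) {
  stopifnot(nBeyond05 >= nBeyond1, nTotal >= nBeyond05)
  set.seed(seed)
  nMid <- nBeyond05 - nBeyond1
  nClose <- nTotal - nBeyond05
  offs <- c(stats::runif(nBeyond1, 1.2, 5),
            stats::runif(nMid, 0.55, 0.95),
            stats::runif(nClose, 0, 0.45)) *
    sample(c(-1, 1), nTotal, replace = TRUE)
  offs <- sample(offs)
  structs <- lapply(seq_len(nTotal), .alkane)
  src <- sample(rep(c("database", "de novo"), c(nDatabase, nTotal - nDatabase)))
  out <- data.frame(
    rank = seq_len(nTotal),
    structure = vapply(structs, `[[`, character(1), "smiles"),
    formula = vapply(structs, `[[`, character(1), "formula"),
    adduct = "[M+H]+", source = src,
    predictedCcs = experimentalCcs * (1 + offs / 100),
    percentDiff = offs)
  attr(out, "truth") <- list(offsets = offs, seed = seed,
                             nBeyond1 = nBeyond1, nBeyond05 = nBeyond05)
  out
}

#' Simulate isobar pairs for CCS adjudication
#'
#' Each pair has a true candidate whose predicted CCS lies within
#' `truthWithin` percent of the experimental value and a decoy beyond
#' `decoyBeyond` percent; the true species is the sodiated adduct and the
#' decoy the protonated one, the configuration in which isobaric
#' database matches arise in positive-mode lipid imaging.
#'
#' @param nPairs Number of pairs (default 5).
#' @param truthWithin Upper bound on the truth's |offset|, percent
#'   (default 0.5).
#' @param decoyBeyond Lower bound on the decoy's |offset|, percent
#'   (default 1.5).
#' @param seed Integer seed.
#' @return List of pairs; each has `experimentalCcs` and a two-row
#'   `candidates` data frame with `name`, `adduct`, `predictedCcs`,
#'   `isTruth`.
#' @export
simulateIsobarPairs <- function(nPairs = 5, truthWithin = 0.5,
                                decoyBeyond = 1.5, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(nPairs), function(i) {
    ccs <- stats::runif(1, 250, 330)
    offT <- stats::runif(1, 0, truthWithin) * sample(c(-1, 1), 1)
    offD <- stats::runif(1, decoyBeyond, decoyBeyond + 2) * sample(c(-1, 1), 1)
    cand <- data.frame(
      name = c(paste0("pair", i, "_Na"), paste0("pair", i, "_H")),
      adduct = c("[M+Na]+", "[M+H]+"),
      predictedCcs = ccs * (1 + c(offT, offD) / 100),
      isTruth = c(TRUE, FALSE))
    list(experimentalCcs = ccs, candidates = cand)
  })
}

#' Simulate CCS predictor training data
#'
#' Descriptor vectors with a known generative CCS function plus Gaussian
#' noise; the default function is a smooth function of the first two
#' descriptors.
#'
#' @param n Number of records (>= 20).
#' @param descriptorDim Number of descriptor columns (default 5).
#' @param generativeFunction Function of the descriptor matrix returning true
#'   CCS; default `180 + 12 d1 + 6 d2 + 0.4 d1 d2`.
#' @param noiseSd Additive CCS noise sd in squared Angstrom (default 1).
#' @param adduct Adduct label attached to all records.
#' @param seed Integer seed.
#' @return Data frame `id`, `adduct`, `ccs`, `d1..dk`, with the generative
#'   function, noiseless CCS and seed attached as attribute `"truth"`.
#' @export
simulatePredictorData <- function(n = 500, descriptorDim = 5,
                                  generativeFunction = NULL, noiseSd = 1,
                                  adduct = "[M+H]+", seed = 1L) {
  stopifnot(n >= 20, descriptorDim >= 2, noiseSd >= 0)
  if (is.null(generativeFunction)) {
    generativeFunction <- function(D) 180 + 12 * D[, 1] + 6 * D[, 2] + 0.4 * D[, 1] * D[, 2]
  }
  set.seed(seed)
  D <- matrix(stats::runif(n * descriptorDim, 0, 10), nrow = n)
  colnames(D) <- paste0("d", seq_len(descriptorDim))
  ccsTrue <- generativeFunction(D)
  ccs <- ccsTrue + stats::rnorm(n, 0, noiseSd)
  out <- data.frame(id = seq_len(n), adduct = adduct, ccs = ccs, D)
  attr(out, "truth") <- list(f = generativeFunction, ccsTrue = ccsTrue,
                             noiseSd = noiseSd, seed = seed)
  out
}
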