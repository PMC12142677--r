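## MSI feature-table processing: cross-run alignment, background removal,
## isotope flagging, charge-state linking, spatial correlation, and
## differential group statistics.

#' Align features across imaging runs
#'
#' Greedy centroid clustering: features are pooled over runs, visited in
#' descending intensity (ties broken by ascending m/z), and each joins the
#' nearest existing cluster whose intensity-weighted centroid lies within both
#' the m/z and the drift tolerance, or founds a new cluster.
#'
#' @param runs List of data frames with columns `mz`, `drift` (bins) and
#'   `intensity`; one element per run.
#' @param mzTol m/z tolerance in Da (default 0.03).
#' @param driftTol Drift tolerance in bins (default 2).
#' @return Data frame with one row per cluster: `feature`, centroid `mz` and
#'   `drift`, `intensity` (summed), `nMembers`, and one mean-intensity column
#'   per run (`run1`, `run2`, ... or the list's names).  The pooled per-feature
#'   assignment is attached as attribute `"assignments"`.
#' @export
alignFeatures <- function(runs, mzTol = 0.03, driftTol = 2) {
  stopifnot(is.list(runs), length(runs) >= 1)
  runNames <- names(runs)
  if (is.null(runNames)) runNames <- paste0("run", seq_along(runs))
  pooled <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    data.frame(run = runNames[i], mz = r$mz, drift = r$drift,
               intensity = r$intensity)
  }))
  ord <- order(-pooled$intensity, pooled$mz)
  pooled <- pooled[ord, , drop = FALSE]

  nMax <- nrow(pooled)
  cMz <- cDrift <- cInt <- numeric(nMax)
  nClust <- 0L
  assign <- integer(nMax)
  for (i in seq_len(nMax)) {
    if (nClust > 0L) {
      idx <- seq_len(nClust)
      ok <- abs(cMz[idx] - pooled$mz[i]) <= mzTol &
            abs(cDrift[idx] - pooled$drift[i]) <= driftTol
      hit <- which(ok)
    } else hit <- integer(0)
    if (length(hit)) {
      j <- hit[which.min(abs(cMz[hit] - pooled$mz[i]))]
      w <- pooled$intensity[i]
      tot <- cInt[j] + w
      cMz[j] <- (cMz[j] * cInt[j] + pooled$mz[i] * w) / tot
      cDrift[j] <- (cDrift[j] * cInt[j] + pooled$drift[i] * w) / tot
      cInt[j] <- tot
    } else {
      nClust <- nClust + 1L
      j <- nClust
      cMz[j] <- pooled$mz[i]; cDrift[j] <- pooled$drift[i]
      cInt[j] <- pooled$intensity[i]
    }
    assign[i] <- j
  }
  pooled$feature <- assign
  out <- data.frame(feature = seq_len(nClust),
                    mz = cMz[seq_len(nClust)], drift = cDrift[seq_len(nClust)],
                    intensity = cInt[seq_len(nClust)],
                    nMembers = as.integer(table(factor(assign, seq_len(nClust)))))
  for (rn in runNames) {
    sub <- pooled[pooled$run == rn, ]
    m <- tapply(sub$intensity, factor(sub$feature, seq_len(nClust)), mean)
    out[[rn]] <- as.numeric(m)
  }
  attr(out, "assignments") <- pooled
  out
}

#' Remove background features by exclusion list
#'
#' Flags features whose m/z matches a user-supplied exclusion list within a
#' ppm tolerance (the list-based analogue of manual background removal).
#'
#' @param table Aligned feature table with an `mz` column.
#' @param exclusionMz Numeric vector of background m/z values.
#' @param ppmTol Tolerance in ppm (default 10).
#' @param drop If `TRUE` (default) remove flagged rows; otherwise keep them
#'   with `flag = "background"`.
#' @return The filtered (or flagged) table.
#' @export
removeBackground <- function(table, exclusionMz, ppmTol = 10, drop = TRUE) {
  if (!length(exclusionMz)) {
    if (!drop) table$flag <- "analyte"
    return(table)
  }
  isBg <- vapply(table$mz, function(m) {
    any(abs(ppmError(m, exclusionMz)) <= ppmTol)
  }, logical(1))
  if (drop) {
    table[!isBg, , drop = FALSE]
  } else {
    table$flag <- ifelse(isBg, "background", "analyte")
    table
  }
}

#' Flag isotopic features
#'
#' A feature B is flagged as the first isotopologue of a more intense feature
#' A when its m/z matches `isotopeMz(mz_A, z, 1)` within `ppmTol`, its drift
#' lies within `driftTol` bins of A's, and the intensity ratio B/A falls in
#' `ratioBounds`.  Chains are limited to `maxDepth` (an isotope's isotope is
#' never a parent at depth > 2), keeping the flags acyclic.
#'
#' @param table Aligned feature table with `mz`, `drift`, `intensity` and
#'   optionally `z` (charge, default 1).
#' @param driftTol Drift tolerance in bins (default 2).
#' @param ratioBounds Length-2 numeric, admissible B/A intensity ratio
#'   (default `c(0.01, 1)`).
#' @param ppmTol m/z tolerance in ppm (default 10).
#' @param maxDepth Maximum isotope chain depth (default 2).
#' @return The table with columns `flag` (`"analyte"` or `"isotope"`) and
#'   `parent` (row feature id of the parent, `NA` for analytes).
#' @export
flagIsotopes <- function(table, driftTol = 2, ratioBounds = c(0.01, 1),
                         ppmTol = 10, maxDepth = 2) {
  n <- nrow(table)
  z <- if ("z" %in% names(table)) table$z else rep(1L, n)
  flag <- rep("analyte", n)
  parent <- rep(NA_integer_, n)
  depth <- integer(n)
  ord <- order(-table$intensity, table$mz)
  for (a in ord) {
    if (depth[a] >= maxDepth) next
    expected <- isotopeMz(table$mz[a], z[a], 1L)
    cand <- which(flag == "analyte" &
                  seq_len(n) != a &
                  abs(ppmError(table$mz, expected)) <= ppmTol &
                  abs(table$drift - table$drift[a]) <= driftTol &
                  table$intensity / table$intensity[a] >= ratioBounds[1] &
                  table$intensity / table$intensity[a] <= ratioBounds[2])
    if (length(cand)) {
      b <- cand[which.min(abs(table$mz[cand] - expected))]
      flag[b] <- "isotope"
      parent[b] <- if ("feature" %in% names(table)) table$feature[a] else a
      depth[b] <- depth[a] + 1L
    }
  }
  table$flag <- flag
  table$parent <- parent
  table
}

#' Test whether two features are charge states of one species
#'
#' Checks whether the lower-m/z feature is the doubly protonated form of the
#' singly charged (or pre-charged) feature: true when the observed m/z of the
#' doubly charged ion matches `(mz1 + m_H) / 2` within `ppmTol`.
#'
#' @param mz1 m/z of the singly charged feature (larger).
#' @param mz2 m/z of the putative doubly charged feature (smaller).
#' @param ppmTol Tolerance in ppm (default 5).
#' @return List with `linked` (logical) and `residualPpm`.
#' @export
#' @examples
#' linkMultiplyCharged(529.3989, 265.2030)
linkMultiplyCharged <- function(mz1, mz2, ppmTol = 5) {
  stopifnot(mz1 > mz2)
  expected <- (mz1 + .MASS_PROTON_H) / 2
  res <- ppmError(mz2, expected)
  list(linked = abs(res) <= ppmTol, residualPpm = res)
}

#' Pearson correlation of two ion images
#'
#' @param image1,image2 Numeric matrices (or vectors) on identical pixel
#'   grids; at least 2 pixels, neither constant.
#' @return Pearson correlation coefficient.
#' @export
spatialCorrelation <- function(image1, image2) {
  x <- as.numeric(image1); y <- as.numeric(image2)
  if (length(x) != length(y)) stop("images have different pixel grids")
  if (length(x) < 2) stop("need at least 2 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant image")
  stats::cor(x, y)
}

#' Differential filtering by fold change and p-value
#'
#' Per feature: fold change FC = mean(control) / mean(tumor) and a two-sided
#' Welch t-test on per-sample intensity summaries.  Features are kept when
#' `FC >= fcThreshold` or `FC <= 1/fcThreshold`, and `p <= pThreshold`.  No
#' multiple-testing correction is applied by default; `pAdjustMethod` enables
#' one.
#'
#' MS intensity noise is multiplicative, so by default the t-test is computed
#' on log-transformed intensities, where the sampling distribution is close
#' to normal and the test holds its nominal level at small n; the fold change
#' is always reported on the raw means.  Set `logTransform = FALSE` to test
#' raw intensities.
#'
#' @param table Feature table with one intensity column per sample.
#' @param groups Named character vector mapping sample column names to
#'   `"control"` or `"tumor"` (any two labels; the first level is the FC
#'   numerator).
#' @param fcThreshold Fold-change cutoff (default 1.5).
#' @param pThreshold p-value cutoff (default 0.1).
#' @param pAdjustMethod `"none"` (default) or any [stats::p.adjust()] method.
#' @param logTransform Test log intensities (default `TRUE`).
#' @return List with `stats` (per-feature `fc`, `p`, group means and sizes,
#'   `kept`) and `kept` (the subset of `table` passing both cutoffs).
#' @export
differentialFilter <- function(table, groups, fcThreshold = 1.5,
                               pThreshold = 0.1, pAdjustMethod = "none",
                               logTransform = TRUE) {
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  g1 <- names(groups)[groups == lv[1]]
  g2 <- names(groups)[groups == lv[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs >= 2 samples")
  missing <- setdiff(c(g1, g2), names(table))
  if (length(missing)) stop("sample columns missing: ", paste(missing, collapse = ", "))
  X1 <- as.matrix(table[g1]); X2 <- as.matrix(table[g2])
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  T1 <- if (logTransform) log(X1) else X1
  T2 <- if (logTransform) log(X2) else X2
  p <- vapply(seq_len(nrow(table)), function(i) {
    stats::t.test(T1[i, ], T2[i, ], var.equal = FALSE)$p.value
  }, numeric(1))
  p <- stats::p.adjust(p, method = pAdjustMethod)
  fc <- m1 / m2
  keep <- (fc >= fcThreshold | fc <= 1 / fcThreshold) & p <= pThreshold
  stats <- data.frame(fc = fc, p = p, mean1 = m1, mean2 = m2,
                      n1 = length(g1), n2 = length(g2), kept = keep)
  if ("feature" %in% names(table)) stats <- cbind(feature = table$feature, stats)
  list(stats = stats, kept = table[keep, , drop = FALSE])
}

#' Volcano-plot coordinates and significance classes
#'
#' @param stats Data frame with `fc` and `p` columns (as from
#'   [differentialFilter()]'s `stats`).
#' @param pCut p-value cutoff (default 0.05).
#' @param fcCut Fold-change cutoff (default 2); FC is oriented
#'   numerator-group / denominator-group, so `"up"` means up in the numerator
#'   group.
#' @return Data frame with `log2Fc`, `negLog10P` and `class` in
#'   `{"up", "down", "ns"}`.
#' @export
volcanoData <- function(stats, pCut = 0.05, fcCut = 2) {
  cls <- rep("ns", nrow(stats))
  cls[stats$p <= pCut & stats$fc >= fcCut] <- "up"
  cls[stats$p <= pCut & stats$fc <= 1 / fcCut] <- "down"
  data.frame(log2Fc = log2(stats$fc), negLog10P = -log10(stats$p),
             class = cls)
}
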