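## Annotation engine: m/z database matching, CCS-based isobar adjudication,
## candidate-list ingestion, threshold filtering and sum-composition checks.

#' Match a measured m/z against a compound database
#'
#' Computes adduct m/z values for every database entry and returns the matches
#' within tolerance, sorted by absolute error.  Tolerance bounds are inclusive.
#'
#' @param mz Measured m/z.
#' @param database Data frame with columns `name`, `formula`, and optionally
#'   `mass` (recomputed from `formula` when absent) and `class`.
#' @param adducts Adduct labels to search (default the positive-mode panel
#'   `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+2H]2+`).
#' @param tol Tolerance value: Da when `tolMode = "da"` (default 0.005), ppm
#'   when `tolMode = "ppm"` (default 5).
#' @param tolMode `"da"` or `"ppm"`.
#' @return Data frame of matches: `name`, `formula`, `adduct`,
#'   `theoreticalMz`, `errorDa`, `errorPpm` (zero rows if none).
#' @export
dbMatch <- function(mz, database,
                    adducts = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+2H]2+"),
                    tol = if (tolMode == "da") 0.005 else 5,
                    tolMode = c("da", "ppm")) {
  tolMode <- match.arg(tolMode)
  if (!nrow(database)) stop("empty database")
  mass <- if ("mass" %in% names(database)) database$mass else
    vapply(database$formula, monoisotopicMass, numeric(1))
  hits <- do.call(rbind, lapply(adducts, function(ad) {
    theo <- adductMz(mass, ad)
    errDa <- mz - theo
    errPpm <- ppmError(mz, theo)
    ok <- if (tolMode == "da") abs(errDa) <= tol else abs(errPpm) <= tol
    if (!any(ok)) return(NULL)
    data.frame(name = database$name[ok], formula = database$formula[ok],
               adduct = ad, theoreticalMz = theo[ok],
               errorDa = errDa[ok], errorPpm = errPpm[ok])
  }))
  if (is.null(hits)) {
    hits <- data.frame(name = character(0), formula = character(0),
                       adduct = character(0), theoreticalMz = numeric(0),
                       errorDa = numeric(0), errorPpm = numeric(0))
  }
  err <- if (tolMode == "da") hits$errorDa else hits$errorPpm
  hits <- hits[order(abs(err)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Adjudicate isobaric candidates by CCS agreement
#'
#' Ranks candidates by the absolute percent difference between their predicted
#' CCS and the experimental CCS; the smallest wins.  When the top two are
#' within `tieWindow` percentage points of each other the call is ambiguous
#' and no winner is declared.
#'
#' @param experimentalCcs Experimental CCS in squared Angstrom.
#' @param candidates Data frame with a `predictedCcs` column (and any id
#'   columns); or a `percentDiff` column used directly.
#' @param tieWindow Tie threshold in percentage points (default 0.05).
#' @return List with `ranked` (candidates plus `percentDiff`, sorted by
#'   absolute difference), `winner` (row of `ranked`, or `NULL`), and
#'   `ambiguous` (logical).
#' @export
adjudicateIsobars <- function(experimentalCcs, candidates, tieWindow = 0.05) {
  if (nrow(candidates) < 2) stop("need at least 2 candidates to adjudicate")
  if (!"percentDiff" %in% names(candidates)) {
    if (!"predictedCcs" %in% names(candidates)) {
      stop("candidates carry neither percentDiff nor predictedCcs")
    }
    candidates$percentDiff <-
      percentDifference(candidates$predictedCcs, experimentalCcs)
  }
  ranked <- candidates[order(abs(candidates$percentDiff)), , drop = FALSE]
  rownames(ranked) <- NULL
  gap <- abs(ranked$percentDiff[2]) - abs(ranked$percentDiff[1])
  ambiguous <- gap <= tieWindow
  list(ranked = ranked,
       winner = if (ambiguous) NULL else ranked[1, , drop = FALSE],
       ambiguous = ambiguous)
}

#' Filter candidates by a CCS percent-difference threshold
#'
#' Removes candidates whose absolute percent difference between predicted and
#' experimental CCS exceeds the threshold; the rest are kept.
#'
#' @param candidates Data frame with a `percentDiff` column (signed percent).
#' @param threshold Threshold in percent (default 1.0).
#' @return List with `kept`, `removed` (disjoint subsets whose union is the
#'   input) and `counts` (`total`, `kept`, `removed`).
#' @export
#' @examples
#' filterCandidates(data.frame(percentDiff = c(0.4, -0.5, 2.4, 3.1)))
filterCandidates <- function(candidates, threshold = 1.0) {
  if (!nrow(candidates)) {
    return(list(kept = candidates, removed = candidates,
                counts = c(total = 0L, kept = 0L, removed = 0L)))
  }
  out <- abs(candidates$percentDiff) > threshold
  kept <- candidates[!out, , drop = FALSE]
  removed <- candidates[out, , drop = FALSE]
  if ("disposition" %in% names(candidates) || TRUE) {
    kept$disposition <- if (nrow(kept)) "kept" else character(0)
    removed$disposition <- if (nrow(removed)) "removed" else character(0)
  }
  list(kept = kept, removed = removed,
       counts = c(total = nrow(candidates), kept = nrow(kept),
                  removed = nrow(removed)))
}

#' Check a candidate against the putative sum composition
#'
#' True when the candidate's elemental formula equals the database entry's
#' formula and the adducts agree: the same molecular formula under a different
#' adduct is a mismatch.
#'
#' @param candidateFormula,putativeFormula Formulas (strings or
#'   `ElementalFormula`).
#' @param candidateAdduct,putativeAdduct Adduct labels.
#' @return Logical.
#' @export
#' @examples
#' sumCompositionCheck("C39H76NO8P", "[M+H]+", "C39H76NO8P", "[M+K]+")
sumCompositionCheck <- function(candidateFormula, candidateAdduct,
                                putativeFormula, putativeAdduct) {
  fa <- .asFormula(candidateFormula); fb <- .asFormula(putativeFormula)
  ea <- union(names(fa), names(fb))
  ca <- stats::setNames(integer(length(ea)), ea)
  cb <- ca
  ca[names(fa)] <- unclass(fa); cb[names(fb)] <- unclass(fb)
  identical(ca, cb) && identical(candidateAdduct, putativeAdduct)
}

#' Read a candidate list from a delimited file
#'
#' Reads structure-summary style exports: required columns `rank`,
#' `structure`, `formula`, `adduct`, `source`; candidates are rank-ordered and
#' truncated to the top `topK`.  Rows with unparseable structures are skipped
#' with a warning when `validateStructures = TRUE`.
#'
#' @param file Path to a comma-delimited file with a header row.
#' @param topK Keep the `topK` best-ranked candidates (default 20).
#' @param validateStructures Parse each structure and drop failures
#'   (default `FALSE`; requires the chemistry backend).
#' @return Data frame of candidates ordered by rank.
#' @export
ingestCandidates <- function(file, topK = 20, validateStructures = FALSE) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("rank", "structure", "formula", "adduct", "source")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("candidate file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$rank)) stop("duplicate ranks in candidate file")
  if (!all(tab$source %in% c("database", "de novo"))) {
    stop("source must be 'database' or 'de novo'")
  }
  tab <- tab[order(tab$rank), , drop = FALSE]
  if (validateStructures) {
    ok <- vapply(tab$structure, function(s) {
      !inherits(tryCatch(featurize(s), error = function(e) e), "error")
    }, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " candidate structure(s) unparseable; skipped")
      tab <- tab[ok, , drop = FALSE]
    }
  }
  utils::head(tab, topK)
}

#' Annotate one feature end to end
#'
#' Composes database matching, CCS prediction, percent-difference computation,
#' threshold filtering, isobar adjudication and sum-composition checking into
#' a single report.
#'
#' @param mz Measured m/z of the feature.
#' @param experimentalCcs Experimental CCS (squared Angstrom).
#' @param database Compound database (see [dbMatch()]).
#' @param candidates Candidate data frame (see [ingestCandidates()]); may
#'   already carry a `predictedCcs` column, otherwise `predictor` is used.
#' @param predictor Optional `CcsPredictor` used to predict candidate CCS from
#'   structures.
#' @param threshold CCS percent-difference threshold (default 1.0).
#' @param adducts,tol,tolMode Passed to [dbMatch()].
#' @return List of class `AnnotationReport`: `mz`, `experimentalCcs`,
#'   `putativeMatches`, `candidates` (with `percentDiff`,
#'   `sumCompositionMatch`, `disposition`), `bestIsobar`, `counts`, `status`
#'   (`"annotated"` or `"unknown"`).
#' @export
annotateFeature <- function(mz, experimentalCcs, database,
                            candidates = NULL, predictor = NULL,
                            threshold = 1.0,
                            adducts = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+2H]2+"),
                            tol = 5, tolMode = "ppm") {
  matches <- dbMatch(mz, database, adducts = adducts, tol = tol, tolMode = tolMode)

  cand <- candidates
  if (!is.null(cand) && nrow(cand)) {
    if (!"predictedCcs" %in% names(cand)) {
      if (is.null(predictor)) stop("candidates lack predictedCcs and no predictor given")
      cand$predictedCcs <- predict(predictor, cand$structure)
    }
    cand$percentDiff <- percentDifference(cand$predictedCcs, experimentalCcs)
    if (nrow(matches) && all(c("formula", "adduct") %in% names(cand))) {
      top <- matches[1, ]
      cand$sumCompositionMatch <- mapply(sumCompositionCheck,
                                         cand$formula, cand$adduct,
                                         MoreArgs = list(putativeFormula = top$formula,
                                                         putativeAdduct = top$adduct))
    }
    filt <- filterCandidates(cand, threshold)
    cand <- rbind(filt$kept, filt$removed)
    cand <- cand[order(cand$rank), , drop = FALSE]
    counts <- filt$counts
  } else {
    counts <- c(total = 0L, kept = 0L, removed = 0L)
  }

  best <- NULL
  if (nrow(matches) >= 2 && !is.null(cand) && nrow(cand) >= 2) {
    adj <- adjudicateIsobars(experimentalCcs, cand)
    best <- adj$winner
  }

  status <- if (nrow(matches) || (!is.null(cand) && any(cand$disposition == "kept")))
    "annotated" else "unknown"
  structure(list(mz = mz, experimentalCcs = experimentalCcs,
                 putativeMatches = matches, candidates = cand,
                 bestIsobar = best, counts = counts, status = status),
            class = "AnnotationReport")
}

#' @export
print.AnnotationReport <- function(x, ...) {
  cat("AnnotationReport for m/z", format(round(x$mz, 4), nsmall = 4),
      "(CCS", round(x$experimentalCcs, 1), "A^2):", x$status, "\n")
  cat("  putative database matches:", nrow(x$putativeMatches), "\n")
  cat("  candidates:", x$counts["total"], "(kept", x$counts["kept"],
      ", removed", x$counts["removed"], ")\n")
  invisible(x)
}
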