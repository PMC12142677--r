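## Machine-learning CCS prediction from molecular structure.
##
## One support-vector regression model per adduct, trained on scaled 2-D
## molecular descriptors with a 70/30 train/validation split.  Descriptors are
## computed with OpenBabel (through ChemmineOB) so that any valid SMILES or
## InChI encoding of the same structure yields the same vector.

setClass("CcsPredictor", representation(
  adduct = "character",
  svm = "ANY",
  center = "numeric",
  scale = "numeric",
  descriptorNames = "character",
  metrics = "list",
  seed = "numeric",
  trainIndex = "integer",
  validationIndex = "integer"
))

setMethod("show", "CcsPredictor", function(object) {
  cat("CcsPredictor for adduct ", object@adduct, "\n",
      "  ", length(object@trainIndex), " training / ",
      length(object@validationIndex), " validation records, ",
      length(object@descriptorNames), " descriptors\n",
      "  validation median |rel. error|: ",
      signif(object@metrics$medianRelErrPct, 4), "%   RMSE: ",
      signif(object@metrics$rmse, 5), " A^2\n", sep = "")
})

#' Validation metrics of a CCS predictor
#' @param object A `CcsPredictor`.
#' @return List with `medianRelErrPct` and `rmse`, both computed on the
#'   held-out validation split only.
#' @export
setGeneric("validationMetrics", function(object) standardGeneric("validationMetrics"))
#' @rdname validationMetrics
setMethod("validationMetrics", "CcsPredictor", function(object) object@metrics)

.isInchi <- function(x) grepl("^InChI=", x)

.toSmiles <- function(structure) {
  if (.isInchi(structure)) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop("InChI input requires the ChemmineOB package")
    }
    structure <- ChemmineOB::convertFormat("INCHI", "SMI", structure)
    structure <- sub("[[:space:]].*$", "", structure)
  }
  structure
}

#' Molecular descriptors from a structure string
#'
#' Parses a SMILES or InChI string, canonicalizes it, and computes a fixed
#' panel of 2-D descriptors: molecular weight, logP, topological polar surface
#' area, molar refractivity, hydrogen-bond acceptor/donor counts, fluorine
#' count, and heavy-element counts (C, H, N, O, P, S) from the molecular
#' formula.  Equivalent encodings of one structure give identical vectors.
#'
#' @param structure SMILES or InChI string.
#' @return Named numeric descriptor vector with attributes `canonicalSmiles`
#'   and `formula`.
#' @export
#' @examples
#' \donttest{
#' identical(featurize("CCO"), featurize("OCC"))
#' }
featurize <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  smi <- .toSmiles(structure)
  # OpenBabel silently repairs unclosed branches; reject them up front
  chars <- strsplit(smi, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")") ||
      sum(chars == "[") != sum(chars == "]")) {
    stop("unparseable structure (unbalanced brackets): ", structure)
  }
  parse <- function(s) {
    props <- tryCatch(
      suppressWarnings(
        ChemmineOB::forEachMol("SMILES", s, ChemmineOB::prop_OB)[[1]]),
      error = function(e) stop("unparseable structure: ", structure))
    if (!is.data.frame(props) || !nrow(props) ||
        !is.finite(props$MW[1]) || props$MW[1] <= 0) {
      stop("unparseable structure: ", structure)
    }
    props
  }
  # descriptors are computed on the canonical SMILES so that every encoding
  # of one structure yields a bit-identical vector
  props <- parse(smi)
  if (!identical(props$cansmi[1], smi)) props <- parse(props$cansmi[1])
  f <- parseFormula(props$formula[1])
  cnt <- function(el) if (el %in% names(f)) as.numeric(f[[el]]) else 0
  v <- c(MW = props$MW[1], logP = props$logP[1], TPSA = props$TPSA[1],
         MR = props$MR[1], HBA1 = props$HBA1[1], HBA2 = props$HBA2[1],
         HBD = props$HBD[1], nF = props$nF[1],
         nC = cnt("C"), nH = cnt("H"), nN = cnt("N"), nO = cnt("O"),
         nP = cnt("P"), nS = cnt("S"))
  attr(v, "canonicalSmiles") <- props$cansmi[1]
  attr(v, "formula") <- props$formula[1]
  v
}

#' @rdname featurize
#' @param structures Character vector of structure strings.
#' @return `featurizeAll()`: a numeric matrix, one row per structure.
#' @export
featurizeAll <- function(structures) {
  rows <- lapply(structures, featurize)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(structures)
  mat
}

.descriptorMatrix <- function(data) {
  if ("structure" %in% names(data)) {
    featurizeAll(data$structure)
  } else {
    num <- setdiff(names(data), c("id", "adduct", "ccs", "structure"))
    num <- num[vapply(data[num], is.numeric, logical(1))]
    if (!length(num)) stop("no descriptor columns found")
    as.matrix(data[num])
  }
}

#' Train a per-adduct CCS predictor
#'
#' Fits an epsilon-SVR with radial-basis kernel on scaled molecular
#' descriptors.  Records are split 70/30 into training and validation
#' (`ceiling(trainFraction * n)` training rows); descriptors are standardized
#' with training-fold statistics; hyperparameters (cost, gamma, epsilon) are
#' chosen by 5-fold cross-validation on the training fold only; validation
#' metrics are computed on the held-out rows.
#'
#' @param data Data frame with a `ccs` column and either a `structure` column
#'   (SMILES/InChI, featurized internally) or numeric descriptor columns;
#'   an optional `adduct` column restricts training to one adduct.
#' @param adduct Adduct label the model is trained for.
#' @param trainFraction Fraction of records used for training (default 0.70).
#' @param seed Integer seed controlling the split and cross-validation folds.
#' @param tuneGrid List with vectors `cost`, `gamma`, `epsilon`; `gamma` is
#'   relative to `1/ncol(descriptors)`.
#' @return A `CcsPredictor`.
#' @export
trainCcsPredictor <- function(data, adduct = "[M+H]+", trainFraction = 0.70,
                              seed = 1L,
                              tuneGrid = list(cost = c(1, 10, 100, 1000),
                                              gamma = c(0.5, 1, 2),
                                              epsilon = c(0.001, 0.01, 0.1))) {
  if ("adduct" %in% names(data)) data <- data[data$adduct == adduct, , drop = FALSE]
  n <- nrow(data)
  if (n < 20) stop("need at least 20 records for adduct ", adduct, ", got ", n)
  if (length(unique(data$ccs)) < 2) stop("CCS values are single-valued")
  X <- .descriptorMatrix(data)
  y <- data$ccs

  set.seed(seed)
  nTrain <- ceiling(trainFraction * n)
  trainIdx <- sort(sample.int(n, nTrain))
  valIdx <- setdiff(seq_len(n), trainIdx)

  keep <- apply(X[trainIdx, , drop = FALSE], 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X[trainIdx, , drop = FALSE])
  scl <- apply(X[trainIdx, , drop = FALSE], 2, stats::sd)
  Xs <- scale(X, center = ctr, scale = scl)

  d <- ncol(Xs)
  tuned <- e1071::tune.svm(
    x = Xs[trainIdx, , drop = FALSE], y = y[trainIdx],
    type = "eps-regression", kernel = "radial", scale = FALSE,
    cost = tuneGrid$cost, gamma = tuneGrid$gamma / d,
    epsilon = tuneGrid$epsilon,
    tunecontrol = e1071::tune.control(cross = 5))
  model <- tuned$best.model

  predVal <- stats::predict(model, Xs[valIdx, , drop = FALSE])
  relErr <- abs(predVal - y[valIdx]) / y[valIdx] * 100
  metrics <- list(medianRelErrPct = stats::median(relErr),
                  rmse = sqrt(mean((predVal - y[valIdx])^2)),
                  best = tuned$best.parameters)

  new("CcsPredictor", adduct = adduct, svm = model,
      center = ctr, scale = scl, descriptorNames = colnames(X),
      metrics = metrics, seed = as.numeric(seed),
      trainIndex = as.integer(trainIdx), validationIndex = as.integer(valIdx))
}

#' Predict CCS values
#'
#' @param object A `CcsPredictor`.
#' @param newdata Character vector of structures (featurized internally) or a
#'   numeric descriptor matrix/data frame with the training columns.
#' @param adduct Adduct of the query ions; a mismatch with the model's adduct
#'   raises a warning (the prediction proceeds with the model as-is).
#' @param ... Unused.
#' @return Numeric vector of predicted CCS values (squared Angstrom).
#' @export
setMethod("predict", "CcsPredictor", function(object, newdata, adduct = NULL, ...) {
  if (!is.null(adduct) && !identical(adduct, object@adduct)) {
    warning("model trained for ", object@adduct, " applied to ", adduct,
            " ions; prediction is unshifted")
  }
  X <- if (is.character(newdata)) {
    featurizeAll(newdata)[, object@descriptorNames, drop = FALSE]
  } else {
    df <- as.data.frame(newdata)
    missing <- setdiff(object@descriptorNames, names(df))
    if (length(missing)) {
      stop("newdata lacks descriptor column(s): ", paste(missing, collapse = ", "))
    }
    as.matrix(df[object@descriptorNames])
  }
  Xs <- scale(X, center = object@center, scale = object@scale)
  unname(stats::predict(object@svm, Xs))
})

#' Percent difference between predicted and experimental CCS
#'
#' `(predicted - experimental) / experimental * 100`, signed by default; the
#' absolute value is what threshold filtering compares.
#'
#' @param predicted,experimental CCS values; `experimental > 0`.
#' @param signed If `FALSE`, return absolute percent difference.
#' @return Percent difference.
#' @export
#' @examples
#' percentDifference(202, 200)
percentDifference <- function(predicted, experimental, signed = TRUE) {
  stopifnot(all(experimental > 0))
  d <- (predicted - experimental) / experimental * 100
  if (signed) d else abs(d)
}
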