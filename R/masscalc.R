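## Exact-mass and m/z arithmetic for ion-mobility annotation workflows.
##
## All mass arithmetic is neutral-atom based: adduct m/z values are computed by
## adding monoisotopic neutral-atom masses (H, Na, K, ...) and dividing by the
## charge, with no electron-mass correction.  This is the convention used by the
## instrument software this package interoperates with; a proton-mass mode
## (subtracting z electron masses) is available via `electronCorrection = TRUE`
## for data processed under the physically strict convention.

# cached atomic-mass environment, filled lazily from inst/extdata
.cimccs_masses <- new.env(parent = emptyenv())

#' Monoisotopic atomic mass table
#'
#' Returns the packaged table of monoisotopic atomic masses (Da) used by all
#' mass arithmetic in the package.
#'
#' @return Named numeric vector of monoisotopic masses, named by element symbol.
#' @export
#' @examples
#' atomicMasses()[c("C", "H", "O")]
atomicMasses <- function() {
  if (is.null(.cimccs_masses$table)) {
    path <- system.file("extdata", "monoisotopic_masses.csv", package = "cimCCS")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    masses <- stats::setNames(tab$mass, tab$element)
    .cimccs_masses$table <- masses
  }
  .cimccs_masses$table
}

## constants used throughout
.MASS_PROTON_H <- 1.00782503207  # neutral H atom, Da
.MASS_ELECTRON <- 0.00054857990  # Da
.MASS_C13_C12  <- 1.003355       # 13C - 12C spacing, Da

#' Parse a Hill-notation elemental formula
#'
#' Parses strings such as `"C32H53N2O4"` into a named integer vector of element
#' counts.  Element symbols must be present in [atomicMasses()].
#'
#' @param x Character scalar, Hill-notation formula. An empty string is the
#'   empty formula.
#' @return Named integer vector of element counts (class `ElementalFormula`).
#' @export
#' @examples
#' parseFormula("C28H37N5O7")
parseFormula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("[[:space:]]", "", x)
  counts <- integer(0)
  if (nzchar(x)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    pieces <- regmatches(x, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x)) {
      stop("cannot parse formula: ", x)
    }
    elems <- sub("[0-9]*$", "", pieces)
    nums <- sub("^[A-Za-z]+", "", pieces)
    n <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
    unknown <- setdiff(elems, names(atomicMasses()))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    counts <- tapply(n, factor(elems, levels = unique(elems)), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  structure(counts, class = "ElementalFormula")
}

#' @export
format.ElementalFormula <- function(x, ...) {
  if (!length(x)) return("(empty)")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.ElementalFormula <- function(x, ...) {
  cat("ElementalFormula:", format(x), "\n")
  invisible(x)
}

.asFormula <- function(x) {
  if (inherits(x, "ElementalFormula")) x else parseFormula(x)
}

#' Add or subtract elemental formulas
#'
#' Element-wise addition and subtraction of formulas.  Subtraction errors if any
#' element count would become negative.
#'
#' @param a,b Formulas (strings or `ElementalFormula`).
#' @return An `ElementalFormula`.
#' @export
#' @examples
#' formulaAdd("C2H4", "H2O")
#' formulaSubtract("C32H53N2O4", "C3H6")  # propene loss
formulaAdd <- function(a, b) {
  a <- .asFormula(a); b <- .asFormula(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  structure(out[out > 0L], class = "ElementalFormula")
}

#' @rdname formulaAdd
#' @export
formulaSubtract <- function(a, b) {
  a <- .asFormula(a); b <- .asFormula(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0L)) {
    stop("formula subtraction would give negative counts for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  }
  structure(out[out > 0L], class = "ElementalFormula")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of per-atom monoisotopic masses; no electron-mass correction.
#'
#' @param formula A Hill-notation string or `ElementalFormula`.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopicMass("H2O")
#' monoisotopicMass("C32H53N2O4")  # rocuronium cation composition
monoisotopicMass <- function(formula) {
  f <- .asFormula(formula)
  if (!length(f)) return(0)
  sum(atomicMasses()[names(f)] * unclass(f))
}

## supported adducts: number of H/Na/K atoms added and implied charge
.ADDUCTS <- list(
  "[M+H]+"   = list(add = c(H = 1L),  z = 1L),
  "[M+Na]+"  = list(add = c(Na = 1L), z = 1L),
  "[M+K]+"   = list(add = c(K = 1L),  z = 1L),
  "[M+2H]2+" = list(add = c(H = 2L),  z = 2L),
  "[M]+"     = list(add = c(),        z = 1L),
  "[M+H]2+"  = list(add = c(H = 1L),  z = 2L)  # pre-charged cation + H
)

#' Supported adduct labels
#' @return Character vector of adduct labels, e.g. `"[M+H]+"`.
#' @export
supportedAdducts <- function() names(.ADDUCTS)

#' Implied charge of an adduct
#' @param adduct Adduct label (see [supportedAdducts()]).
#' @return Integer charge.
#' @export
adductCharge <- function(adduct) {
  spec <- .ADDUCTS[[adduct]]
  if (is.null(spec)) stop("unsupported adduct: ", adduct)
  spec$z
}

#' Adduct m/z from a neutral (or pre-charged cation) mass
#'
#' Computes m/z by adding neutral-atom masses of the adducting atoms and
#' dividing by the implied charge.  For `"[M]+"` the mass is returned unchanged
#' (pre-charged cation, e.g. a quaternary ammonium).  With
#' `electronCorrection = TRUE`, z electron masses are subtracted, giving the
#' physically strict cation m/z.
#'
#' @param mass Monoisotopic mass in Da of the neutral molecule, or of the
#'   cation itself for `"[M]+"` / `"[M+H]2+"`.
#' @param adduct Adduct label, one of [supportedAdducts()].
#' @param electronCorrection Logical; default `FALSE` (neutral-atom
#'   convention).
#' @return m/z in Thomson.
#' @export
#' @examples
#' adductMz(monoisotopicMass("C28H37N5O7"), "[M+H]+")   # 556.2771 lock mass
adductMz <- function(mass, adduct, electronCorrection = FALSE) {
  stopifnot(is.numeric(mass), all(mass > 0))
  spec <- .ADDUCTS[[adduct]]
  if (is.null(spec)) stop("unsupported adduct: ", adduct)
  addmass <- if (length(spec$add)) sum(atomicMasses()[names(spec$add)] * spec$add) else 0
  mz <- (mass + addmass) / spec$z
  if (electronCorrection) mz <- mz - .MASS_ELECTRON
  mz
}

#' Parts-per-million mass error
#'
#' `(measured - theoretical) / theoretical * 1e6`.
#'
#' @param measured,theoretical m/z values in Thomson; `theoretical` must be
#'   positive.
#' @return Signed ppm error.
#' @export
#' @examples
#' ppmError(529.3989, adductMz(monoisotopicMass("C32H53N2O4"), "[M]+"))
ppmError <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  (measured - theoretical) / theoretical * 1e6
}

#' m/z of the k-th isotopologue
#'
#' Carbon-driven single-parameter approximation: the k-th isotope peak lies
#' `k * 1.003355 / z` above the monoisotopic m/z.
#'
#' @param mz Monoisotopic m/z.
#' @param z Charge (>= 1).
#' @param k Isotopologue index (>= 0).
#' @return m/z of the isotope peak.
#' @export
#' @examples
#' isotopeMz(265.2030, z = 2, k = 1)
isotopeMz <- function(mz, z, k = 1L) {
  stopifnot(all(z >= 1), all(k >= 0))
  mz + k * .MASS_C13_C12 / z
}

#' Infer charge state from isotope spacing
#'
#' The spacing between the monoisotopic peak and its first isotopologue is
#' `1.003355 / z`; the charge is the rounded reciprocal of the observed
#' spacing in those units.
#'
#' @param mzMono Monoisotopic m/z.
#' @param mzIso m/z of the first isotope peak (must exceed `mzMono`).
#' @param zMax Largest admissible charge (default 4).
#' @return List with `z` (integer) and `residual`, the difference between the
#'   observed and the ideal spacing for the inferred charge (Thomson).
#' @export
#' @examples
#' inferCharge(265.2030, 265.7046)  # doubly charged
inferCharge <- function(mzMono, mzIso, zMax = 4L) {
  stopifnot(mzIso > mzMono)
  spacing <- mzIso - mzMono
  z <- round(.MASS_C13_C12 / spacing)
  if (z < 1 || z > zMax) {
    stop("isotope spacing ", signif(spacing, 6), " implies charge ", z,
         " outside [1, ", zMax, "]")
  }
  list(z = as.integer(z), residual = spacing - .MASS_C13_C12 / z)
}

#' Reduced mass of an ion-gas pair
#'
#' `1/mu = 1/m_ion + 1/m_gas`.
#'
#' @param mIon,mGas Masses in Da, both positive.
#' @return Reduced mass mu in Da.
#' @export
#' @examples
#' reducedMass(529.4005, 28.00615)  # vs N2
reducedMass <- function(mIon, mGas) {
  stopifnot(all(mIon > 0), all(mGas > 0))
  1 / (1 / mIon + 1 / mGas)
}

#' Drift-gas definitions
#'
#' Nitrogen is the default drift gas, with its monoisotopic mass.  Use
#' `driftGas(mass, name)` for other gases or the average-mass convention.
#'
#' @param mass Gas mass in Da (> 0).
#' @param name Gas name.
#' @return List with `mass` and `name`.
#' @export
#' @examples
#' driftGas()  # N2, monoisotopic
driftGas <- function(mass = 28.00615, name = "N2") {
  stopifnot(is.numeric(mass), mass > 0)
  list(mass = mass, name = name)
}
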