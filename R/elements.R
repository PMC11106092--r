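#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd setNames rnorm rlnorm runif
#' @importFrom utils head read.delim write.table
NULL

## Monoisotopic masses and natural abundances, IUPAC 2013 representative
## values. Lightest isotope first; abundances sum to 1 per element.
.ELEMENT_ISOTOPES <- list(
  H = data.frame(mass = c(1.0078250319, 2.0141017779),
                 abundance = c(0.999885, 0.000115)),
  C = data.frame(mass = c(12.0000000, 13.0033548378),
                 abundance = c(0.9893, 0.0107)),
  N = data.frame(mass = c(14.0030740052, 15.0001088984),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = data.frame(mass = 30.97376151, abundance = 1.0)
)

.PROTON_MASS   <- 1.00727646
.HYDROGEN_MASS <- 1.0078250319

#' Element isotope table
#'
#' Returns the internal table of isotope masses (Da) and natural abundances
#' used for all monoisotopic-mass and fine-isotope-pattern computations.
#' Values are IUPAC 2013 representative abundances for H, C, N, O, S (P is
#' monoisotopic). Per element the isotopes are ordered lightest first and
#' abundances sum to 1.
#'
#' @return A named list of data frames with columns `mass` and `abundance`.
#' @export
#' @examples
#' elementIsotopes()$C
elementIsotopes <- function() .ELEMENT_ISOTOPES

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula string such as `"C12H20O10"` into a named
#' integer vector of element counts. A named numeric vector is passed through
#' (after validation), so all formula-consuming functions accept both forms.
#'
#' @param x A formula string (e.g. `"C6H12N2O"`) or a named integer vector.
#' @return Named integer vector of element counts (elements with count 0
#'   dropped).
#' @export
#' @examples
#' parseFormula("C12H20O10")
parseFormula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("numeric formula must be a named vector of element counts")
    counts <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(x)) return(setNames(integer(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(x))
      stop("cannot parse formula: '", x, "'")
    el <- sub("[0-9]*$", "", toks)
    n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
    n[is.na(n)] <- 1L
    counts <- tapply(n, el, sum)
    counts <- setNames(as.integer(counts), names(counts))
  }
  if (any(counts < 0)) stop("negative element count in formula")
  counts <- counts[counts != 0]
  unknown <- setdiff(names(counts), names(.ELEMENT_ISOTOPES))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  counts[order(names(counts))]
}

#' Add two molecular formulas
#'
#' @param a,b Formulas (strings or named count vectors).
#' @return Named integer vector, the element-wise sum.
#' @export
formulaAdd <- function(a, b) {
  a <- parseFormula(a); b <- parseFormula(b)
  el <- union(names(a), names(b))
  out <- setNames(integer(length(el)), el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out <- out[out != 0L]
  out[order(names(out))]
}

#' Subtract one molecular formula from another
#'
#' Errors if any element count would become negative.
#'
#' @param a,b Formulas (strings or named count vectors); computes `a - b`.
#' @return Named integer vector.
#' @export
formulaSubtract <- function(a, b) {
  a <- parseFormula(a); b <- parseFormula(b)
  el <- union(names(a), names(b))
  out <- setNames(integer(length(el)), el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L))
    stop("formula subtraction yields negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  out <- out[out != 0L]
  out[order(names(out))]
}

#' Render a formula as a string
#'
#' @param x A formula (named count vector or string).
#' @return Single string with explicit counts, elements in Hill-ish order
#'   (C, H, then alphabetical).
#' @export
formulaToString <- function(x) {
  x <- parseFormula(x)
  if (!length(x)) return("")
  ord <- c(intersect(c("C", "H"), names(x)),
           sort(setdiff(names(x), c("C", "H"))))
  paste0(ord, x[ord], collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the mass of the element's lightest
#' isotope.
#'
#' @param formula A formula (string or named count vector).
#' @return Mass in Da.
#' @export
#' @examples
#' monoMass("H2O")            # 18.010565
#' monoMass("C12H20O10")      # lactulosyllysine mass shift, 324.105647
monoMass <- function(formula) {
  f <- parseFormula(formula)
  if (!length(f)) return(0)
  masses <- vapply(names(f), function(e) .ELEMENT_ISOTOPES[[e]]$mass[1L],
                   numeric(1))
  sum(f * masses)
}

#' m/z of an ion from its neutral mass
#'
#' Computes `(neutral_mass + charge * adduct_mass) / charge`. The default
#' adduct is a proton (1.00727646 Da); `"hydrogen"` adds a neutral hydrogen
#' atom (1.00782503 Da) instead, a convention some isotope-pattern tools use
#' when charging patterns.
#'
#' @param neutralMass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @param adduct `"proton"` (default) or `"hydrogen"`.
#' @return m/z in Da per charge.
#' @export
#' @examples
#' ionMz(monoMass("H2O"), 1)  # 19.017841
ionMz <- function(neutralMass, charge, adduct = c("proton", "hydrogen")) {
  adduct <- match.arg(adduct)
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  am <- if (adduct == "proton") .PROTON_MASS else .HYDROGEN_MASS
  (neutralMass + charge * am) / charge
}
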