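## Per-element isotopologue states for n atoms of one element: enumerate
## heavy-isotope count vectors with multinomial probabilities, keeping states
## with probability >= pmin. Returns matrix-free lists (mass, prob).
.elementStates <- function(element, n, pmin) {
  iso <- .ELEMENT_ISOTOPES[[element]]
  k <- nrow(iso)
  if (k == 1L)
    return(list(mass = n * iso$mass, prob = 1))
  ## enumerate counts of heavy isotopes (indices 2..k); light count fills up
  heavyIdx <- 2:k
  grids <- lapply(heavyIdx, function(j) {
    ## generous per-isotope cap: probability of >= m heavies falls fast
    p <- iso$abundance[j]
    cap <- min(n, max(10L, ceiling(n * p + 12 * sqrt(max(n * p * (1 - p), 1)))))
    0:cap
  })
  grid <- do.call(expand.grid, grids)
  heavyTot <- rowSums(grid)
  grid <- grid[heavyTot <= n, , drop = FALSE]
  heavyTot <- heavyTot[heavyTot <= n]
  counts <- cbind(n - heavyTot, as.matrix(grid))
  logp <- lgamma(n + 1) - rowSums(lgamma(counts + 1)) +
    as.vector(counts %*% log(iso$abundance))
  prob <- exp(logp)
  keep <- prob >= pmin
  list(mass = as.vector(counts[keep, , drop = FALSE] %*% iso$mass),
       prob = prob[keep])
}

#' Fine (isotopologue-resolved) isotope pattern of a formula
#'
#' Enumerates per-element isotope-count vectors with multinomial
#' probabilities, combines them across elements, and keeps species by
#' descending abundance until their cumulative abundance reaches `coverage`
#' (default 0.9995, i.e. a 0.05% cut-off). Species with identical nominal
#' mass shift but different composition (e.g. one 13C vs one 15N) are kept
#' distinct -- the fine structure is never aggregated.
#'
#' @param formula Molecular formula (string or named count vector).
#' @param charge Integer >= 0; 0 returns neutral isotopologue masses,
#'   otherwise m/z at that charge with the chosen adduct.
#' @param coverage Cumulative abundance to retain, in (0, 1].
#' @param adduct `"proton"` or `"hydrogen"` charge-carrier convention.
#' @return Data frame with columns `mz` (Da, or Da/charge when charged) and
#'   `abundance` (fractions of the full distribution; they sum to a value in
#'   `[coverage, 1]`), sorted by `mz`, with attributes `coverage`, `charge`
#'   and `adduct`.
#' @export
#' @examples
#' fineIsotopePattern("C1", charge = 0)
fineIsotopePattern <- function(formula, charge = 0, coverage = 0.9995,
                               adduct = c("proton", "hydrogen")) {
  adduct <- match.arg(adduct)
  if (coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]")
  if (charge < 0 || charge != as.integer(charge))
    stop("charge must be a non-negative integer")
  f <- parseFormula(formula)
  if (!length(f)) stop("empty formula")
  ## states small enough to keep far below the final cut so that the final
  ## descending-abundance truncation is exact for all reported species
  pmin <- min(1e-10, (1 - coverage) * 1e-4)
  mass <- 0; prob <- 1
  for (e in names(f)) {
    st <- .elementStates(e, f[[e]], pmin)
    mass <- outer(mass, st$mass, `+`)
    prob <- outer(prob, st$prob, `*`)
    keep <- prob >= pmin
    mass <- mass[keep]; prob <- prob[keep]
  }
  o <- order(prob, decreasing = TRUE)
  mass <- mass[o]; prob <- prob[o]
  ncut <- if (coverage >= 1) length(prob) else {
    k <- which(cumsum(prob) >= coverage)[1]
    if (is.na(k)) length(prob) else k
  }
  mass <- mass[seq_len(ncut)]; prob <- prob[seq_len(ncut)]
  mz <- if (charge == 0) mass else
    ionMz(mass, charge, adduct)
  o <- order(mz)
  out <- data.frame(mz = mz[o], abundance = prob[o])
  attr(out, "coverage") <- coverage
  attr(out, "charge") <- charge
  attr(out, "adduct") <- adduct
  out
}
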