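.CO_MASS <- 27.9949146221   # formula CO

#' Default neutral-loss table for fragment generation
#'
#' A fragment acquires a loss variant when it contains at least one
#' qualifying residue: water loss (H2O1) for S/T/E/D, ammonia loss (H3N1)
#' for K/R/Q/N, and loss of CH2N2 for R. Losses are rendered as explicit
#' element-count strings in fragment labels (e.g. `y11-H3N1`).
#'
#' @return Data frame with columns `loss` (formula string) and `residues`.
#' @export
defaultNeutralLosses <- function() {
  data.frame(loss = c("H2O1", "H3N1", "C1H2N2"),
             residues = c("STED", "KRQN", "R"),
             stringsAsFactors = FALSE)
}

.fragmentLabel <- function(series, index, loss, charge) {
  paste0(series, index,
         ifelse(is.na(loss) | !nzchar(loss), "", paste0("-", loss)),
         " ", vapply(charge, function(z)
           paste(rep("+", z), collapse = " "), character(1)))
}

#' Theoretical a/b/y fragment ions of a peptide
#'
#' Generates all b and y ions for cleavage positions 1..L-1, plus a ions
#' (a = b - CO), at charges 1..`maxCharge`, with neutral-loss variants from
#' `losses`. When the peptide carries a modification, the modification mass
#' is included in exactly those fragments that contain the modified residue
#' (b/a ions with index >= position; y ions with index >= L - position + 1),
#' and those ions are flagged `modified`. m/z uses the proton adduct.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param modifications `NULL` or data frame with columns `name`, `position`.
#' @param maxCharge Maximum fragment charge (default 2).
#' @param losses Neutral-loss table, see [defaultNeutralLosses()].
#' @param registry Modification registry for mass shifts.
#' @return Data frame with columns `series`, `index`, `charge`, `loss`,
#'   `modified`, `mz` and `label` (e.g. `"y12-C1H2N2 + +"`).
#' @export
#' @examples
#' frag <- generateFragments("VLPVPQKAVPYPQR")
#' frag[frag$label == "y3 +", ]
generateFragments <- function(sequence, modifications = NULL, maxCharge = 2,
                              losses = defaultNeutralLosses(),
                              registry = defaultModifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < 2L) stop("peptide must have length >= 2 for fragmentation")
  rm <- .residueMasses()[res]
  if (anyNA(rm))
    stop("non-canonical residue(s) in '", sequence, "'")
  modShift <- numeric(L)   # shift attributed to each residue position
  if (!is.null(modifications) && nrow(modifications)) {
    for (i in seq_len(nrow(modifications))) {
      mod <- .modRow(registry, modifications$name[i])
      modShift[modifications$position[i]] <-
        modShift[modifications$position[i]] + mod$mono_shift
    }
  }
  cumN <- cumsum(rm)                      # residues 1..i
  cumModN <- cumsum(modShift)
  totalMod <- cumModN[L]
  rows <- list()
  addIons <- function(series, index, neutral, containsMod, prefixRes) {
    ## loss variants applicable to this fragment
    lossStrings <- NA_character_
    lossMasses <- 0
    if (nrow(losses)) {
      for (k in seq_len(nrow(losses))) {
        qual <- any(strsplit(losses$residues[k], "")[[1]] %in% prefixRes)
        if (qual) {
          lossStrings <- c(lossStrings, losses$loss[k])
          lossMasses <- c(lossMasses, monoMass(losses$loss[k]))
        }
      }
    }
    for (z in seq_len(maxCharge)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        series = series, index = index, charge = z,
        loss = lossStrings, modified = containsMod,
        mz = (neutral - lossMasses + z * .PROTON_MASS) / z,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(L - 1L)) {
    bNeutral <- cumN[i] + cumModN[i]
    addIons("b", i, bNeutral, cumModN[i] > 0, res[seq_len(i)])
    addIons("a", i, bNeutral - .CO_MASS, cumModN[i] > 0, res[seq_len(i)])
    yRes <- res[(L - i + 1L):L]
    yMod <- totalMod - cumModN[L - i]
    yNeutral <- (cumN[L] - cumN[L - i]) + .WATER_MASS + yMod
    addIons("y", i, yNeutral, yMod > 0, yRes)
  }
  out <- do.call(rbind, rows)
  out$label <- .fragmentLabel(out$series, out$index, out$loss, out$charge)
  rownames(out) <- NULL
  out
}
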