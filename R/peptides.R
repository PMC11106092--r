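## Residue (amino acid minus water) elemental formulas, canonical 20 letters.
.RESIDUE_FORMULAS <- list(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.residueMasses <- local({
  env <- new.env()
  env$m <- NULL
  function() {
    if (is.null(env$m))
      env$m <- vapply(.RESIDUE_FORMULAS, monoMass, numeric(1))
    env$m
  }
})

.WATER_MASS <- 2 * 1.0078250319 + 15.9949146221   # monoMass("H2O")

#' Read protein sequences from a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readAAStringSet()]. Sequences
#' are uppercased, whitespace is stripped, and residues are checked against
#' the 20 canonical amino-acid letters. Records containing the ambiguity
#' codes B, Z or X are passed through with a warning when
#' `allowAmbiguous = TRUE`, otherwise rejected.
#'
#' @param path Path to a FASTA file.
#' @param allowAmbiguous Allow B/Z/X with a warning (default `FALSE`).
#' @return A named character vector of protein sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
readProteinFasta <- function(path, allowAmbiguous = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## read without alphabet coercion so that invalid characters survive to
  ## be reported (the AA reader silently drops them)
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("cannot read FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(aa) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aa)))
  ids <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, character(1), 1L)
  names(seqs) <- ids
  canonical <- paste(names(.RESIDUE_FORMULAS), collapse = "")
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[[i]], "")[[1]],
                   strsplit(canonical, "")[[1]])
    amb <- intersect(bad, c("B", "Z", "X"))
    bad <- setdiff(bad, c("B", "Z", "X"))
    if (length(bad))
      stop("record '", ids[i], "' contains non-residue character(s): ",
           paste(bad, collapse = ", "))
    if (length(amb)) {
      if (!allowAmbiguous)
        stop("record '", ids[i], "' contains ambiguity code(s) ",
             paste(amb, collapse = ", "),
             "; set allowAmbiguous = TRUE to keep the record")
      warning("record '", ids[i], "' contains ambiguity code(s) ",
              paste(amb, collapse = ", "),
              "; mass computations on it will fail")
    }
  }
  seqs
}

## 1-based positions after which trypsin cleaves: K/R not followed by P.
.trypticSites <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  i <- which(res[-n] %in% c("K", "R"))
  i[res[i + 1L] != "P"]
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except when the next residue is proline, and
#' returns every peptide with 0 up to `missedCleavages` uncut internal sites.
#'
#' @param sequence Protein sequence (canonical residues).
#' @param missedCleavages Maximum number of missed cleavages (0--2 in the
#'   standard workflow; any non-negative integer accepted).
#' @param minLength Minimum peptide length to report (default 1, no filter).
#' @return A data frame with columns `sequence`, `start`, `end` (1-based,
#'   inclusive, in the parent protein) and `missed_cleavages`.
#' @export
#' @examples
#' digest("AKRPGKAR", missedCleavages = 2)
digest <- function(sequence, missedCleavages = 2, minLength = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (missedCleavages < 0) stop("missedCleavages must be >= 0")
  n <- nchar(sequence)
  sites <- .trypticSites(sequence)
  bounds <- c(0L, sites, n)            # peptide k spans bounds[k]+1 .. bounds[k+1]
  nfrag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (mc in 0:min(missedCleavages, nfrag - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + mc]
      if (e - s + 1L < minLength) next
      out[[length(out) + 1L]] <- list(sequence = substr(sequence, s, e),
                                      start = s, end = e,
                                      missed_cleavages = mc)
    }
  }
  df <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
}

#' Default peptide modification registry
#'
#' Modifications are treated as elemental-composition (hence mass) shifts
#' with residue site rules. Defaults cover the heat-induced chemistry of the
#' milk model system: lactulosyllysine (Amadori product of lysine and
#' lactose, +C12H20O10, abolishes tryptic cleavage at the modified lysine),
#' methionine oxidation (+O), methylation (+CH2 on K/R) and acetylation
#' (+C2H2O on K or the peptide N-terminus). All site rules are user
#' configurable: pass any data frame with the same columns.
#'
#' @return Data frame with columns `name`, `formula`, `mono_shift` (Da),
#'   `sites` (string of residue letters), `nterm` (also allowed on the
#'   peptide N-terminal residue) and `blocks_cleavage`.
#' @export
defaultModifications <- function() {
  df <- data.frame(
    name = c("Lactulosyllysine", "Oxidation", "Methylation", "Acetylation"),
    formula = c("C12H20O10", "O", "CH2", "C2H2O"),
    sites = c("K", "M", "KR", "K"),
    nterm = c(FALSE, FALSE, FALSE, TRUE),
    blocks_cleavage = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  df$mono_shift <- vapply(df$formula, monoMass, numeric(1))
  df
}

.modRow <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown modification: ", name)
  registry[i, , drop = FALSE]
}

#' Elemental formula of a (possibly modified) peptide
#'
#' Sum of residue formulas plus one water, plus the formula shift of each
#' modification. Each modification must be allowed at its stated position by
#' the registry's site rule.
#'
#' @param sequence Peptide sequence.
#' @param modifications `NULL`, or a data frame with columns `name` and
#'   `position` (1-based residue index).
#' @param registry Modification registry, see [defaultModifications()].
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' peptideFormula("G")                              # glycine, C2H5NO2
#' peptideFormula("VLPVPQKAVPYPQR",
#'   modifications = data.frame(name = "Lactulosyllysine", position = 7))
peptideFormula <- function(sequence, modifications = NULL,
                           registry = defaultModifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "))
  counts <- table(factor(res, levels = names(.RESIDUE_FORMULAS)))
  f <- parseFormula("H2O")
  for (aa in names(counts)[counts > 0]) {
    rf <- parseFormula(.RESIDUE_FORMULAS[[aa]])
    f <- formulaAdd(f, rf * as.integer(counts[[aa]]))
  }
  if (!is.null(modifications) && nrow(modifications)) {
    for (i in seq_len(nrow(modifications))) {
      mod <- .modRow(registry, modifications$name[i])
      pos <- modifications$position[i]
      if (pos < 1 || pos > length(res))
        stop("modification position ", pos, " outside peptide")
      okSite <- grepl(res[pos], mod$sites, fixed = TRUE) ||
        (mod$nterm && pos == 1L)
      if (!okSite)
        stop("modification '", mod$name, "' not allowed on residue ",
             res[pos], " at position ", pos)
      f <- formulaAdd(f, mod$formula)
    }
  }
  f
}

#' Neutral monoisotopic mass of a (possibly modified) peptide
#'
#' @inheritParams peptideFormula
#' @return Mass in Da.
#' @export
peptideMass <- function(sequence, modifications = NULL,
                        registry = defaultModifications()) {
  monoMass(peptideFormula(sequence, modifications, registry))
}

#' Enumerate modification variants of digest peptides
#'
#' For each input peptide, returns the unmodified record plus every placement
#' of up to `maxMods` registry modifications on allowed sites. A
#' `blocks_cleavage` modification (lactulosyllysine) is never placed on a
#' C-terminal cleavage lysine: glycation abolishes the tryptic cleavage site,
#' so a peptide ending in the modified lysine could not have been produced.
#' It is only placed on internal (missed-cleavage) K or a K followed by
#' proline.
#'
#' @param peptides Data frame as returned by [digest()], or a character
#'   vector of sequences.
#' @param registry Modification registry, see [defaultModifications()].
#' @param maxMods Maximum simultaneous modifications per peptide (default 1).
#' @return Data frame: the input columns plus `mod_name` and `mod_pos`
#'   (comma-separated when `maxMods > 1`; `NA` for the unmodified record).
#' @export
expandModifications <- function(peptides, registry = defaultModifications(),
                                maxMods = 1) {
  if (maxMods < 0) stop("maxMods must be >= 0")
  if (is.character(peptides))
    peptides <- data.frame(sequence = peptides, stringsAsFactors = FALSE)
  out <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides[i, , drop = FALSE]
    res <- strsplit(pep$sequence, "")[[1]]
    L <- length(res)
    placements <- list()   # each: list(name, pos)
    for (j in seq_len(nrow(registry))) {
      mod <- registry[j, ]
      sites <- which(vapply(res, grepl, logical(1), x = mod$sites,
                            fixed = TRUE))
      if (mod$nterm) sites <- union(1L, sites)
      if (mod$blocks_cleavage) {
        ## exclude the C-terminal residue: a cleavage-site K there would have
        ## been uncleavable if glycated
        sites <- sites[sites < L]
      }
      for (s in sort(sites))
        placements[[length(placements) + 1L]] <-
          list(name = mod$name, pos = s)
    }
    recs <- list(cbind(pep, mod_name = NA_character_, mod_pos = NA_character_))
    if (maxMods >= 1 && length(placements)) {
      for (k in seq_len(min(maxMods, length(placements)))) {
        idx <- utils::combn(length(placements), k, simplify = FALSE)
        for (sel in idx) {
          pos <- vapply(placements[sel], `[[`, numeric(1), "pos")
          if (anyDuplicated(pos)) next
          nm <- vapply(placements[sel], `[[`, character(1), "name")
          o <- order(pos)
          recs[[length(recs) + 1L]] <-
            cbind(pep, mod_name = paste(nm[o], collapse = ","),
                  mod_pos = paste(pos[o], collapse = ","))
        }
      }
    }
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## parse "a,b" mod columns back into a modifications data.frame (or NULL)
.modsFromRecord <- function(mod_name, mod_pos) {
  if (is.na(mod_name) || !nzchar(mod_name)) return(NULL)
  data.frame(name = strsplit(mod_name, ",")[[1]],
             position = as.integer(strsplit(as.character(mod_pos), ",")[[1]]),
             stringsAsFactors = FALSE)
}
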