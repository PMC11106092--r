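.NO_MATCH <- "No match found in the limitations of the search parameters"

#' SearchSpace: indexed candidate species for feature identification
#'
#' Every species is either a precursor (a possibly modified digest peptide
#' at a precursor charge) or one of its a/b/y fragment ions, with its
#' theoretical m/z computed with the proton adduct. The table is sorted by
#' m/z for binary-search range queries.
#'
#' @slot table A data frame sorted by `mz` with columns `mz`, `charge`,
#'   `type` (`"precursor"`/`"fragment"`), `sequence`, `protein`, `start`,
#'   `end`, `missed_cleavages`, `mod_name`, `mod_pos`, `series`, `index`,
#'   `loss`, `label`.
#' @slot params The build parameters (missed cleavages, registry, charges,
#'   m/z range).
#' @export
setClass("SearchSpace",
  representation(table = "data.frame", params = "list"),
  validity = function(object) {
    msg <- character(0)
    need <- c("mz", "charge", "type", "sequence", "protein", "mod_name")
    if (!all(need %in% colnames(object@table)))
      msg <- c(msg, paste("table must contain:", paste(need, collapse = ", ")))
    if (is.unsorted(object@table$mz))
      msg <- c(msg, "table must be sorted by mz")
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("show", "SearchSpace", function(object) {
  tab <- object@table
  cat("SearchSpace:", nrow(tab), "species (",
      sum(tab$type == "precursor"), "precursor /",
      sum(tab$type == "fragment"), "fragment ) from",
      length(unique(tab$protein)), "protein(s)\n")
  cat("  m/z range:", format(min(tab$mz), digits = 7), "-",
      format(max(tab$mz), digits = 7), "\n")
})

#' @describeIn SearchSpace-class The species table.
#' @param x A `SearchSpace`.
#' @export
searchTable <- function(x) x@table

#' Build the digest/modification/fragment search space
#'
#' Digests every protein with up to `missedCleavages` missed cleavages,
#' enumerates modification variants (up to `maxMods` per peptide), and
#' emits each variant as precursor species at the precursor charges plus
#' all its a/b/y fragment ions (with neutral losses) at the fragment
#' charges. Species are deduplicated by (sequence, modification, series,
#' index, loss, charge) and restricted to the instrument m/z range.
#'
#' @param fasta Path(s) to FASTA file(s), or a named character vector of
#'   protein sequences.
#' @param missedCleavages Maximum missed cleavages (default 2).
#' @param registry Modification registry, see [defaultModifications()].
#' @param maxMods Maximum modifications per peptide (default 1).
#' @param precursorCharges Precursor charge states (default 1:3).
#' @param fragmentCharges Fragment charge states (default 1:2).
#' @param mzRange Instrument m/z range (default `c(50, 2000)`).
#' @param minPeptideLength Minimum digest peptide length (default 2).
#' @return A [SearchSpace-class].
#' @export
buildSearchSpace <- function(fasta, missedCleavages = 2,
                             registry = defaultModifications(), maxMods = 1,
                             precursorCharges = 1:3, fragmentCharges = 1:2,
                             mzRange = c(50, 2000), minPeptideLength = 2) {
  proteins <- if (is.character(fasta) && all(file.exists(fasta))) {
    do.call(c, lapply(fasta, readProteinFasta))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else stop("fasta must be existing file path(s) or a named sequence vector")
  if (!length(proteins)) stop("no protein sequences")
  rows <- vector("list", 0L)
  for (prot in names(proteins)) {
    peps <- digest(proteins[[prot]], missedCleavages,
                   minLength = minPeptideLength)
    if (nrow(peps) == 0L) next
    vars <- expandModifications(peps, registry, maxMods)
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      mods <- .modsFromRecord(v$mod_name, v$mod_pos)
      neutral <- peptideMass(v$sequence, mods, registry)
      base <- data.frame(sequence = v$sequence, protein = prot,
                         start = v$start, end = v$end,
                         missed_cleavages = v$missed_cleavages,
                         mod_name = ifelse(is.na(v$mod_name), NA_character_,
                                           v$mod_name),
                         mod_pos = ifelse(is.na(v$mod_pos), NA_character_,
                                          as.character(v$mod_pos)),
                         stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(
        base[rep(1L, length(precursorCharges)), , drop = FALSE],
        type = "precursor", charge = precursorCharges,
        mz = ionMz(neutral, precursorCharges),
        series = NA_character_, index = NA_integer_, loss = NA_character_,
        label = paste0("[M+", precursorCharges, "H]",
                       strrep("+", precursorCharges)))
      if (nchar(v$sequence) >= 2L) {
        fr <- generateFragments(v$sequence, mods,
                                maxCharge = max(fragmentCharges),
                                registry = registry)
        fr <- fr[fr$charge %in% fragmentCharges, , drop = FALSE]
        rows[[length(rows) + 1L]] <- cbind(
          base[rep(1L, nrow(fr)), , drop = FALSE],
          type = "fragment", charge = fr$charge, mz = fr$mz,
          series = fr$series, index = fr$index, loss = fr$loss,
          label = fr$label)
      }
    }
  }
  tab <- data.table::rbindlist(rows)
  if (is.null(tab) || nrow(tab) == 0L) stop("empty digest: no species")
  tab <- unique(tab, by = c("sequence", "mod_name", "mod_pos", "series",
                            "index", "loss", "charge"))
  tab <- tab[tab$mz >= mzRange[1] & tab$mz <= mzRange[2], ]
  tab <- as.data.frame(tab)
  tab <- tab[order(tab$mz), , drop = FALSE]
  rownames(tab) <- NULL
  new("SearchSpace", table = tab,
      params = list(missedCleavages = missedCleavages, registry = registry,
                    maxMods = maxMods, precursorCharges = precursorCharges,
                    fragmentCharges = fragmentCharges, mzRange = mzRange))
}

#' Match one feature against the search space
#'
#' Binary-searches the m/z-sorted species index for candidates with
#' `|mz_obs - mz_theo| / mz_theo <= relTol` and the feature's charge.
#' Candidates are ordered by absolute ppm error, ties broken by fewer
#' modifications, then shorter sequence.
#'
#' @param mz Observed feature m/z.
#' @param charge Observed feature charge.
#' @param space A [SearchSpace-class].
#' @param relTol Relative tolerance (default `1e-5`, i.e. 0.001%).
#' @return Data frame of candidate species with `rel_error` and `ppm`
#'   columns (possibly zero rows).
#' @export
matchFeature <- function(mz, charge, space, relTol = 1e-5) {
  stopifnot(relTol > 0, length(mz) == 1L)
  tab <- space@table
  lo <- mz / (1 + relTol); hi <- mz / (1 - relTol)
  i1 <- findInterval(lo, tab$mz, left.open = TRUE) + 1L
  i2 <- findInterval(hi, tab$mz)
  if (i2 < i1) return(cbind(tab[0, ], rel_error = numeric(0),
                            ppm = numeric(0)))
  cand <- tab[i1:i2, , drop = FALSE]
  cand <- cand[cand$charge == charge, , drop = FALSE]
  relerr <- (mz - cand$mz) / cand$mz
  cand <- cand[abs(relerr) <= relTol, , drop = FALSE]
  relerr <- relerr[abs(relerr) <= relTol]
  cand$rel_error <- relerr
  cand$ppm <- relerr * 1e6
  nmods <- ifelse(is.na(cand$mod_name), 0L,
                  lengths(strsplit(cand$mod_name, ",")))
  ## quantise |ppm| so mass-degenerate species (e.g. a peptide and the
  ## full-length y ion of its missed-cleavage parent) rank by the
  ## documented tie-breaks instead of floating-point noise
  cand[order(round(abs(cand$ppm), 4), nmods, nchar(cand$sequence),
             cand$sequence, cand$label), , drop = FALSE]
}

.nearestScan <- function(spectra, rt, energy, rtWindow) {
  sel <- Filter(function(s) scanEnergy(s) == energy, spectra)
  if (!length(sel)) return(NULL)
  rts <- vapply(sel, scanRt, numeric(1))
  i <- which.min(abs(rts - rt))
  if (abs(rts[i] - rt) > rtWindow) return(NULL)
  sel[[i]]
}

.matchPeaks <- function(theoMz, spectrum, relTol, priority = NULL) {
  ## nearest observed peak within relative tolerance per theoretical m/z;
  ## with `priority` the assignment is one-to-one and greedy (theoretical
  ## species claimed in descending priority, each observed peak used once)
  obsMz <- spectrum@mz; obsInt <- spectrum@intensity
  n <- length(theoMz)
  outMz <- rep(NA_real_, n); outInt <- rep(NA_real_, n)
  if (length(obsMz)) {
    used <- rep(FALSE, length(obsMz))
    ord <- if (is.null(priority)) seq_len(n) else order(-priority)
    for (i in ord) {
      j <- which(abs(obsMz - theoMz[i]) / theoMz[i] <= relTol &
                   (is.null(priority) | !used))
      if (length(j)) {
        j <- j[which.min(abs(obsMz[j] - theoMz[i]))]
        outMz[i] <- obsMz[j]; outInt[i] <- obsInt[j]
        used[j] <- TRUE
      }
    }
  }
  data.frame(observed_mz = outMz, observed_intensity = outInt)
}

#' Verify a candidate's isotope signature in the low-energy spectra
#'
#' Computes the fine isotope pattern of the candidate peptide's formula at
#' the requested charge(s) and compares it peak-by-peak against the nearest
#' low-energy scan within the retention-time window, at the relative
#' tolerance. The verdict is `"isotopes_found"` when the monoisotopic peak
#' plus at least `minIsotopes` further isotopologues are assigned,
#' `"isotopes_not_found"` otherwise, and `"no_spectrum"` when no scan lies
#' in the window.
#'
#' @param candidate One row of a [matchFeature()] result (or any list with
#'   `sequence`, `mod_name`, `mod_pos`, `charge`).
#' @param spectra List of [MseSpectrum-class] for the run.
#' @param rt Feature retention time in seconds.
#' @param rtWindow Scan lookup window in seconds (default 5).
#' @param relTol Relative m/z tolerance (default `1e-5`).
#' @param coverage Isotope-pattern cumulative abundance cut (default
#'   0.9995).
#' @param minIsotopes Isotopologues beyond the monoisotopic peak required
#'   for a positive verdict (default 2).
#' @param charges Charges at which to search the envelope (default: the
#'   candidate's charge).
#' @param registry Modification registry.
#' @return List with `pairs` (theoretical vs observed table), `n_assigned`,
#'   and `verdict`.
#' @export
verifyIsotopes <- function(candidate, spectra, rt, rtWindow = 5,
                           relTol = 1e-5, coverage = 0.9995, minIsotopes = 2,
                           charges = NULL,
                           registry = defaultModifications()) {
  if (is.null(charges)) charges <- candidate$charge
  mods <- .modsFromRecord(candidate$mod_name, candidate$mod_pos)
  formula <- peptideFormula(candidate$sequence, mods, registry)
  scan <- .nearestScan(spectra, rt, "low", rtWindow)
  pairs <- list()
  for (z in charges) {
    pat <- fineIsotopePattern(formula, charge = z, coverage = coverage)
    obs <- if (is.null(scan))
      data.frame(observed_mz = rep(NA_real_, nrow(pat)),
                 observed_intensity = rep(NA_real_, nrow(pat)))
    else .matchPeaks(pat$mz, scan, relTol, priority = pat$abundance)
    pairs[[length(pairs) + 1L]] <- data.frame(
      charge = z, theoretical_mz = pat$mz, abundance = pat$abundance, obs)
  }
  pairs <- do.call(rbind, pairs)
  pairs$assigned <- !is.na(pairs$observed_mz)
  if (is.null(scan))
    return(list(pairs = pairs, n_assigned = 0L, verdict = "no_spectrum"))
  ## monoisotopic = lowest theoretical m/z per charge
  monoOk <- any(vapply(split(pairs, pairs$charge), function(df)
    df$assigned[which.min(df$theoretical_mz)], logical(1)))
  nBeyond <- max(vapply(split(pairs, pairs$charge), function(df)
    sum(df$assigned[-which.min(df$theoretical_mz)]), integer(1)))
  verdict <- if (monoOk && nBeyond >= minIsotopes) "isotopes_found"
             else "isotopes_not_found"
  list(pairs = pairs, n_assigned = sum(pairs$assigned), verdict = verdict)
}

#' Verify a candidate's fragments in the low- and high-energy spectra
#'
#' Generates all a/b/y fragments of the candidate peptide both with and
#' without its modification, and assigns them to peaks of the nearest
#' high-energy scan (and, as fragments also arise in-source, the nearest
#' low-energy scan) within the retention-time window. Assignments are
#' purely mathematical at the stated tolerance; an assignment of an
#' unmodified fragment whose span covers the modified residue is kept but
#' flagged `implausible`, since such an ion should carry the modification.
#'
#' @inheritParams verifyIsotopes
#' @param fragmentCharges Fragment charges to generate (default 1:2).
#' @return List with `pairs` (the assigned-fragment table: observed m/z and
#'   intensity, fragment label, theoretical m/z, `modified`, `implausible`,
#'   `energy`), `n_assigned` and `verdict` (`"fragments_found"`,
#'   `"fragments_not_found"` or `"no_spectrum"`).
#' @export
verifyFragments <- function(candidate, spectra, rt, rtWindow = 5,
                            relTol = 1e-5, fragmentCharges = 1:2,
                            registry = defaultModifications()) {
  mods <- .modsFromRecord(candidate$mod_name, candidate$mod_pos)
  L <- nchar(candidate$sequence)
  frUnmod <- generateFragments(candidate$sequence, NULL,
                               maxCharge = max(fragmentCharges),
                               registry = registry)
  frUnmod$variant <- "unmodified"
  frAll <- frUnmod
  if (!is.null(mods)) {
    frMod <- generateFragments(candidate$sequence, mods,
                               maxCharge = max(fragmentCharges),
                               registry = registry)
    frMod$variant <- "modified"
    ## keep modified rows only where the mass actually differs
    frMod <- frMod[frMod$modified, , drop = FALSE]
    frAll <- rbind(frUnmod, frMod)
  }
  frAll <- frAll[frAll$charge %in% fragmentCharges, , drop = FALSE]
  ## does an unmodified fragment span a modified residue? (b/a: index >=
  ## pos; y: index >= L - pos + 1)
  frAll$implausible <- FALSE
  if (!is.null(mods)) {
    for (pos in mods$position) {
      spans <- ifelse(frAll$series == "y",
                      frAll$index >= L - pos + 1L, frAll$index >= pos)
      frAll$implausible <- frAll$implausible |
        (spans & frAll$variant == "unmodified")
    }
  }
  out <- list()
  found <- FALSE; anyScan <- FALSE
  for (energy in c("high", "low")) {
    scan <- .nearestScan(spectra, rt, energy, rtWindow)
    if (is.null(scan)) next
    anyScan <- TRUE
    obs <- .matchPeaks(frAll$mz, scan, relTol)
    hit <- !is.na(obs$observed_mz)
    if (any(hit)) {
      found <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        energy = energy, observed_mz = obs$observed_mz[hit],
        observed_intensity = obs$observed_intensity[hit],
        fragment = frAll$label[hit], theoretical_mz = frAll$mz[hit],
        variant = frAll$variant[hit], implausible = frAll$implausible[hit],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(energy = character(0), observed_mz = numeric(0),
               observed_intensity = numeric(0), fragment = character(0),
               theoretical_mz = numeric(0), variant = character(0),
               implausible = logical(0))
  verdict <- if (!anyScan) "no_spectrum"
             else if (found) "fragments_found" else "fragments_not_found"
  list(pairs = pairs, n_assigned = nrow(pairs), verdict = verdict)
}

#' IdentificationReport: per-feature identification outcomes
#'
#' One entry per selected feature: either the ranked match candidates with
#' their isotope/fragment evidence, or the explicit no-match outcome. No
#' composite score is computed -- the evidence (ppm error, assigned isotope
#' and fragment counts, plausibility flags) is exposed for individual
#' interpretation.
#'
#' @slot results Named list (by feature id) with elements `feature`,
#'   `candidates`, `isotopes`, `fragments`.
#' @slot summary The per-feature summary table.
#' @export
setClass("IdentificationReport",
  representation(results = "list", summary = "data.frame"),
  validity = function(object) {
    if (!identical(sort(as.character(names(object@results))),
                   sort(as.character(object@summary$feature_id))))
      "results and summary must cover the same features" else TRUE
  })

#' @export
setMethod("show", "IdentificationReport", function(object) {
  s <- object@summary
  cat("IdentificationReport:", nrow(s), "feature(s),",
      sum(s$peptide != .NO_MATCH), "matched\n")
  for (i in seq_len(nrow(s))) {
    if (s$peptide[i] == .NO_MATCH) {
      cat(sprintf("  %s (m/z %.4f, %d+): %s\n", s$feature_id[i], s$mz[i],
                  s$charge[i], .NO_MATCH))
    } else {
      cat(sprintf(
        "  %s (m/z %.4f, %d+): %s [%s] %s%s, %+.1f ppm, %d isotopes, %d fragments\n",
        s$feature_id[i], s$mz[i], s$charge[i], s$peptide[i], s$protein[i],
        ifelse(is.na(s$modification[i]) | s$modification[i] == "", "",
               paste0(s$modification[i], " ")),
        ifelse(is.na(s$fragment[i]) | s$fragment[i] == "", "precursor",
               s$fragment[i]),
        s$ppm[i], s$n_isotopes[i], s$n_fragments[i]))
    }
  }
})

#' @describeIn IdentificationReport-class The summary table.
#' @param x An `IdentificationReport`.
#' @export
reportSummary <- function(x) x@summary

#' @describeIn IdentificationReport-class Full per-feature results.
#' @export
reportResults <- function(x) x@results

#' Identify selected features against a search space
#'
#' Runs the two-part identification for each feature: (1) m/z matching
#' against the digest/modification/fragment space at the relative
#' tolerance; (2) verification of the best candidate's isotope envelope in
#' the low-energy spectra and -- for precursor candidates -- of its a/b/y
#' fragments in the high- and low-energy spectra. Features whose candidate
#' is itself a fragment ion skip fragment verification. When no spectra are
#' supplied only matching is performed.
#'
#' @param features Data frame with columns `feature_id`, `mz`, `charge` and
#'   (for verification) `rt_s`.
#' @param space A [SearchSpace-class].
#' @param spectra Optional list of [MseSpectrum-class] for verification.
#' @param relTol Relative m/z tolerance (default `1e-5`).
#' @param rtWindow Spectrum lookup window in seconds (default 5).
#' @param isotopeCharges Optional charges for isotope verification beyond
#'   the feature charge (e.g. `2:3`).
#' @param ... Passed to [verifyIsotopes()] and [verifyFragments()].
#' @return An [IdentificationReport-class].
#' @export
identifyFeatures <- function(features, space, spectra = NULL, relTol = 1e-5,
                             rtWindow = 5, isotopeCharges = NULL, ...) {
  stopifnot(all(c("feature_id", "mz", "charge") %in% colnames(features)))
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    cand <- matchFeature(ft$mz, ft$charge, space, relTol)
    iso <- NULL; frg <- NULL
    if (nrow(cand)) {
      best <- cand[1L, ]
      if (!is.null(spectra) && "rt_s" %in% colnames(ft)) {
        iso <- verifyIsotopes(best, spectra, ft$rt_s, rtWindow = rtWindow,
                              relTol = relTol,
                              charges = union(best$charge, isotopeCharges),
                              ...)
        if (best$type == "precursor")
          frg <- verifyFragments(best, spectra, ft$rt_s, rtWindow = rtWindow,
                                 relTol = relTol, ...)
      }
      rows[[i]] <- data.frame(
        feature_id = ft$feature_id, mz = ft$mz, charge = ft$charge,
        peptide = best$sequence, protein = best$protein,
        modification = ifelse(is.na(best$mod_name), "", best$mod_name),
        fragment = ifelse(best$type == "fragment", best$label, ""),
        ppm = best$ppm,
        n_isotopes = if (is.null(iso)) NA_integer_ else iso$n_assigned,
        n_fragments = if (is.null(frg)) NA_integer_ else frg$n_assigned,
        flags = paste(c(
          if (!is.null(iso)) iso$verdict,
          if (!is.null(frg)) frg$verdict,
          if (!is.null(frg) && any(frg$pairs$implausible))
            "implausible_unmodified_fragment"), collapse = ";"),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        feature_id = ft$feature_id, mz = ft$mz, charge = ft$charge,
        peptide = .NO_MATCH, protein = "", modification = "", fragment = "",
        ppm = NA_real_, n_isotopes = NA_integer_, n_fragments = NA_integer_,
        flags = "", stringsAsFactors = FALSE)
    }
    results[[ft$feature_id]] <- list(feature = ft, candidates = cand,
                                     isotopes = iso, fragments = frg)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), mz = numeric(0),
               charge = integer(0), peptide = character(0),
               protein = character(0), modification = character(0),
               fragment = character(0), ppm = numeric(0),
               n_isotopes = integer(0), n_fragments = integer(0),
               flags = character(0))
  rownames(summary) <- NULL
  new("IdentificationReport", results = results, summary = summary)
}

#' The explicit no-match outcome string
#'
#' @return The string reported for features with no candidate within the
#'   search parameters.
#' @export
noMatchString <- function() .NO_MATCH

#' Write / read an identification report summary as TSV
#'
#' @param report An [IdentificationReport-class].
#' @param path Output TSV path.
#' @return `writeIdentificationReport()`: `path` invisibly;
#'   `readIdentificationReport()`: the summary data frame.
#' @export
writeIdentificationReport <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(reportSummary(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeIdentificationReport
#' @export
readIdentificationReport <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = c(n_isotopes = "integer",
                                  n_fragments = "integer",
                                  ppm = "numeric", charge = "integer"))
  for (col in c("modification", "fragment", "flags", "protein"))
    df[[col]][is.na(df[[col]])] <- ""
  df
}
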