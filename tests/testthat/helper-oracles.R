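# Independent oracles used across tests; deliberately brute-force and slow.

# every contiguous substring that is a valid tryptic product with <= mc
# internal cleavage sites (cleave after K/R not before P)
bruteDigest <- function(sequence, mc) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  isSite <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  out <- list()
  for (s in seq_len(n)) for (e in s:n) {
    startOk <- s == 1 || isSite(s - 1)
    endOk <- e == n || isSite(e)
    if (!startOk || !endOk) next
    internal <- if (e > s) sum(vapply(s:(e - 1), isSite, logical(1))) else 0L
    if (internal <= mc)
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(res[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal)
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# exhaustive isotopologue enumeration over all per-atom isotope assignments
# (feasible only for tiny formulas); aggregates identical count-vectors
bruteIsotopes <- function(formula) {
  f <- parseFormula(formula)
  iso <- elementIsotopes()
  mass <- 0; prob <- 1
  for (e in names(f)) {
    tbl <- iso[[e]]
    for (atom in seq_len(f[[e]])) {
      mass <- outer(mass, tbl$mass, `+`)
      prob <- outer(prob, tbl$abundance, `*`)
      mass <- as.vector(mass); prob <- as.vector(prob)
    }
  }
  agg <- tapply(prob, round(mass, 5), sum)
  data.frame(mz = as.numeric(names(agg)), abundance = as.vector(agg))
}

randomPeptide <- function(n, letters = names(mseMarkers:::.RESIDUE_FORMULAS)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# a small, fast simulated study for feature/pipeline tests
smallSimConfig <- function(seed, nNoise = 30, nPerClass = c(heated = 2, "non-heated" = 2),
                           ...) {
  markers <- defaultMarkers()[c(1, 3), ]
  markers$rt <- c(15, 30)
  simulationConfig(markers = markers, nNoise = nNoise, nPerClass = nPerClass,
                   rtSpanS = 45, seed = seed, ...)
}

tmpFasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
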