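test_that("the search space enumerates a small protein exhaustively", {
  space <- buildSearchSpace(c(P1 = "AAKAA"), missedCleavages = 2,
                            registry = defaultModifications()[0, ],
                            mzRange = c(0, 5000), minPeptideLength = 1)
  tab <- searchTable(space)
  pre <- tab[tab$type == "precursor", ]
  expect_setequal(unique(pre$sequence), c("AAK", "AA", "AAKAA"))
  expect_setequal(unique(pre$charge), 1:3)
  # fragments only for length >= 2; b/y/a series at charges 1..2
  frg <- tab[tab$type == "fragment", ]
  expect_setequal(unique(frg$series), c("a", "b", "y"))
  expect_setequal(unique(frg$charge), 1:2)
  # y1 of AAK at 1+: lysine + water + proton
  y1 <- frg[frg$sequence == "AAK" & frg$series == "y" & frg$index == 1 &
              frg$charge == 1 & is.na(frg$loss), ]
  expect_equal(y1$mz, monoMass("C6H12N2O") + monoMass("H2O") + 1.00727646,
               tolerance = 1e-9)
  expect_error(buildSearchSpace(character(0)), "fasta|protein")
})

test_that("species are deduplicated and the index is sorted", {
  space <- buildSearchSpace(c(P1 = "AKAKAK"), missedCleavages = 2,
                            registry = defaultModifications()[0, ])
  tab <- searchTable(space)
  key <- with(tab, paste(sequence, mod_name, series, index, loss, charge))
  expect_false(anyDuplicated(key) > 0)
  expect_false(is.unsorted(tab$mz))
})

test_that("matching equals a brute-force linear scan over the space", {
  space <- buildSearchSpace(syntheticMilkFasta())
  tab <- searchTable(space)
  set.seed(21)
  probes <- data.frame(
    mz = c(sample(tab$mz, 30) * (1 + runif(30, -2e-5, 2e-5)),
           runif(10, 50, 2000)),
    charge = sample(1:3, 40, replace = TRUE))
  for (i in seq_len(nrow(probes))) {
    got <- matchFeature(probes$mz[i], probes$charge[i], space)
    rel <- abs(probes$mz[i] - tab$mz) / tab$mz
    lin <- tab[rel <= 1e-5 & tab$charge == probes$charge[i], ]
    expect_setequal(paste(got$sequence, got$label, got$charge),
                    paste(lin$sequence, lin$label, lin$charge))
    if (nrow(got)) expect_true(all(abs(got$rel_error) <= 1e-5))
  }
})

test_that("an exact m/z probe matches at zero ppm", {
  space <- buildSearchSpace(c(P1 = "AAKAA"),
                            registry = defaultModifications()[0, ])
  sp1 <- searchTable(space)[1, ]
  got <- matchFeature(sp1$mz, sp1$charge, space)
  expect_gte(nrow(got), 1L)
  expect_equal(got$ppm[1], 0, tolerance = 1e-9)
})

test_that("isotope verification assigns planted envelopes", {
  mods <- data.frame(name = "Lactulosyllysine", position = 7)
  f <- peptideFormula("VLPVPQKAVPYPQR", mods)
  pat <- fineIsotopePattern(f, charge = 3)
  spectra <- list(MseSpectrum(100, "low", pat$mz, pat$abundance * 1e5))
  cand <- list(sequence = "VLPVPQKAVPYPQR", mod_name = "Lactulosyllysine",
               mod_pos = "7", charge = 3L)
  v <- verifyIsotopes(cand, spectra, rt = 101)
  expect_identical(v$verdict, "isotopes_found")
  expect_equal(v$n_assigned, nrow(pat))
  # an empty spectrum assigns nothing
  v0 <- verifyIsotopes(cand, list(MseSpectrum(100, "low")), rt = 101)
  expect_identical(v0$verdict, "isotopes_not_found")
  expect_equal(v0$n_assigned, 0L)
  # no scan within the window
  v1 <- verifyIsotopes(cand, spectra, rt = 300)
  expect_identical(v1$verdict, "no_spectrum")
})

test_that("unassigned theoretical isotopologues are reported", {
  # an instrument records only the strong species; with one-to-one
  # assignment the minor 15N and 18O isotopologues stay unassigned even
  # though stronger neighbours lie within the m/z tolerance
  mods <- data.frame(name = "Lactulosyllysine", position = 7)
  f <- peptideFormula("VLPVPQKAVPYPQR", mods)
  pat <- fineIsotopePattern(f, charge = 3)
  mono <- min(pat$mz)
  n15 <- mono + (15.0001088984 - 14.0030740052) / 3   # one 15N
  o18 <- mono + (17.9991604 - 15.9949146221) / 3      # one 18O
  c13n15 <- mono + (1.0033548378 + 0.9970348932) / 3  # 13C + 15N
  c13x2 <- mono + 2 * 1.0033548378 / 3                # two 13C
  major <- pat$abundance > 0.01 &
    !vapply(pat$mz, function(m)
      any(abs(m - c(n15, o18)) < 1e-4), logical(1))
  spectra <- list(MseSpectrum(50, "low", pat$mz[major],
                              pat$abundance[major] * 1e5))
  cand <- list(sequence = "VLPVPQKAVPYPQR", mod_name = "Lactulosyllysine",
               mod_pos = "7", charge = 3L)
  v <- verifyIsotopes(cand, spectra, rt = 50)
  unas <- v$pairs[!v$pairs$assigned, ]
  expect_true(any(abs(unas$theoretical_mz - n15) < 1e-4))
  expect_true(any(abs(unas$theoretical_mz - o18) < 1e-4))
  # the strong neighbouring species are both assigned
  asg <- v$pairs[v$pairs$assigned, ]
  expect_true(any(abs(asg$theoretical_mz - c13n15) < 1e-4))
  expect_true(any(abs(asg$theoretical_mz - c13x2) < 1e-4))
  expect_identical(v$verdict, "isotopes_found")
})

test_that("fragment verification pairs peaks and flags implausible ions", {
  mods <- data.frame(name = "Lactulosyllysine", position = 7)
  frm <- generateFragments("VLPVPQKAVPYPQR", mods)
  planted <- frm[frm$label %in% c("y3 +", "b10 + +", "y12 + +"), ]
  # add the unmodified y8 2+ peak: spans K7, chemically implausible
  fru <- generateFragments("VLPVPQKAVPYPQR")
  y8 <- fru$mz[fru$label == "y8 + +"]
  high <- MseSpectrum(100.3, "high", c(planted$mz, y8),
                      rep(100, nrow(planted) + 1))
  cand <- list(sequence = "VLPVPQKAVPYPQR", mod_name = "Lactulosyllysine",
               mod_pos = "7", charge = 3L, type = "precursor")
  v <- verifyFragments(cand, list(high), rt = 100)
  expect_identical(v$verdict, "fragments_found")
  expect_true(all(c("y3 +", "b10 + +", "y12 + +") %in% v$pairs$fragment))
  y8row <- v$pairs[v$pairs$fragment == "y8 + +" &
                     v$pairs$variant == "unmodified", ]
  expect_equal(nrow(y8row), 1L)
  expect_true(y8row$implausible)
  # y3 does not span K7 and is plausible unmodified
  y3row <- v$pairs[v$pairs$fragment == "y3 +", ]
  expect_false(any(y3row$implausible))
  v0 <- verifyFragments(cand, list(), rt = 100)
  expect_identical(v0$verdict, "no_spectrum")
})

test_that("reports cover every feature once and round-trip through TSV", {
  space <- buildSearchSpace(syntheticMilkFasta())
  ft <- data.frame(feature_id = c("FT43359", "FT66837"),
                   mz = c(639.3498, 458.7419), charge = c(3L, 2L))
  rep <- identifyFeatures(ft, space)
  s <- reportSummary(rep)
  expect_identical(s$feature_id, ft$feature_id)
  expect_identical(s$peptide[2], noMatchString())
  path <- tempfile(fileext = ".tsv")
  writeIdentificationReport(rep, path)
  back <- readIdentificationReport(path)
  expect_equal(back, s, tolerance = 1e-9)
  # empty input gives an empty report
  rep0 <- identifyFeatures(ft[0, ], space)
  expect_equal(nrow(reportSummary(rep0)), 0L)
})
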