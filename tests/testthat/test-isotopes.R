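test_that("a single-carbon pattern reproduces the element table", {
  pat <- fineIsotopePattern("C1", charge = 0, coverage = 1)
  iso <- elementIsotopes()$C
  expect_equal(pat$mz, iso$mass, tolerance = 1e-9)
  expect_equal(pat$abundance, iso$abundance, tolerance = 1e-12)
})

test_that("patterns agree with exhaustive enumeration on small formulas", {
  for (f in c("CH4", "C2H5NO2", "H2OS")) {
    got <- fineIsotopePattern(f, charge = 0, coverage = 1)
    agg <- tapply(got$abundance, round(got$mz, 5), sum)
    exp <- bruteIsotopes(f)
    expect_equal(as.numeric(names(agg)), exp$mz, tolerance = 1e-9)
    expect_equal(as.vector(agg), exp$abundance, tolerance = 1e-9,
                 info = f)
  }
})

test_that("coverage truncation keeps the stated abundance mass", {
  f <- peptideFormula("VLPVPQKAVPYPQR")
  for (cov in c(0.9, 0.99, 0.9995)) {
    pat <- fineIsotopePattern(f, charge = 0, coverage = cov)
    expect_gte(sum(pat$abundance), cov)
    expect_lte(sum(pat$abundance), 1 + 1e-12)
  }
  expect_error(fineIsotopePattern("CH4", coverage = 0), "coverage")
  expect_error(fineIsotopePattern("CH4", coverage = 1.5), "coverage")
})

test_that("the monoisotopic species dominates small CHNO peptides", {
  set.seed(9)
  for (i in 1:5) {
    pep <- randomPeptide(sample(5:15, 1),
                         letters = strsplit("GASPVTLNDQKEHFRYW", "")[[1]])
    f <- peptideFormula(pep)
    pat <- fineIsotopePattern(f, charge = 0)
    expect_equal(which.max(pat$abundance), which.min(pat$mz))
  }
})

test_that("fine structure keeps near-isobaric species distinct", {
  f <- peptideFormula("VLPVPQKAVPYPQR",
                      data.frame(name = "Lactulosyllysine", position = 7))
  pat <- fineIsotopePattern(f, charge = 3, adduct = "hydrogen")
  # one 13C vs one 15N differ by ~0.0021 at z=3 and must both be present
  expect_true(any(abs(pat$mz - 639.6857) < 2e-4))
  expect_true(any(abs(pat$mz - 639.6836) < 2e-4))
})

test_that("charged patterns shift by the adduct convention", {
  pat0 <- fineIsotopePattern("C10H20O5", charge = 0)
  patP <- fineIsotopePattern("C10H20O5", charge = 2, adduct = "proton")
  patH <- fineIsotopePattern("C10H20O5", charge = 2, adduct = "hydrogen")
  expect_equal(patP$mz, (pat0$mz + 2 * 1.00727646) / 2, tolerance = 1e-9)
  expect_equal(patH$mz - patP$mz,
               rep((1.0078250319 - 1.00727646), nrow(patP)), tolerance = 1e-9)
})
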