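test_that("simulation is deterministic given the seed", {
  cfg <- smallSimConfig(seed = 5)
  a <- simulateRun(cfg, 1, "heated")
  b <- simulateRun(cfg, 1, "heated")
  expect_identical(lapply(a$spectra, scanPeaks), lapply(b$spectra, scanPeaks))
  expect_identical(a$truth, b$truth)
  # different sample index changes the realisation
  c2 <- simulateRun(cfg, 2, "heated")
  expect_false(identical(a$truth$intensity, c2$truth$intensity))
})

test_that("the noise-free limit reproduces truth exactly", {
  markers <- defaultMarkers()[c(1, 2), ]
  markers$rt <- c(15, 30)   # on the scan grid
  cfg <- simulationConfig(markers = markers, nNoise = 0,
                          nPerClass = c(heated = 2, "non-heated" = 2),
                          noiseSdLog = 0, mzSdPpm = 0, rtSdS = 0,
                          rtSpanS = 45, seed = 1)
  run <- simulateRun(cfg, 1, "heated")
  f <- detectFeatures(run$spectra)
  expect_equal(nrow(f), 2L)
  tm <- run$truth[run$truth$marker, ]
  o <- order(f$rt); ot <- order(tm$rt)
  expect_equal(f$mz[o], tm$mz[ot], tolerance = 1e-6)
  expect_equal(f$rt[o], tm$rt[ot])
  expect_equal(f$charge[o], tm$charge[ot])
})

test_that("noise-free envelopes carry the theoretical abundance ratios", {
  markers <- defaultMarkers()[1, ]
  markers$rt <- 20
  cfg <- simulationConfig(markers = markers, nNoise = 0,
                          nPerClass = c(heated = 2, "non-heated" = 2),
                          noiseSdLog = 0, mzSdPpm = 0, rtSdS = 0,
                          rtSpanS = 40, seed = 2)
  run <- simulateRun(cfg, 1, "non-heated")
  low <- Filter(function(s) scanEnergy(s) == "low", run$spectra)
  apex <- low[[which.min(abs(vapply(low, scanRt, numeric(1)) - 20))]]
  pat <- fineIsotopePattern(
    peptideFormula("VLPVPQKAVPYPQR",
                   data.frame(name = "Lactulosyllysine", position = 7)),
    charge = 3, coverage = cfg$coverage)
  got <- vapply(pat$mz, function(m) {
    i <- which.min(abs(apex@mz - m)); apex@intensity[i]
  }, numeric(1))
  expect_equal(got / max(got), pat$abundance / max(pat$abundance),
               tolerance = 1e-6)
})

test_that("a study writes mzML runs, sheet and truth that round-trip", {
  cfg <- smallSimConfig(seed = 3, nNoise = 5)
  dir <- tempfile()
  study <- simulateStudy(cfg, dir = dir)
  sheet <- attr(study, "sampleSheet")
  expect_equal(nrow(sheet), 4L)
  expect_true(all(file.exists(sheet$path)))
  expect_true(file.exists(file.path(dir, "sample_sheet.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  back <- readMseRun(sheet$path[1])
  expect_length(back, length(study[[1]]$spectra))
  i <- which(vapply(study[[1]]$spectra, function(s)
    length(s@mz) > 0, logical(1)))[1]
  expect_equal(scanPeaks(back[[i]]), scanPeaks(study[[1]]$spectra[[i]]),
               tolerance = 1e-6)
  expect_identical(vapply(back, scanEnergy, character(1)),
                   vapply(study[[1]]$spectra, scanEnergy, character(1)))
})

test_that("the full study layout matches the 8+8 design by default", {
  cfg <- simulationConfig(seed = 9)
  expect_equal(unname(cfg$nPerClass), c(8, 8))
  expect_equal(nrow(cfg$markers), 5L)
  expect_equal(cfg$nNoise, 500L)
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, nPerClass = c(heated = 1,
                                                        "non-heated" = 8)),
               "replicates")
})

test_that("planted species outside the instrument range error", {
  markers <- defaultMarkers()[1, ]
  cfg <- simulationConfig(markers = markers, nNoise = 0,
                          nPerClass = c(heated = 2, "non-heated" = 2),
                          mzRange = c(50, 600), rtSpanS = 40, seed = 4)
  expect_error(simulateRun(cfg, 1, "heated"), "outside instrument range")
})
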