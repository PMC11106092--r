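# helper: spectra containing one isotope envelope eluting over some scans
envelopeSpectra <- function(mzs, abund, rts, apexRt, amp = 1e4, fwhm = 10) {
  lapply(seq_along(rts), function(i) {
    g <- amp * exp(-0.5 * ((rts[i] - apexRt) / (fwhm / 2.3548))^2)
    MseSpectrum(rts[i], "low", mzs, g * abund)
  })
}

test_that("a planted doubly charged envelope yields one charge-2 feature", {
  mzs <- 500 + (0:3) * 1.0033548378 / 2
  sp <- envelopeSpectra(mzs, c(1, 0.8, 0.4, 0.15), rts = 1:10, apexRt = 5)
  f <- detectFeatures(sp)
  expect_equal(nrow(f), 1L)
  expect_equal(f$charge, 2L)
  expect_equal(f$mz, 500, tolerance = 1e-6)
  expect_equal(f$rt, 5)
  expect_equal(f$n_traces, 4L)
})

test_that("analytes separated in time become separate features", {
  mzs <- c(400, 410.17)
  sp <- lapply(seq(0, 60, by = 1), function(t) {
    i1 <- 1e4 * exp(-0.5 * ((t - 15) / 4)^2)
    i2 <- 8e3 * exp(-0.5 * ((t - 45) / 4)^2)
    MseSpectrum(t, "low", mzs, c(i1 + 0.01, i2 + 0.01))
  })
  f <- detectFeatures(sp, intensityThreshold = 1)
  expect_equal(nrow(f), 2L)
  expect_equal(sort(f$rt), c(15, 45))
})

test_that("sub-threshold noise produces no features", {
  sp <- lapply(1:10, function(t)
    MseSpectrum(t, "low", c(100, 200, 300), c(1, 1, 1)))
  expect_equal(nrow(detectFeatures(sp, intensityThreshold = 5)), 0L)
  expect_equal(nrow(detectFeatures(list())), 0L)
})

test_that("merging respects the m/z and retention-time tolerances", {
  fA <- data.frame(mz = 500.000, rt = 100, charge = 2L, intensity = 10)
  fB <- data.frame(mz = 500.005, rt = 102, charge = 2L, intensity = 20)
  fs <- mergeFeatures(list(s1 = fA, s2 = fB),
                      c(s1 = "heated", s2 = "non-heated"))
  expect_equal(nrow(fs), 1L)
  expect_false(any(is.nan(intensities(fs))))

  fC <- data.frame(mz = 500.020, rt = 102, charge = 2L, intensity = 20)
  fs2 <- mergeFeatures(list(s1 = fA, s2 = fC),
                       c(s1 = "heated", s2 = "non-heated"))
  expect_equal(nrow(fs2), 2L)
  expect_equal(sum(is.nan(intensities(fs2))), 2L)

  # same m/z but different charge never merges
  fD <- data.frame(mz = 500.000, rt = 100, charge = 1L, intensity = 5)
  fs3 <- mergeFeatures(list(s1 = fA, s2 = fD),
                       c(s1 = "heated", s2 = "non-heated"))
  expect_equal(nrow(fs3), 2L)
})

test_that("merged columns stay within tolerance of their representative", {
  set.seed(13)
  featureList <- lapply(1:6, function(s) {
    n <- 40
    data.frame(mz = runif(n, 100, 1000), rt = runif(n, 0, 300),
               charge = sample(1:3, n, replace = TRUE),
               intensity = rlnorm(n, 10, 1))
  })
  names(featureList) <- paste0("s", 1:6)
  labs <- setNames(rep(c("heated", "non-heated"), 3), names(featureList))
  fs <- mergeFeatures(featureList, labs, mzTol = 0.5, rtTol = 20)
  md <- featureData(fs)
  # re-merging the merged representatives is a fixed point
  relist <- list(all = data.frame(mz = md$mz, rt = md$rt_s,
                                  charge = md$charge, intensity = 1))
  fs2 <- mergeFeatures(relist, c(all = "heated"), mzTol = 0.5, rtTol = 20)
  expect_equal(nrow(fs2), nrow(fs))
  expect_equal(sort(featureData(fs2)$mz), sort(md$mz), tolerance = 1e-9)
})

test_that("feature ids are deterministic under input order permutation", {
  set.seed(4)
  featureList <- lapply(1:3, function(s)
    data.frame(mz = runif(10, 100, 900), rt = runif(10, 0, 100),
               charge = 1L, intensity = rlnorm(10, 8, 1)))
  names(featureList) <- paste0("s", 1:3)
  labs <- setNames(rep("heated", 3), names(featureList))
  fs1 <- mergeFeatures(featureList, labs)
  shuffled <- lapply(featureList, function(df) df[sample(nrow(df)), ])
  fs2 <- mergeFeatures(shuffled, labs)
  expect_equal(featureData(fs1), featureData(fs2))
  expect_equal(intensities(fs1), intensities(fs2))
})

test_that("sample selection excludes standards and validates labels", {
  m <- matrix(1, nrow = 2, ncol = 20,
              dimnames = list(c("FT1", "FT2"), paste0("s", 1:20)))
  labs <- setNames(c(rep(c("heated", "non-heated"), each = 8),
                     rep("standard", 4)), colnames(m))
  fs <- FeatureSet(m, data.frame(mz = c(100, 200), rt_s = c(1, 2),
                                 charge = c(1L, 2L),
                                 row.names = rownames(m)), labs)
  expect_equal(ncol(selectSamples(fs)), 16L)
  expect_equal(ncol(selectSamples(fs, keep = "standard")), 4L)
  expect_error(selectSamples(fs, keep = "unknown"), "unknown")
})

test_that("feature tables round-trip through TSV", {
  m <- matrix(c(1, NaN, 3, 4), nrow = 2,
              dimnames = list(c("FT1", "FT2"), c("a", "b")))
  fs <- FeatureSet(m, data.frame(mz = c(100.5, 200.25), rt_s = c(10, 20),
                                 charge = c(1L, 2L),
                                 row.names = rownames(m)),
                   c(a = "heated", b = "non-heated"))
  d <- tempfile()
  writeFeatureTables(fs, d)
  back <- readFeatureTables(d)
  expect_equal(intensities(back), intensities(fs))
  expect_equal(featureData(back), featureData(fs))
  expect_equal(sampleLabels(back), sampleLabels(fs))
})
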