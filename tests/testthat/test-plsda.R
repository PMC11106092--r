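simData <- function(seed, n = 16, pNoise = 100, nMarkers = 0, fold = 4,
                    sigma = 0.3) {
  set.seed(seed)
  lab <- rep(c("heated", "non-heated"), each = n / 2)
  X <- sapply(seq_len(pNoise), function(j) rlnorm(n, log(2e4), sigma))
  colnames(X) <- sprintf("N%03d", seq_len(pNoise))
  if (nMarkers > 0) {
    M <- sapply(seq_len(nMarkers), function(j)
      5e4 * ifelse(lab == "heated", fold, 1) * rlnorm(n, 0, sigma))
    colnames(M) <- sprintf("M%02d", seq_len(nMarkers))
    X <- cbind(M, X)
  }
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, labels = setNames(lab, rownames(X)))
}

test_that("a perfectly separating feature separates the first score", {
  d <- simData(1, pNoise = 10)
  d$X <- cbind(SEP = ifelse(d$labels == "heated", 100, 0), d$X)
  m <- fitPlsda(d$X, d$labels)
  t1 <- plsdaScores(m)[, 1]
  expect_true(all(sign(t1[d$labels == "heated"]) ==
                    sign(t1[d$labels == "heated"])[1]))
  expect_true(all(t1[d$labels == "heated"] * t1[d$labels == "non-heated"][1] < 0))
})

test_that("scores are orthogonal and weights unit norm", {
  d <- simData(2, nMarkers = 3)
  m <- fitPlsda(d$X, d$labels, ncomp = 2)
  Tm <- plsdaScores(m)
  expect_lt(abs(sum(Tm[, 1] * Tm[, 2])), 1e-8 * sd(Tm[, 1]) * sd(Tm[, 2]) * 16)
  expect_equal(colSums(plsdaWeights(m)^2), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the native fit reproduces the mixOmics reference up to sign", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:30)))
  lab <- setNames(rep(c("A", "B"), each = 10), rownames(X))
  m <- fitPlsda(X, lab, ncomp = 2, scale = TRUE)
  ref <- mixOmics::pls(X, matrix(as.numeric(lab == "B"), ncol = 1),
                       ncomp = 2, scale = TRUE, mode = "regression")
  for (a in 1:2) {
    w <- plsdaWeights(m)[, a]; wr <- ref$loadings$X[, a]
    s <- sign(sum(w * wr))
    expect_equal(w, s * wr, tolerance = 1e-6, ignore_attr = TRUE)
    t <- plsdaScores(m)[, a]; tr <- ref$variates$X[, a]
    expect_equal(t, s * tr, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("VIP scores satisfy the normalisation identity", {
  for (seed in 1:5) {
    d <- simData(seed, nMarkers = 2)
    m <- fitPlsda(d$X, d$labels)
    v <- vipScores(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
})

test_that("identical columns share a VIP of exactly one", {
  set.seed(6)
  x <- rlnorm(16, 10, 1)
  X <- matrix(rep(x, 8), ncol = 8,
              dimnames = list(paste0("s", 1:16), paste0("f", 1:8)))
  lab <- setNames(rep(c("heated", "non-heated"), each = 8), rownames(X))
  m <- fitPlsda(X, lab)
  expect_equal(unname(vipScores(m)), rep(1, 8), tolerance = 1e-8)
})

test_that("VIP ranking is invariant to feature order and global rescaling", {
  d <- simData(8, nMarkers = 5)
  m1 <- fitPlsda(d$X, d$labels)
  r1 <- names(sort(vipScores(m1), decreasing = TRUE))
  perm <- sample(ncol(d$X))
  m2 <- fitPlsda(d$X[, perm], d$labels)
  expect_identical(names(sort(vipScores(m2), decreasing = TRUE)), r1)
  m3 <- fitPlsda(d$X * 1e3, d$labels, scale = TRUE)
  expect_identical(names(sort(vipScores(m3), decreasing = TRUE)), r1)
})

test_that("planted markers outrank noise; permuted labels break the link", {
  hits <- 0; nullHits <- 0
  for (seed in 1:10) {
    d <- simData(seed + 100, pNoise = 100, nMarkers = 5, sigma = 0.2)
    m <- fitPlsda(d$X, d$labels)
    top <- names(sort(vipScores(m), decreasing = TRUE))[1:5]
    hits <- hits + all(grepl("^M", top))
    set.seed(seed)
    permLab <- setNames(sample(d$labels), names(d$labels))
    mp <- fitPlsda(d$X, permLab)
    topP <- names(sort(vipScores(mp), decreasing = TRUE))[1:5]
    nullHits <- nullHits + all(grepl("^M", topP))
  }
  expect_gte(hits, 9)       # real contrast recovers the markers
  expect_lte(nullHits, 1)   # permuted labels do not
})

test_that("NaN cells, zero-variance columns and bad inputs are handled", {
  d <- simData(11, pNoise = 10)
  d$X[1, 3] <- NaN
  d$X <- cbind(d$X, CONST = rep(5, 16))
  expect_warning(m <- fitPlsda(d$X, d$labels), "zero-variance")
  expect_false("CONST" %in% names(vipScores(m)))
  expect_error(fitPlsda(d$X[1:8, ], d$labels[1:8]), "two classes")
  expect_error(vipScores("not a model"), "PLSDAModel")
})

test_that("top-k selection applies the documented tie-breaks", {
  vip <- c(FT2 = 3, FT1 = 3, FT3 = 5)
  md <- data.frame(feature_id = c("FT1", "FT2", "FT3"),
                   mz = c(100, 200, 300), rt_s = c(1, 2, 3),
                   charge = c(1L, 1L, 2L))
  top <- selectTopK(vip, md, k = 2)
  expect_identical(top$feature_id, c("FT3", "FT1"))
  expect_identical(colnames(top), c("feature_id", "mz", "rt_s", "charge", "vip"))
  expect_identical(selectTopK(vip, md, k = 1)$feature_id, "FT3")
  expect_warning(all4 <- selectTopK(vip, md, k = 10), "exceeds")
  expect_equal(nrow(all4), 3L)
})

test_that("class-presence filtering finds exclusive features only", {
  m <- matrix(c(1, NaN, 2, NaN,   # FT1: heated only
                1, 2, 3, 4,       # FT2: both
                NaN, 5, NaN, 6),  # FT3: non-heated only
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("FT", 1:3), paste0("s", 1:4)))
  labs <- setNames(c("heated", "non-heated", "heated", "non-heated"),
                   colnames(m))
  fs <- FeatureSet(m, data.frame(mz = 1:3, rt_s = 1:3, charge = rep(1L, 3),
                                 row.names = rownames(m)), labs)
  res <- classPresenceFilter(fs)
  expect_identical(res$feature_id, c("FT1", "FT3"))
  expect_identical(res$class, c("heated", "non-heated"))
})
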