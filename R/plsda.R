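#' PLSDAModel: a fitted PLS-DA model
#'
#' Partial least squares discriminant analysis for a binary contrast,
#' fitted by the deterministic NIPALS/PLS1 algorithm on a 0/1 class
#' response. Successive score vectors are orthogonal and weight vectors
#' have unit norm.
#'
#' @slot ncomp Number of latent components.
#' @slot weights p x A matrix of X-weights (unit columns).
#' @slot scores n x A matrix of X-scores.
#' @slot xloadings p x A matrix of X-loadings.
#' @slot yloadings Length-A numeric of y-loadings.
#' @slot xmeans,xscales Preprocessing record for the retained features.
#' @slot featureIds Retained feature identifiers.
#' @slot dropped Identifiers of zero-variance features dropped before
#'   fitting.
#' @slot labels Sample class labels in fitting order.
#' @slot classes The two class labels; the second is encoded as y = 1.
#' @export
setClass("PLSDAModel",
  representation(ncomp = "integer", weights = "matrix", scores = "matrix",
                 xloadings = "matrix", yloadings = "numeric",
                 xmeans = "numeric", xscales = "numeric",
                 featureIds = "character", dropped = "character",
                 labels = "character", classes = "character"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@weights) != object@ncomp)
      msg <- c(msg, "weights must have ncomp columns")
    if (length(object@classes) != 2L)
      msg <- c(msg, "exactly two classes required")
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("show", "PLSDAModel", function(object) {
  cat("PLSDAModel:", object@ncomp, "components,",
      length(object@featureIds), "features,",
      length(object@labels), "samples\n")
  cat("  contrast:", object@classes[1], "(y=0) vs",
      object@classes[2], "(y=1)\n")
  if (length(object@dropped))
    cat("  dropped zero-variance features:", length(object@dropped), "\n")
})

#' Fit a PLS-DA model on a feature table
#'
#' The intensity matrix (samples x features) is prepared by replacing `NaN`
#' ("no data available") with 0, mean-centering each feature and, with
#' `scale = TRUE`, dividing by its sample standard deviation; zero-variance
#' features are dropped with a warning. The binary class response is encoded
#' 0/1 and centered, and latent components are extracted by NIPALS (PLS1),
#' which is deterministic.
#'
#' @param x A [FeatureSet-class], or a samples x features matrix.
#' @param labels Class labels per sample (taken from `colData` for a
#'   `FeatureSet` when omitted). Exactly two classes, each with at least two
#'   samples.
#' @param ncomp Number of latent components (default 2).
#' @param scale Unit-variance scaling (default `TRUE`).
#' @return A [PLSDAModel-class].
#' @export
fitPlsda <- function(x, labels = NULL, ncomp = 2, scale = TRUE) {
  if (is(x, "FeatureSet")) {
    if (is.null(labels)) labels <- sampleLabels(x)
    X <- t(intensities(x))
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop("labels required for a plain matrix")
  }
  labels <- as.character(if (!is.null(names(labels)) && !is.null(rownames(X)))
    labels[rownames(X)] else labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required, got: ", paste(classes, collapse = ", "))
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X[is.nan(X) | is.na(X)] <- 0
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped before PLS-DA")
    X <- X[, keep, drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
  }
  if (ncol(X) == 0L) stop("no features left after zero-variance filtering")
  scl <- if (scale) sdv else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, mu), 2L, scl, "/")
  y <- as.numeric(labels == classes[2L])
  yc <- y - mean(y)
  n <- nrow(Xc); p <- ncol(Xc)
  A <- min(ncomp, n - 1L, p)
  W <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A)
  Xd <- Xc; yd <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pA <- crossprod(Xd, t) / tt
    qA <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pA)
    yd <- yd - qA * t
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pA; q[a] <- qA
  }
  if (A < 1L) stop("no informative component could be extracted")
  new("PLSDAModel", ncomp = as.integer(A),
      weights = W[, seq_len(A), drop = FALSE],
      scores = Tm[, seq_len(A), drop = FALSE],
      xloadings = P[, seq_len(A), drop = FALSE],
      yloadings = q[seq_len(A)],
      xmeans = mu, xscales = scl,
      featureIds = colnames(X),
      dropped = setdiff(names(keep)[!keep], character(0)),
      labels = labels, classes = classes)
}

#' @describeIn fitPlsda X-scores (n x A matrix).
#' @param model A [PLSDAModel-class].
#' @export
plsdaScores <- function(model) model@scores

#' @describeIn fitPlsda X-weights (p x A matrix, unit columns).
#' @export
plsdaWeights <- function(model) model@weights

#' Variable importance in projection (VIP) scores
#'
#' For feature j, `vip_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) /
#' sum_a(SSY_a))` with `SSY_a = q_a^2 * (t_a . t_a)`, the y-variance
#' explained by component a. The scores satisfy `mean(vip^2) = 1`. Features
#' dropped before fitting (zero variance) are absent from the result, not
#' reported as zero.
#'
#' @param model A fitted [PLSDAModel-class].
#' @return Named numeric vector of VIP scores, in feature order.
#' @export
vipScores <- function(model) {
  if (!is(model, "PLSDAModel")) stop("vipScores expects a PLSDAModel")
  W <- model@weights
  ssy <- model@yloadings^2 * colSums(model@scores^2)
  p <- nrow(W)
  W2 <- sweep(W, 2L, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.vector(W2 %*% ssy) / sum(ssy))
  setNames(vip, model@featureIds)
}

#' Select the top-k features by VIP score
#'
#' Ranks features by descending VIP score (ties broken by feature id for
#' reproducibility) and joins the per-feature metadata, yielding the
#' marker-candidate report (feature, m/z, retention time, charge, VIP).
#'
#' @param vip Named VIP vector from [vipScores()].
#' @param metadata Per-feature metadata: a [FeatureSet-class] or a data
#'   frame with `feature_id`, `mz`, `rt_s`, `charge`.
#' @param k Number of features to keep (default 5). If `k` exceeds the
#'   number of features, all are returned with a warning.
#' @return Data frame `feature_id, mz, rt_s, charge, vip`, descending by
#'   VIP.
#' @export
selectTopK <- function(vip, metadata = NULL, k = 5) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(vip)) {
    warning("k exceeds the number of features; returning all")
    k <- length(vip)
  }
  ord <- order(-vip, names(vip))
  sel <- names(vip)[ord][seq_len(k)]
  out <- data.frame(feature_id = sel, vip = unname(vip[sel]))
  if (!is.null(metadata)) {
    md <- if (is(metadata, "FeatureSet")) featureData(metadata) else metadata
    out <- merge(out, md[, c("feature_id", "mz", "rt_s", "charge")],
                 by = "feature_id", sort = FALSE)
    out <- out[, c("feature_id", "mz", "rt_s", "charge", "vip")]
  }
  out[order(-out$vip, out$feature_id), , drop = FALSE]
}

#' Features exclusive to one class
#'
#' Reports features whose observed (non-`NaN`) intensities all lie in a
#' single class -- candidate presence/absence markers. The report may be
#' empty.
#'
#' @param x A [FeatureSet-class].
#' @param labels Optional label override (named by sample id).
#' @return Data frame `feature_id, class, n_present`.
#' @export
classPresenceFilter <- function(x, labels = NULL) {
  if (is.null(labels)) labels <- sampleLabels(x)
  m <- intensities(x)
  lab <- labels[colnames(m)]
  classes <- unique(lab)
  out <- list()
  for (i in seq_len(nrow(m))) {
    present <- !is.nan(m[i, ]) & !is.na(m[i, ])
    if (!any(present)) next
    cl <- unique(lab[present])
    if (length(cl) == 1L && length(classes) > 1L)
      out[[length(out) + 1L]] <- data.frame(
        feature_id = rownames(m)[i], class = cl,
        n_present = sum(present))
  }
  if (!length(out))
    return(data.frame(feature_id = character(0), class = character(0),
                      n_present = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
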