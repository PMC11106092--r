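.C13_SHIFT <- 1.0033548378

#' FeatureSet: linked feature-intensity and feature-metadata tables
#'
#' The central data container of the workflow, extending
#' [SummarizedExperiment::SummarizedExperiment]. The `"intensity"` assay
#' holds features (rows) by samples (columns); missing cells are `NaN`
#' ("no data available"). `rowData` carries the per-feature metadata (`mz`,
#' `rt_s`, `charge`), `colData` the sample sheet (`label`, optionally
#' `path`).
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character(0)
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'intensity' is required")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("mz", "rt_s", "charge")
    if (!all(need %in% colnames(rd)))
      msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      msg <- c(msg, "colData must contain 'label'")
    if (length(msg)) msg else TRUE
  })

#' Construct a FeatureSet
#'
#' @param intensity Numeric matrix, features x samples (`NaN` = missing).
#' @param metadata Data frame with one row per feature: `mz`, `rt_s`,
#'   `charge` (row order matching `intensity`).
#' @param labels Named character vector or data frame mapping sample id to
#'   class label (e.g. `"heated"`, `"non-heated"`, `"standard"`).
#' @param paths Optional named character vector of source file paths.
#' @return A [FeatureSet-class].
#' @export
FeatureSet <- function(intensity, metadata, labels, paths = NULL) {
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$sample_id)
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample ids as column names")
  miss <- setdiff(colnames(intensity), names(labels))
  if (length(miss))
    stop("samples missing from the sample sheet: ", paste(miss, collapse = ", "))
  cd <- S4Vectors::DataFrame(sample_id = colnames(intensity),
                             label = unname(labels[colnames(intensity)]),
                             row.names = colnames(intensity))
  if (!is.null(paths)) cd$path <- unname(paths[colnames(intensity)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(metadata, row.names = rownames(intensity)),
    colData = cd)
  new("FeatureSet", se)
}

#' @export
setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object), "features x", ncol(object), "samples\n")
  lab <- table(SummarizedExperiment::colData(object)$label)
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:",
      sum(is.nan(SummarizedExperiment::assay(object, "intensity"))), "\n")
})

#' @describeIn FeatureSet-class Feature intensity matrix (features x
#'   samples; `NaN` = missing).
#' @param x A `FeatureSet`.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn FeatureSet-class Feature identifiers.
#' @export
featureIds <- function(x) rownames(x)

#' @describeIn FeatureSet-class Per-feature metadata (`feature_id`, `mz`,
#'   `rt_s`, `charge`) as a data frame.
#' @export
featureData <- function(x)
  data.frame(feature_id = rownames(x),
             as.data.frame(SummarizedExperiment::rowData(x)),
             row.names = NULL)

#' @describeIn FeatureSet-class Named vector of sample class labels.
#' @export
sampleLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(cd$label, rownames(cd))
}

#' Detect features in the low-energy scans of one run
#'
#' A transparent re-implementation of centroided feature finding in three
#' steps: (1) build mass traces by grouping peaks within `mzTraceTol` across
#' at least `minScans` consecutive low-energy scans; (2) group co-eluting
#' traces into isotope envelopes when spaced by 1.003355/z for some charge z
#' in 1..`maxCharge`, assigning the best-fitting z; (3) report one feature
#' per envelope with the monoisotopic trace's intensity-weighted m/z, the
#' apex-scan retention time and the summed envelope intensity. Traces that
#' join no envelope become charge-1 features with `envelope = FALSE`.
#'
#' @param spectra List of [MseSpectrum-class]; only centroided low-energy
#'   scans are used.
#' @param mzTraceTol Absolute m/z tolerance for trace building and isotope
#'   spacing (default 0.01).
#' @param minScans Minimum consecutive scans per trace (default 3).
#' @param maxCharge Maximum envelope charge considered (default 3).
#' @param intensityThreshold Discard peaks at or below this intensity.
#' @return Data frame with columns `mz`, `rt`, `charge`, `intensity`,
#'   `n_traces`, `envelope`.
#' @export
detectFeatures <- function(spectra, mzTraceTol = 0.01, minScans = 3,
                           maxCharge = 3, intensityThreshold = 0) {
  spectra <- Filter(function(s) scanEnergy(s) == "low", spectra)
  if (!length(spectra)) return(.emptyFeatures())
  spectra <- spectra[order(vapply(spectra, scanRt, numeric(1)))]
  tabs <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    keep <- s@intensity > intensityThreshold
    if (!any(keep)) return(NULL)
    data.table::data.table(scan = i, rt = s@rt,
                           mz = s@mz[keep], intensity = s@intensity[keep])
  })
  pk <- data.table::rbindlist(tabs)
  if (is.null(pk) || nrow(pk) == 0L) return(.emptyFeatures())
  data.table::setorder(pk, mz)
  ## m/z clusters: break where the gap to the previous peak exceeds tolerance
  pk[, clus := cumsum(c(1, diff(mz) > mzTraceTol))]
  ## strongest peak per scan within a cluster
  pk <- pk[order(-intensity)][, head(.SD, 1L), by = .(clus, scan)]
  data.table::setorder(pk, clus, scan)
  ## split clusters into runs of consecutive scans
  pk[, run := cumsum(c(1, diff(scan) > 1)), by = clus]
  traces <- pk[, .(mz = sum(mz * intensity) / sum(intensity),
                   rt = rt[which.max(intensity)],
                   apex = max(intensity), intensity = sum(intensity),
                   scanMin = min(scan), scanMax = max(scan),
                   nScans = .N),
               by = .(clus, run)]
  traces <- traces[nScans >= minScans]
  if (nrow(traces) == 0L) return(.emptyFeatures())
  data.table::setorder(traces, -apex)
  n <- nrow(traces)
  assigned <- rep(FALSE, n)
  feats <- vector("list", 0L)
  mzv <- traces$mz; smin <- traces$scanMin; smax <- traces$scanMax
  for (i in seq_len(n)) {
    if (assigned[i]) next
    best <- NULL
    for (z in seq_len(maxCharge)) {
      members <- i
      k <- 1L
      repeat {
        target <- mzv[i] + k * .C13_SHIFT / z
        cand <- which(!assigned & abs(mzv - target) <= mzTraceTol &
                        smin <= smax[i] & smax >= smin[i])
        if (!length(cand)) break
        members <- c(members, cand[which.min(abs(mzv[cand] - target))])
        k <- k + 1L
      }
      if (is.null(best) || length(members) > length(best$members))
        best <- list(z = z, members = members)
    }
    isEnv <- length(best$members) > 1L
    assigned[best$members] <- TRUE
    feats[[length(feats) + 1L]] <- data.frame(
      mz = traces$mz[i], rt = traces$rt[i],
      charge = if (isEnv) best$z else 1L,
      intensity = sum(traces$intensity[best$members]),
      n_traces = length(best$members), envelope = isEnv)
  }
  out <- do.call(rbind, feats)
  out <- out[order(out$rt, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyFeatures <- function()
  data.frame(mz = numeric(0), rt = numeric(0), charge = integer(0),
             intensity = numeric(0), n_traces = integer(0),
             envelope = logical(0))

## union-find for single-linkage merging
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge features across samples into linked tables
#'
#' Single-linkage clustering of per-sample features that agree in charge and
#' lie within `mzTol` (absolute m/z) and `rtTol` (seconds) of each other.
#' Each cluster becomes one feature column; its representative m/z and
#' retention time are intensity-weighted means over members. Within one
#' sample, co-clustered features are summed; a sample with no member has
#' `NaN`. Feature ids `FT1, FT2, ...` are assigned deterministically after
#' sorting clusters by retention time then m/z.
#'
#' @param featureList Named list (names = sample ids) of data frames from
#'   [detectFeatures()].
#' @param labels Sample sheet: named vector or data frame
#'   (`sample_id`, `label`).
#' @param mzTol Absolute m/z tolerance (default 0.01).
#' @param rtTol Absolute retention-time tolerance in seconds (default 5).
#' @param paths Optional named vector of source paths, stored in `colData`.
#' @return A [FeatureSet-class].
#' @export
mergeFeatures <- function(featureList, labels, mzTol = 0.01, rtTol = 5,
                          paths = NULL) {
  if (is.null(names(featureList)) || anyDuplicated(names(featureList)))
    stop("featureList must be uniquely named by sample id")
  all <- data.table::rbindlist(
    lapply(names(featureList), function(sid) {
      df <- featureList[[sid]]
      if (nrow(df) == 0L) return(NULL)
      data.table::data.table(sample_id = sid, mz = df$mz, rt = df$rt,
                             charge = df$charge, intensity = df$intensity)
    }))
  if (is.null(all) || nrow(all) == 0L)
    stop("no features to merge")
  data.table::setorder(all, mz)
  n <- nrow(all)
  ## candidate pairs within the m/z window (sorted sweep), then filter
  edges <- list()
  j <- 1L
  mzv <- all$mz
  for (i in seq_len(n)) {
    k <- i + 1L
    while (k <= n && mzv[k] - mzv[i] <= mzTol) {
      if (all$charge[k] == all$charge[i] &&
          abs(all$rt[k] - all$rt[i]) <= rtTol)
        edges[[length(edges) + 1L]] <- c(i, k)
      k <- k + 1L
    }
  }
  comp <- .unionFind(n, do.call(rbind, c(edges, list(matrix(0L, 0, 2)))))
  all[, clus := comp]
  ## members of one component share the charge (edges require equality)
  reps <- all[, .(mz = sum(mz * intensity) / sum(intensity),
                  rt = sum(rt * intensity) / sum(intensity)),
              by = .(clus, charge)]
  ## deterministic ids: sort clusters by rt then mz
  data.table::setorder(reps, rt, mz)
  reps[, feature_id := paste0("FT", .I)]
  sampleIds <- names(featureList)
  mat <- matrix(NaN, nrow = nrow(reps), ncol = length(sampleIds),
                dimnames = list(reps$feature_id, sampleIds))
  cells <- all[, .(intensity = sum(intensity)), by = .(clus, sample_id)]
  cells <- merge(cells, reps[, .(clus, feature_id)], by = "clus")
  mat[cbind(match(cells$feature_id, rownames(mat)),
            match(cells$sample_id, colnames(mat)))] <- cells$intensity
  meta <- data.frame(mz = reps$mz, rt_s = reps$rt, charge = reps$charge,
                     row.names = reps$feature_id)
  FeatureSet(mat, meta, labels, paths = paths)
}

#' Subset a FeatureSet to selected sample classes
#'
#' The standard-protein runs support identification but are excluded from
#' the chemometric contrast; this selects the samples to model. Sample order
#' is preserved.
#'
#' @param x A [FeatureSet-class].
#' @param keep Labels to keep (default `c("heated", "non-heated")`).
#' @return A [FeatureSet-class] with the selected columns.
#' @export
selectSamples <- function(x, keep = c("heated", "non-heated")) {
  lab <- sampleLabels(x)
  unknown <- setdiff(keep, unique(lab))
  if (length(unknown))
    stop("no samples with label(s): ", paste(unknown, collapse = ", "))
  sel <- lab %in% keep
  if (!any(sel)) stop("selection is empty")
  x[, sel]
}

#' Write / read the linked feature tables as TSV
#'
#' `writeFeatureTables()` serialises a [FeatureSet-class] as three TSV
#' files: `feature_metadata.tsv` (`feature_id, mz, rt_s, charge`),
#' `feature_intensities.tsv` (`sample_id` plus one column per feature id,
#' missing cells written as `NaN`) and `sample_sheet.tsv`
#' (`sample_id, label, path`). `readFeatureTables()` reads them back.
#'
#' @param x A [FeatureSet-class].
#' @param dir Directory for the three files (created if needed).
#' @return `writeFeatureTables()`: `dir` invisibly; `readFeatureTables()`: a
#'   [FeatureSet-class].
#' @export
writeFeatureTables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- featureData(x)
  write.table(md, file.path(dir, "feature_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  m <- t(intensities(x))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  write.table(df, file.path(dir, "feature_intensities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (!"path" %in% colnames(cd)) cd$path <- NA_character_
  write.table(cd[, c("sample_id", "label", "path")],
              file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeFeatureTables
#' @export
readFeatureTables <- function(dir) {
  md <- read.delim(file.path(dir, "feature_metadata.tsv"))
  it <- read.delim(file.path(dir, "feature_intensities.tsv"),
                   check.names = FALSE)
  sh <- read.delim(file.path(dir, "sample_sheet.tsv"))
  mat <- t(as.matrix(it[, -1, drop = FALSE]))
  colnames(mat) <- it$sample_id
  if (!identical(rownames(mat), md$feature_id))
    stop("intensity and metadata tables disagree on feature columns")
  meta <- data.frame(mz = md$mz, rt_s = md$rt_s, charge = md$charge,
                     row.names = md$feature_id)
  paths <- if ("path" %in% colnames(sh)) setNames(sh$path, sh$sample_id)
  FeatureSet(mat, meta, setNames(sh$label, sh$sample_id), paths = paths)
}
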