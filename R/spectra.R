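#' MseSpectrum: a single low- or high-energy scan
#'
#' A lightweight container for one scan of an MSE (alternating collision
#' energy) run: retention time in seconds, energy level, a peak list and the
#' acquisition mode.
#'
#' @slot rt Retention time in seconds.
#' @slot energy `"low"` (precursor-level) or `"high"` (fragment-level).
#' @slot mz Numeric vector of m/z values, strictly increasing.
#' @slot intensity Numeric vector of non-negative intensities, parallel to
#'   `mz`.
#' @slot mode `"centroid"` or `"profile"`.
#' @export
setClass("MseSpectrum",
  representation(rt = "numeric", energy = "character",
                 mz = "numeric", intensity = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@rt) != 1L || is.na(object@rt))
      msg <- c(msg, "rt must be a single number")
    if (!object@energy %in% c("low", "high"))
      msg <- c(msg, "energy must be 'low' or 'high'")
    if (!object@mode %in% c("centroid", "profile"))
      msg <- c(msg, "mode must be 'centroid' or 'profile'")
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity lengths differ")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
      msg <- c(msg, "mz must be strictly increasing")
    if (any(object@intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct an MseSpectrum
#'
#' Peaks are sorted by m/z; duplicate m/z values have their intensities
#' summed.
#'
#' @param rt Retention time in seconds.
#' @param energy `"low"` or `"high"`.
#' @param mz,intensity Parallel peak vectors.
#' @param mode `"centroid"` (default) or `"profile"`.
#' @return An [MseSpectrum-class] object.
#' @export
MseSpectrum <- function(rt, energy, mz = numeric(0), intensity = numeric(0),
                        mode = "centroid") {
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) > 1L && any(diff(mz) == 0)) {
    agg <- tapply(intensity, mz, sum)
    mz <- as.numeric(names(agg)); intensity <- as.vector(agg)
  }
  new("MseSpectrum", rt = as.numeric(rt), energy = energy,
      mz = as.numeric(mz), intensity = as.numeric(intensity), mode = mode)
}

#' @export
setMethod("show", "MseSpectrum", function(object) {
  cat("MseSpectrum (", object@energy, " energy, ", object@mode, ") rt=",
      format(object@rt, digits = 6), " s, ", length(object@mz), " peaks\n",
      sep = "")
})

#' @describeIn MseSpectrum-class Retention time in seconds.
#' @param x An `MseSpectrum`.
#' @export
scanRt <- function(x) x@rt

#' @describeIn MseSpectrum-class Energy level (`"low"`/`"high"`).
#' @export
scanEnergy <- function(x) x@energy

#' @describeIn MseSpectrum-class Two-column peak matrix (`mz`, `intensity`).
#' @export
scanPeaks <- function(x) cbind(mz = x@mz, intensity = x@intensity)

#' Read an MSE run from an mzML file
#'
#' Loads all MS1 spectra via \pkg{mzR}, converts retention times to seconds
#' (mzR normalises minute-unit attributes on read), sorts by retention time
#' and assigns each scan a collision-energy level. The default
#' `"alternating"` rule labels scans alternately low/high by acquisition
#' order within the run, the MSE cycle structure; `"collision_energy"` uses
#' the collision-energy header field where present (values <=
#' `ceThreshold` eV are low energy).
#'
#' @param path Path to an mzML file.
#' @param energyRule `"alternating"` (default) or `"collision_energy"`.
#' @param ceThreshold Collision-energy cut between low and high (eV),
#'   default 10.
#' @return A list of [MseSpectrum-class] objects sorted by retention time.
#' @export
readMseRun <- function(path, energyRule = c("alternating", "collision_energy"),
                       ceThreshold = 10) {
  energyRule <- match.arg(energyRule)
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot open mzML '", path, "': ",
                                          conditionMessage(e)))
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (is.null(hdr) || nrow(hdr) == 0L) stop("no spectra in '", path, "'")
  pk <- mzR::peaks(fh)
  if (!is.list(pk)) pk <- list(pk)
  ord <- order(hdr$acquisitionNum)
  hdr <- hdr[ord, , drop = FALSE]; pk <- pk[ord]
  if (energyRule == "collision_energy" &&
      !is.null(hdr$collisionEnergy) && !all(is.na(hdr$collisionEnergy))) {
    energy <- ifelse(!is.na(hdr$collisionEnergy) &
                       hdr$collisionEnergy > ceThreshold, "high", "low")
  } else {
    if (energyRule == "collision_energy")
      warning("no collision-energy metadata; falling back to alternating rule")
    energy <- rep(c("low", "high"), length.out = nrow(hdr))
  }
  centroided <- if (!is.null(hdr$centroided)) hdr$centroided else TRUE
  centroided[is.na(centroided)] <- TRUE
  spectra <- lapply(seq_len(nrow(hdr)), function(i)
    MseSpectrum(rt = hdr$retentionTime[i], energy = energy[i],
                mz = pk[[i]][, 1L], intensity = pk[[i]][, 2L],
                mode = if (centroided[i]) "centroid" else "profile"))
  spectra[order(vapply(spectra, scanRt, numeric(1)))]
}

#' Centroid a profile-mode spectrum
#'
#' Picks local maxima over each contiguous above-threshold run of the
#' profile raster, splits runs at valleys between maxima, and reports each
#' peak as the intensity-weighted mean m/z of its points with the apex
#' intensity. Already-centroided spectra are returned unchanged.
#'
#' @param spectrum An [MseSpectrum-class].
#' @param threshold Intensity threshold defining the raster support
#'   (default 0: any positive point).
#' @return A centroid-mode [MseSpectrum-class].
#' @export
centroidSpectrum <- function(spectrum, threshold = 0) {
  if (spectrum@mode == "centroid") return(spectrum)
  mz <- spectrum@mz; int <- spectrum@intensity
  above <- int > threshold
  if (!any(above))
    return(MseSpectrum(spectrum@rt, spectrum@energy, mode = "centroid"))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cmz <- numeric(0); cint <- numeric(0)
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    y <- int[idx]
    n <- length(idx)
    ## local maxima within the run
    isMax <- vapply(seq_len(n), function(i) {
      (i == 1L || y[i] >= y[i - 1L]) && (i == n || y[i] > y[i + 1L])
    }, logical(1))
    maxPos <- which(isMax)
    if (length(maxPos) <= 1L) {
      cmz <- c(cmz, sum(mz[idx] * y) / sum(y))
      cint <- c(cint, max(y))
    } else {
      ## split at the minimum between consecutive maxima
      cuts <- vapply(seq_len(length(maxPos) - 1L), function(k) {
        seg <- maxPos[k]:maxPos[k + 1L]
        seg[which.min(y[seg])]
      }, integer(1))
      grp <- findInterval(seq_len(n), cuts + 0.5) + 1L
      for (g in unique(grp)) {
        sel <- idx[grp == g]
        cmz <- c(cmz, sum(mz[sel] * int[sel]) / sum(int[sel]))
        cint <- c(cint, max(int[sel]))
      }
    }
  }
  MseSpectrum(spectrum@rt, spectrum@energy, cmz, cint, mode = "centroid")
}

#' Write spectra to an mzML file
#'
#' Serialises a list of [MseSpectrum-class] objects to a
#' standards-conformant mzML file via [mzR::writeMSData()]. Round-tripping
#' through [readMseRun()] recovers m/z, intensity and retention time to
#' float precision; the low/high energy labelling is recovered by the
#' alternating-scan rule.
#'
#' @param spectra Non-empty list of [MseSpectrum-class] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMzml <- function(spectra, path) {
  if (!length(spectra)) stop("no spectra to write")
  n <- length(spectra)
  pks <- lapply(spectra, function(s) {
    m <- scanPeaks(s)
    ## mzR's writer requires at least one data point per spectrum
    if (nrow(m) == 0L) m <- cbind(mz = 0, intensity = 0)
    m
  })
  rts <- vapply(spectra, scanRt, numeric(1))
  npk <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n),
    peaksCount = npk,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rts,
    basePeakMZ = vapply(pks, function(p) p[which.max(p[, 2]), 1], numeric(1)),
    basePeakIntensity = vapply(pks, function(p) max(p[, 2]), numeric(1)),
    collisionEnergy = ifelse(vapply(spectra, scanEnergy, character(1)) == "low",
                             4, 30),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pks, function(p) min(p[, 1]), numeric(1)),
    highMZ = vapply(pks, function(p) max(p[, 1]), numeric(1)),
    precursorScanNum = rep(0L, n), precursorMZ = rep(0, n),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(spectra, function(s) s@mode == "centroid", logical(1)),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
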