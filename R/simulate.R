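#' Default planted marker peptides for the synthetic study
#'
#' Five marker species mirroring the kinds of analytes the milk model
#' produces: a lactulosyllysine-modified tryptic peptide, unmodified
#' tryptic peptides, an in-source y-fragment, and an oxidised peptide. All
#' are tryptic products of the synthetic milk-protein FASTA shipped with
#' the package, so the full pipeline can identify them.
#'
#' @return Data frame with columns `sequence`, `mod_name`, `mod_pos`,
#'   `fragment_series`, `fragment_index`, `charge`, `rt`, `base_intensity`,
#'   `fold_change`, `protein`.
#' @export
defaultMarkers <- function() {
  data.frame(
    sequence = c("VLPVPQKAVPYPQR", "HQGLPQEVLNENLLR", "ALPMHIR",
                 "AVPYPQR", "ALPMHIR"),
    mod_name = c("Lactulosyllysine", NA, NA, NA, "Oxidation"),
    mod_pos = c(7L, NA, NA, NA, 4L),
    fragment_series = c(NA, NA, "y", NA, NA),
    fragment_index = c(NA, NA, 3L, NA, NA),
    charge = c(3L, 2L, 1L, 1L, 2L),
    rt = c(25, 40, 55, 70, 85),
    base_intensity = c(5e4, 6e4, 4e4, 5e4, 4.5e4),
    fold_change = rep(4, 5),
    protein = c("beta_casein", "as1_casein", "beta_LG", "beta_casein",
                "beta_LG"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic MSE study generator
#'
#' Defines the simulated study: planted marker species with a
#' heated-class intensity fold change, unstructured noise features, two
#' sample classes with replicate counts, and the instrument/noise model.
#' Defaults emulate the milk study design: 8 heated plus 8 non-heated
#' samples, 5 markers at 4-fold change among 500 noise features, 3 ppm m/z
#' noise, 1 s retention-time noise, and log-normal intensity noise with
#' sigma 0.3.
#'
#' @param markers Data frame of planted species, see [defaultMarkers()].
#' @param nNoise Number of unstructured noise features (default 500).
#' @param nPerClass Named replicate counts (default
#'   `c(heated = 8, "non-heated" = 8)`).
#' @param noiseSdLog Log-normal sigma of between-sample intensity noise
#'   (default 0.3).
#' @param mzSdPpm Gaussian m/z noise in ppm (default 3).
#' @param rtSdS Gaussian retention-time noise in seconds (default 1).
#' @param cycleTimeS Scan cycle time in seconds; each cycle acquires one
#'   low- and one high-energy scan (default 1).
#' @param rtSpanS Gradient span in seconds (default 100).
#' @param peakFwhmS Chromatographic peak FWHM in seconds (default 10).
#' @param fragmentYieldRange Fragment intensity as a uniform fraction of
#'   the precursor apex (default `c(0.05, 0.3)`).
#' @param mzRange Instrument m/z range (default `c(50, 2000)`).
#' @param coverage Isotope-envelope abundance coverage for planted species.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A validated `SimulationConfig` list.
#' @export
simulationConfig <- function(markers = defaultMarkers(), nNoise = 500,
                             nPerClass = c(heated = 8, "non-heated" = 8),
                             noiseSdLog = 0.3, mzSdPpm = 3, rtSdS = 1,
                             cycleTimeS = 1, rtSpanS = 100, peakFwhmS = 10,
                             fragmentYieldRange = c(0.05, 0.3),
                             mzRange = c(50, 2000), coverage = 0.999,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (any(nPerClass < 2)) stop("need >= 2 replicates per class")
  if (noiseSdLog < 0 || mzSdPpm < 0 || rtSdS < 0)
    stop("noise sigmas must be >= 0")
  cfg <- list(markers = markers, nNoise = nNoise, nPerClass = nPerClass,
              noiseSdLog = noiseSdLog, mzSdPpm = mzSdPpm, rtSdS = rtSdS,
              cycleTimeS = cycleTimeS, rtSpanS = rtSpanS,
              peakFwhmS = peakFwhmS, fragmentYieldRange = fragmentYieldRange,
              mzRange = mzRange, coverage = coverage,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

## species-level theoretical quantities for one marker row
.markerSpecies <- function(m, registry = defaultModifications()) {
  mods <- if (!is.na(m$mod_name))
    data.frame(name = m$mod_name, position = m$mod_pos) else NULL
  if (!is.na(m$fragment_series)) {
    ## an in-source fragment: the envelope is that of the fragment's
    ## neutral formula (y_k = C-terminal k residues + H2O)
    L <- nchar(m$sequence)
    sub <- substr(m$sequence, L - m$fragment_index + 1L, L)
    formula <- peptideFormula(sub, NULL)
    label <- paste0(m$fragment_series, m$fragment_index)
  } else {
    formula <- peptideFormula(m$sequence, mods)
    label <- "precursor"
  }
  list(formula = formula, mods = mods, label = label,
       mono_mz = ionMz(monoMass(formula), m$charge))
}

#' Simulate one MSE run
#'
#' Generates the alternating low/high-energy scans of a single sample.
#' Low-energy scans contain each planted species' fine isotope envelope as
#' a Gaussian chromatographic peak plus the noise features; high-energy
#' scans contain the a/b/y fragments of precursor-type markers at seeded
#' uniform yields. Heated-class samples have marker intensities multiplied
#' by the fold change. Deterministic given `config$seed` and
#' `sampleIndex`.
#'
#' @param config A [simulationConfig()].
#' @param sampleIndex Integer index of the sample in the study.
#' @param class `"heated"` or `"non-heated"` (or `"standard"`).
#' @return List with `spectra` (list of [MseSpectrum-class]) and `truth`
#'   (data frame of per-analyte ground truth: `analyte`, `sequence`,
#'   `mod_name`, `mz`, `rt`, `charge`, `intensity`, `marker`).
#' @export
simulateRun <- function(config, sampleIndex, class) {
  stopifnot(inherits(config, "SimulationConfig"))
  ## independent deterministic stream per run
  set.seed((config$seed * 1000L + sampleIndex) %% .Machine$integer.max)
  markers <- config$markers
  nM <- nrow(markers)
  species <- lapply(seq_len(nM), function(i)
    .markerSpecies(markers[i, , drop = FALSE]))
  for (sp in species) {
    if (sp$mono_mz < config$mzRange[1] || sp$mono_mz > config$mzRange[2])
      stop("planted species m/z ", format(sp$mono_mz),
           " outside instrument range")
  }
  ## noise features: fixed positions across the study (seeded from the
  ## study seed only), but sample-specific intensities
  rs <- .Random.seed
  set.seed(config$seed)
  usable <- c(0.15, 0.85) * config$rtSpanS
  noise <- data.frame(
    mz = runif(config$nNoise, 100, 1200),
    rt = runif(config$nNoise, usable[1], usable[2]),
    base = rlnorm(config$nNoise, log(2e4), 0.5))
  .Random.seed <<- rs
  fold <- ifelse(class == "heated", markers$fold_change, 1)
  ## per-sample analyte realisations
  mAmp <- markers$base_intensity * fold *
    rlnorm(nM, 0, config$noiseSdLog)
  mRt <- markers$rt + rnorm(nM, 0, config$rtSdS)
  nAmp <- noise$base * rlnorm(config$nNoise, 0, config$noiseSdLog)
  nRt <- noise$rt + rnorm(config$nNoise, 0, config$rtSdS)
  sigmaT <- config$peakFwhmS / 2.354820045
  cycles <- seq(0, config$rtSpanS, by = config$cycleTimeS)
  yields <- lapply(seq_len(nM), function(i) NULL)
  fragTabs <- vector("list", nM)
  for (i in seq_len(nM)) {
    if (!is.na(markers$fragment_series[i])) next
    mods <- species[[i]]$mods
    fr <- generateFragments(markers$sequence[i], mods, maxCharge = 2)
    fr <- fr[is.na(fr$loss), c("mz", "label")]
    fr$yield <- runif(nrow(fr), config$fragmentYieldRange[1],
                      config$fragmentYieldRange[2])
    fragTabs[[i]] <- fr
  }
  envelopes <- lapply(seq_len(nM), function(i)
    fineIsotopePattern(species[[i]]$formula, charge = markers$charge[i],
                       coverage = config$coverage))
  ppm <- config$mzSdPpm * 1e-6
  spectra <- vector("list", 2L * length(cycles))
  for (ci in seq_along(cycles)) {
    t0 <- cycles[ci]
    ## low energy: marker envelopes + noise features
    mzv <- numeric(0); intv <- numeric(0)
    for (i in seq_len(nM)) {
      g <- exp(-0.5 * ((t0 - mRt[i]) / sigmaT)^2)
      if (g < 1e-3) next
      env <- envelopes[[i]]
      jit <- rnorm(nrow(env), 0, ppm) * env$mz
      mzv <- c(mzv, env$mz + jit)
      intv <- c(intv, mAmp[i] * g * env$abundance / max(env$abundance))
    }
    gNoise <- exp(-0.5 * ((t0 - nRt) / sigmaT)^2)
    on <- gNoise >= 1e-3
    if (any(on)) {
      mzv <- c(mzv, noise$mz[on] * (1 + rnorm(sum(on), 0, ppm)))
      intv <- c(intv, nAmp[on] * gNoise[on])
    }
    spectra[[2L * ci - 1L]] <- MseSpectrum(t0, "low", mzv, intv)
    ## high energy: fragments of precursor markers
    t1 <- t0 + config$cycleTimeS / 2
    mzh <- numeric(0); inth <- numeric(0)
    for (i in seq_len(nM)) {
      fr <- fragTabs[[i]]
      if (is.null(fr)) next
      g <- exp(-0.5 * ((t1 - mRt[i]) / sigmaT)^2)
      if (g < 1e-3) next
      mzh <- c(mzh, fr$mz * (1 + rnorm(nrow(fr), 0, ppm)))
      inth <- c(inth, mAmp[i] * g * fr$yield)
    }
    spectra[[2L * ci]] <- MseSpectrum(t1, "high", mzh, inth)
  }
  truth <- data.frame(analyte = paste0("marker", seq_len(nM)),
                      sequence = markers$sequence,
                      mod_name = markers$mod_name,
                      fragment = vapply(species, `[[`, character(1), "label"),
                      mz = vapply(species, `[[`, numeric(1), "mono_mz"),
                      rt = mRt, charge = markers$charge, intensity = mAmp,
                      marker = TRUE, stringsAsFactors = FALSE)
  if (config$nNoise > 0)
    truth <- rbind(truth, data.frame(
      analyte = paste0("noise", seq_len(config$nNoise)),
      sequence = NA_character_, mod_name = NA_character_,
      fragment = NA_character_, mz = noise$mz, rt = nRt,
      charge = 1L, intensity = nAmp, marker = FALSE,
      stringsAsFactors = FALSE))
  list(spectra = spectra, truth = truth)
}

#' Simulate a full study (all samples)
#'
#' Runs [simulateRun()] for every replicate of every class. With `dir`
#' set, writes one mzML file per sample plus `sample_sheet.tsv`
#' (`sample_id, label, path`) and `ground_truth.tsv`; otherwise the
#' spectra stay in memory.
#'
#' @param config A [simulationConfig()].
#' @param dir Optional output directory.
#' @return Named list per sample with `spectra`, `truth`, `label` (and
#'   `path` when written), plus attributes `sampleSheet`.
#' @export
simulateStudy <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  labels <- rep(names(config$nPerClass), config$nPerClass)
  ids <- unlist(lapply(names(config$nPerClass), function(cl)
    paste0(sub("non-heated", "nonheated", cl), "_",
           seq_len(config$nPerClass[[cl]]))))
  out <- vector("list", length(ids))
  names(out) <- ids
  paths <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    run <- simulateRun(config, i, labels[i])
    run$label <- labels[i]
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(ids[i], ".mzML"))
      writeMzml(run$spectra, path)
      run$path <- path
      paths[i] <- path
    }
    out[[i]] <- run
  }
  sheet <- data.frame(sample_id = ids, label = labels, path = paths,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- do.call(rbind, lapply(ids, function(id)
      cbind(sample_id = id, out[[id]]$truth)))
    write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  attr(out, "sampleSheet") <- sheet
  out
}
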