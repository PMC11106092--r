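.CONFIG_DEFAULTS <- function() list(
  simulate = list(seed = 1L, n_noise = 500L, n_heated = 8L,
                  n_nonheated = 8L, noise_sd_log = 0.3, mz_sd_ppm = 3,
                  rt_sd_s = 1, cycle_time_s = 1, rt_span_s = 100,
                  peak_fwhm_s = 10),
  features = list(mz_trace_tol = 0.01, min_scans = 3L, max_charge = 3L,
                  merge_mz_tol = 0.01, merge_rt_tol = 5),
  chemometrics = list(n_components = 2L, scale = TRUE, k = 5L),
  identification = list(rel_tol = 1e-5, missed_cleavages = 2L,
                        max_mods = 1L, isotope_coverage = 0.9995,
                        rt_window_s = 5, precursor_charges = c(1L, 2L, 3L),
                        fragment_charges = c(1L, 2L)))

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with sections `simulate`, `features`, `chemometrics`
#' and `identification`; every key must be known (unknown keys are
#' rejected by name) and values replace the documented defaults. With
#' `path = NULL` the defaults are returned.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults.
#' @return Nested list of validated settings.
#' @export
pipelineConfig <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  badSec <- setdiff(names(user), names(cfg))
  if (length(badSec))
    stop("unknown config section(s): ", paste(badSec, collapse = ", "))
  for (sec in names(user)) {
    badKey <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badKey))
      stop("unknown key(s) in section '", sec, "': ",
           paste(badKey, collapse = ", "))
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  cfg
}

#' Path to the synthetic milk-protein FASTA shipped with the package
#'
#' A synthetic stand-in for the seven bovine milk proteins of the model
#' system (alpha-s1/s2/beta/kappa-casein, alpha-lactalbumin,
#' beta-lactoglobulin, BSA). The sequences are artificial, but embed the
#' workflow's reference marker peptides in correct tryptic context
#' (VLPVPQKAVPYPQR at position 185-198 of the beta-casein stand-in with a
#' missed cleavage at the internal lysine, HQGLPQEVLNENLLR in the
#' alpha-s1-casein stand-in, ALPMHIR in the beta-lactoglobulin stand-in).
#'
#' @return File path of the FASTA.
#' @export
syntheticMilkFasta <- function()
  system.file("extdata", "synthetic_milk_proteins.fasta",
              package = "mseMarkers", mustWork = TRUE)

#' Generate a synthetic study fixture directory
#'
#' Thin command wrapper over [simulateStudy()]: writes mzML runs, sample
#' sheet and ground truth under `outDir`.
#'
#' @param outDir Output directory.
#' @param config Pipeline configuration list (see [pipelineConfig()]).
#' @return The sample sheet data frame, invisibly.
#' @export
cmdSimulate <- function(outDir, config = pipelineConfig()) {
  s <- config$simulate
  sc <- simulationConfig(
    nNoise = s$n_noise,
    nPerClass = c(heated = s$n_heated, "non-heated" = s$n_nonheated),
    noiseSdLog = s$noise_sd_log, mzSdPpm = s$mz_sd_ppm, rtSdS = s$rt_sd_s,
    cycleTimeS = s$cycle_time_s, rtSpanS = s$rt_span_s,
    peakFwhmS = s$peak_fwhm_s, seed = s$seed)
  study <- simulateStudy(sc, dir = outDir)
  invisible(attr(study, "sampleSheet"))
}

#' Extract and merge features from a sample sheet of mzML runs
#'
#' Loads each run, centroids where needed, detects features in the
#' low-energy scans, merges across samples and writes the linked tables to
#' `outDir`.
#'
#' @param sampleSheet Path to a `sample_sheet.tsv` (columns `sample_id`,
#'   `label`, `path`) or the equivalent data frame.
#' @param outDir Output directory for the feature tables.
#' @param config Pipeline configuration list.
#' @return The [FeatureSet-class], invisibly.
#' @export
cmdFeatures <- function(sampleSheet, outDir = NULL,
                        config = pipelineConfig()) {
  sheet <- if (is.character(sampleSheet)) read.delim(sampleSheet)
           else sampleSheet
  if (nrow(sheet) == 0L) stop("empty sample sheet")
  p <- config$features
  featureList <- list()
  for (i in seq_len(nrow(sheet))) {
    spectra <- readMseRun(sheet$path[i])
    spectra <- lapply(spectra, centroidSpectrum)
    featureList[[sheet$sample_id[i]]] <-
      detectFeatures(spectra, mzTraceTol = p$mz_trace_tol,
                     minScans = p$min_scans, maxCharge = p$max_charge)
  }
  fs <- mergeFeatures(featureList, setNames(sheet$label, sheet$sample_id),
                      mzTol = p$merge_mz_tol, rtTol = p$merge_rt_tol,
                      paths = setNames(sheet$path, sheet$sample_id))
  if (!is.null(outDir)) writeFeatureTables(fs, outDir)
  invisible(fs)
}

#' Select top-VIP marker candidates from feature tables
#'
#' Restricts to the heated/non-heated contrast, fits the PLS-DA model,
#' computes VIP scores and returns the top-k report.
#'
#' @param tables A [FeatureSet-class] or a directory written by
#'   [writeFeatureTables()].
#' @param k Number of features to select (default from config).
#' @param outPath Optional TSV output path for the report.
#' @param config Pipeline configuration list.
#' @return List with `model`, `vip` and `selected` (the top-k table).
#' @export
cmdSelect <- function(tables, k = NULL, outPath = NULL,
                      config = pipelineConfig()) {
  fs <- if (is.character(tables)) readFeatureTables(tables) else tables
  cc <- config$chemometrics
  if (is.null(k)) k <- cc$k
  sub <- selectSamples(fs, keep = c("heated", "non-heated"))
  model <- fitPlsda(sub, ncomp = cc$n_components, scale = cc$scale)
  vip <- vipScores(model)
  sel <- selectTopK(vip, fs, k = k)
  if (!is.null(outPath)) {
    dir.create(dirname(outPath), showWarnings = FALSE, recursive = TRUE)
    write.table(sel, outPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(model = model, vip = vip, selected = sel)
}

#' Identify selected features against a protein FASTA
#'
#' Builds the digest/modification/fragment search space and runs matching
#' plus (when spectra are supplied) isotope and fragment verification.
#'
#' @param selected Data frame (`feature_id`, `mz`, `charge`, optionally
#'   `rt_s`) or TSV path.
#' @param fasta FASTA path(s) for the search space.
#' @param spectra Optional list of [MseSpectrum-class] (one run) for
#'   verification.
#' @param outPath Optional report TSV path.
#' @param config Pipeline configuration list.
#' @return An [IdentificationReport-class].
#' @export
cmdIdentify <- function(selected, fasta, spectra = NULL, outPath = NULL,
                        config = pipelineConfig()) {
  if (is.character(selected)) selected <- read.delim(selected)
  ic <- config$identification
  space <- buildSearchSpace(fasta, missedCleavages = ic$missed_cleavages,
                            maxMods = ic$max_mods,
                            precursorCharges = ic$precursor_charges,
                            fragmentCharges = ic$fragment_charges)
  report <- identifyFeatures(selected, space, spectra,
                             relTol = ic$rel_tol,
                             rtWindow = ic$rt_window_s)
  if (!is.null(outPath)) writeIdentificationReport(report, outPath)
  report
}

#' Run the complete workflow on simulated or real data
#'
#' Convenience driver chaining feature extraction, chemometric selection
#' and identification. `runs` may be an in-memory study from
#' [simulateStudy()] or a sample-sheet path.
#'
#' @param runs In-memory study (from [simulateStudy()]) or sample sheet
#'   path.
#' @param fasta FASTA path(s) for identification.
#' @param config Pipeline configuration list.
#' @return List with `features` ([FeatureSet-class]), `selection` (from
#'   [cmdSelect()]) and `report` ([IdentificationReport-class]).
#' @export
runPipeline <- function(runs, fasta = syntheticMilkFasta(),
                        config = pipelineConfig()) {
  p <- config$features
  if (is.character(runs)) {
    fs <- cmdFeatures(runs, config = config)
    sheet <- read.delim(runs)
    spectra <- readMseRun(sheet$path[1])
  } else {
    featureList <- lapply(runs, function(r)
      detectFeatures(r$spectra, mzTraceTol = p$mz_trace_tol,
                     minScans = p$min_scans, maxCharge = p$max_charge))
    labels <- vapply(runs, `[[`, character(1), "label")
    fs <- mergeFeatures(featureList, setNames(labels, names(runs)),
                        mzTol = p$merge_mz_tol, rtTol = p$merge_rt_tol)
    ## verification spectra: a heated sample carries the strongest signal
    spectra <- runs[[which(labels == "heated")[1]]]$spectra
  }
  selection <- cmdSelect(fs, config = config)
  sel <- selection$selected
  report <- cmdIdentify(sel[, c("feature_id", "mz", "charge", "rt_s")],
                        fasta, spectra = spectra, config = config)
  list(features = fs, selection = selection, report = report)
}
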