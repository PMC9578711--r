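pipelineDefaults <- function() {
  list(
    mode = "synthetic",
    seed = NULL,
    outDir = NULL,
    cohort = list(nDonors = 6L, phenotypes = c("M1", "M2"),
                  treatments = "FCCP", cellsPerField = 24L,
                  fieldsPerCondition = 3L, imageSize = 128L,
                  cellRadius = 6L, photonsPerCell = 42000,
                  background = 0.02),
    featureCsv = NULL,
    fit = list(minPhotons = 500, weighting = "neyman",
               background = "free", chi2Gate = 1.3),
    segmentation = list(enabled = TRUE, sigma = 1, minArea = 20L,
                        clearBorder = TRUE),
    classification = list(treatment = "FCCP",
                          ntree = c(50L, 100L, 150L, 200L, 250L, 300L,
                                    400L, 500L),
                          mtry = NULL, maxnodes = 8L,
                          trainFraction = 0.75),
    flux = list(enabled = FALSE, noiseSd = 1, nReplicates = 3L),
    phasor = list(enabled = TRUE, tauLong = 3.4, tauShort = 0.4))
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopValidation("unknown configuration key(s): %s",
                   paste0(path, unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]],
                                     paste0(path, key, "."))
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a list, or a path to a YAML/JSON document, and returns a fully
#' defaulted, type-checked configuration. Unknown keys are rejected, a
#' seed is mandatory (every stochastic stage derives its own stream from
#' it), and exactly one input mode must be active.
#'
#' @param document list, or path to a `.yaml`/`.yml`/`.json` file
#' @return validated configuration list of class `PipelineConfig`
#' @export
validateConfig <- function(document) {
  if (is.character(document)) {
    document <- if (grepl("\\.ya?ml$", document))
      yaml::read_yaml(document)
    else jsonlite::read_json(document, simplifyVector = TRUE)
  }
  cfg <- mergeConfig(pipelineDefaults(), document)
  if (is.null(cfg$seed))
    stopValidation("a seed is required (stochastic stages: simulate, classify)")
  if (!cfg$mode %in% c("synthetic", "feature_csv"))
    stopValidation("mode must be 'synthetic' or 'feature_csv'")
  if (cfg$mode == "synthetic" && !is.null(cfg$featureCsv))
    stopValidation("two input modes set: synthetic cohort and featureCsv")
  if (cfg$mode == "feature_csv" && is.null(cfg$featureCsv))
    stopValidation("feature_csv mode requires featureCsv paths")
  if (cfg$cohort$cellsPerField < 1L)
    stopValidation("cellsPerField must be >= 1")
  if (cfg$cohort$nDonors < 1L)
    stopValidation("nDonors must be >= 1")
  if (cfg$classification$trainFraction <= 0 ||
      cfg$classification$trainFraction >= 1)
    stopValidation("trainFraction must lie in (0, 1)")
  structure(cfg, class = "PipelineConfig")
}

reportToList <- function(report) {
  list(ntree = report@ntree, mtry = report@mtry,
       oob_error_pct = report@oobError, roc_auc = report@rocAuc,
       confusion = as.list(report@confusion), split = report@split,
       seed = report@seed,
       importance = report@importance)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the inputs,
#' fit full-field and per-cell decays, compute phasor coordinates, segment
#' cells and aggregate features, train the OOB-tuned full-field
#' random-forests model and the donor-specific single-cell models, and
#' (optionally) compute extracellular-flux rates. All tables are
#' materialised as CSV/JSON in `outDir`; the run is deterministic given
#' the configuration seed. Fields are processed one at a time so the full
#' cohort is never held in memory.
#'
#' @param config a [validateConfig()]-validated configuration (lists and
#'   file paths are validated on the fly)
#' @return a `RunReport` list: counts per stage, the full-FoV
#'   [RFModelReport-class], per-donor reports, the file manifest and the
#'   configuration echo
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  if (is.null(config$outDir))
    stopValidation("outDir is required to run the pipeline")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  fitOpt <- fitOptions(minPhotons = config$fit$minPhotons,
                       weighting = config$fit$weighting,
                       background = config$fit$background,
                       chi2Gate = config$fit$chi2Gate)

  if (config$mode == "synthetic") {
    cohortArgs <- config$cohort
    cohortArgs$seed <- config$seed
    cfg <- do.call(cohortConfig, cohortArgs)
    acq <- flimAcquisition(imageSize = cfg$imageSize)
    fullRows <- list(); cellRows <- list(); phasorRows <- list(); k <- 0L
    for (donor in seq_len(cfg$nDonors))
      for (phenotype in cfg$phenotypes)
        for (field in seq_len(cfg$fieldsPerCondition))
          for (treatment in cfg$treatments) {
            k <- k + 1L
            stack <- simulateField(cfg, donor, phenotype, treatment, field)
            ids <- data.frame(donor = donor, phenotype = phenotype,
                              treatment = treatment, field_id = field)
            ff <- fitField(stack, "full_fov", options = fitOpt)
            fullRows[[k]] <- cbind(ids, cell_id = NA_integer_,
                                   ff[, -1, drop = FALSE])
            if (isTRUE(config$segmentation$enabled)) {
              m <- histogramMatrix(stack)
              total <- matrix(rowSums(m), cfg$imageSize, cfg$imageSize)
              lm <- segmentCells(total, sigma = config$segmentation$sigma,
                                 minArea = config$segmentation$minArea,
                                 clearBorder = config$segmentation$clearBorder)
              feats <- aggregateCellFeatures(lm, stack, options = fitOpt)
              cellRows[[k]] <- feats
              if (isTRUE(config$phasor$enabled) && nCells(lm) > 0) {
                ph <- do.call(rbind, lapply(seq_len(nCells(lm)), function(i) {
                  h <- aggregateHistogram(stack, lm@labels == i, m = m)
                  phasorTransform(h, acq)
                }))
                ph$chord_fraction <- chordFraction(
                  ph, acq, tauLong = config$phasor$tauLong,
                  tauShort = config$phasor$tauShort)
                phasorRows[[k]] <- cbind(ids[rep(1, nrow(ph)), ],
                                         cell_id = seq_len(nrow(ph)), ph)
              }
            }
          }
    fullFov <- do.call(rbind, fullRows)
    singleCell <- if (length(cellRows)) do.call(rbind, cellRows) else NULL
    phasorTab <- if (length(phasorRows)) do.call(rbind, phasorRows) else NULL
  } else {
    fullFov <- readFeatureTable(config$featureCsv$fullFov)
    singleCell <- if (!is.null(config$featureCsv$singleCell))
      readFeatureTable(config$featureCsv$singleCell) else NULL
    phasorTab <- NULL
  }

  files <- character(0)
  wf <- function(obj, name) {
    p <- file.path(config$outDir, name)
    writeFeatureTable(obj, p)
    files <<- c(files, p)
  }
  wf(fullFov, "features_fullfov.csv")
  if (!is.null(singleCell)) wf(singleCell, "features_singlecell.csv")
  if (!is.null(phasorTab)) wf(phasorTab, "phasor.csv")

  grid <- rfSearchGrid(ntree = config$classification$ntree,
                       mtry = config$classification$mtry,
                       maxnodes = config$classification$maxnodes)
  tabFull <- buildFeatureTable(fullFov, "full_fov",
                               treatment = config$classification$treatment)
  fullReport <- trainRFOOBGrid(tabFull$x, tabFull$y, grid,
                               deriveSeed(config$seed, "fullfov_rf"))
  donorReports <- if (!is.null(singleCell))
    runDonorModels(singleCell, grid, deriveSeed(config$seed, "donor_rf"),
                   treatment = config$classification$treatment,
                   trainFraction = config$classification$trainFraction)
  else list()

  fluxRates <- NULL
  if (isTRUE(config$flux$enabled)) {
    groups <- list(M1 = cbind(ecar = c(20, 35, 30, 28, 5),
                              ocr = c(40, 20, 55, 10, 10)),
                   M2 = cbind(ecar = c(10, 16, 14, 13, 4),
                              ocr = c(45, 25, 95, 12, 12)))
    fluxRates <- do.call(rbind, lapply(names(groups), function(gp) {
      series <- simulateFluxSeries(groups[[gp]],
                                   noiseSd = config$flux$noiseSd,
                                   nReplicates = config$flux$nReplicates,
                                   seed = deriveSeed(config$seed, gp, "flux"),
                                   group = gp)
      do.call(rbind, lapply(series, computeFluxRates))
    }))
    wf(fluxRates, "flux_rates.csv")
  }

  reportPath <- file.path(config$outDir, "model_reports.json")
  jsonlite::write_json(
    list(full_fov = reportToList(fullReport),
         donors = lapply(donorReports, reportToList)),
    reportPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, reportPath)

  nFailed <- function(x) if (!is.null(x) && "failed" %in% names(x))
    sum(x$failed) else 0L
  counts <- list(
    fields = if (config$mode == "synthetic") k else NA_integer_,
    fullfov_rows = nrow(fullFov),
    fullfov_failed = nFailed(fullFov),
    singlecell_rows = if (is.null(singleCell)) 0L else nrow(singleCell),
    singlecell_failed = nFailed(singleCell),
    donors_modelled = length(donorReports))
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(
    list(package = "flimMacro",
         version = as.character(utils::packageVersion("flimMacro")),
         seed = config$seed, counts = counts, files = files,
         config = unclass(config)),
    manifestPath, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, manifestPath)

  structure(list(fullFovReport = fullReport, donorReports = donorReports,
                 fluxRates = fluxRates, counts = counts, files = files,
                 config = config),
            class = "RunReport")
}
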