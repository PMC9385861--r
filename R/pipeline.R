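## End-to-end orchestration: simulate -> align -> assign -> preprocess ->
## metrics -> ordinate -> network -> isotopes, driven by a serializable
## config with explicit seeds, writing stage outputs and a JSON run report
## with feature counts at every filter step.

#' Pipeline configuration
#'
#' Collects every stage toggle, threshold and seed in one serializable list.
#' Defaults reproduce the package's reference analysis conditions.
#'
#' @param stages character vector of stages to run (subset of simulate,
#'   align, assign, preprocess, metrics, ordinate, network, isotopes).
#' @param tolPpm join/assignment tolerance (ppm).
#' @param mdl method detection limit on signal-to-noise.
#' @param minOccurrence occurrence filter threshold (samples).
#' @param minSamples network prevalence threshold (samples).
#' @param minAbundance minimum ASV relative abundance.
#' @param cutoff |rho| cutoff for the network; \code{NA} selects it by
#'   permutation FDR.
#' @param nPerm permutations for FDR / ordination tests.
#' @param targetFdr target FDR for cutoff selection.
#' @param k NMDS dimensions.
#' @param nStarts NMDS random starts.
#' @param seed master integer seed.
#' @param nSamplesSim,nFormulasPerClass synthetic-data sizes.
#' @param ionMode \code{"neg"} or \code{"neutral"} (see
#'   \code{\link{assignmentParams}}).
#' @param paths named list of input paths (used when \code{"simulate"} is
#'   not among the stages): \code{peakDir}, \code{asvTable},
#'   \code{chemistry}, \code{grouping}, \code{abios}, \code{isotopes}.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(stages = c("simulate", "align", "assign",
                                      "preprocess", "metrics", "ordinate",
                                      "network", "isotopes"),
                           tolPpm = 0.5, mdl = 3, minOccurrence = 3,
                           minSamples = 5, minAbundance = 0.001,
                           cutoff = NA, nPerm = 99, targetFdr = 0.05,
                           k = 2, nStarts = 20, seed = 1,
                           nSamplesSim = 12, nFormulasPerClass = 8,
                           ionMode = "neg", paths = list()) {
  stopifnot(tolPpm > 0, mdl >= 0, minOccurrence >= 0, minSamples >= 0,
            minAbundance >= 0, nPerm >= 0, targetFdr > 0, targetFdr < 1,
            k >= 1, nStarts >= 1)
  structure(list(stages = stages, tolPpm = tolPpm, mdl = mdl,
                 minOccurrence = minOccurrence, minSamples = minSamples,
                 minAbundance = minAbundance, cutoff = cutoff,
                 nPerm = nPerm, targetFdr = targetFdr, k = k,
                 nStarts = nStarts, seed = seed,
                 nSamplesSim = nSamplesSim,
                 nFormulasPerClass = nFormulasPerClass,
                 ionMode = ionMode, paths = paths),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration
#'
#' YAML (\code{.yml}/\code{.yaml}) or JSON by file extension; round-trips
#' losslessly.
#'
#' @param path file path.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$paths <- as.list(raw$paths)
  if (!is.null(raw$cutoff) && is.character(raw$cutoff))
    raw$cutoff <- as.numeric(raw$cutoff)
  if (is.null(raw$cutoff)) raw$cutoff <- NA
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  ext <- tolower(sub(".*\\.", "", path))
  x <- unclass(config)
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order and writes every stage output
#' plus a JSON run report (seeds, thresholds, and feature counts before and
#' after each filtering step) to \code{outDir}. Reruns with the same config
#' are deterministic.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @return the run report (list), invisibly; also written as
#'   \code{report.json}.
#' @export
runPipeline <- function(config, outDir = tempfile("deepdom_run_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  on <- function(stage) stage %in% config$stages
  report <- list(seed = config$seed,
                 thresholds = config[c("tolPpm", "mdl", "minOccurrence",
                                       "minSamples", "minAbundance",
                                       "targetFdr")],
                 stages = config$stages, counts = list(), outputs = list(),
                 skipped = setdiff(c("simulate", "align", "assign",
                                     "preprocess", "metrics", "ordinate",
                                     "network", "isotopes"),
                                   config$stages))
  peakLists <- NULL; chem <- NULL; asvSim <- NULL; truth <- NULL

  if (on("simulate")) .stageError("simulate", {
    lib <- generateFormulaLibrary(config$nFormulasPerClass,
                                  seed = config$seed)
    sim <- .demoMixingSimulation(lib, config$nSamplesSim,
                                 seed = config$seed,
                                 ionMode = config$ionMode)
    peakLists <- sim$peakLists; chem <- sim$chemistry; truth <- sim$truth
    writeSyntheticData(sim, file.path(outDir, "synthetic"))
    report$counts$simulated_formulas <- nrow(sim$truth$formulas)
    report$counts$simulated_samples <- length(peakLists)
  })
  if (is.null(peakLists) && !is.null(config$paths$peakDir))
    .stageError("align", {
      files <- list.files(config$paths$peakDir, pattern = "\\.csv$",
                          full.names = TRUE)
      peakLists <- lapply(files, readPeakList)
      names(peakLists) <- vapply(peakLists, attr, "", "sampleId")
    })
  if (!is.null(config$paths$chemistry) && is.null(chem))
    chem <- utils::read.csv(config$paths$chemistry)

  aligned <- NULL
  if (on("align")) .stageError("align", {
    if (is.null(peakLists)) stop("no peak lists available")
    aligned <- joinMassLists(peakLists, tolPpm = config$tolPpm)
    report$counts$features_aligned <- nrow(aligned)
    aligned <- removeSingletons(aligned)
    report$counts$features_after_singleton_removal <- nrow(aligned)
    writeAlignedMatrix(aligned, file.path(outDir, "aligned.csv"))
  })

  annotated <- NULL
  if (on("assign")) .stageError("assign", {
    if (is.null(aligned)) stop("no aligned matrix available")
    params <- assignmentParams(tolPpm = config$tolPpm, mdl = config$mdl,
                               ionMode = config$ionMode)
    annotated <- assignFormulas(aligned, params)
    report$counts$features_assigned <-
      sum(formulaData(annotated)$assigned)
    report$counts$features_contaminant_removed <-
      metadata(annotated)$nContaminantsRemoved
    report$counts$features_after_assignment <- nrow(annotated)
  })

  if (on("preprocess")) .stageError("preprocess", {
    if (is.null(annotated)) stop("no annotated matrix available")
    annotated <- normalizeToSum(annotated)
    annotated <- harmonizeDetectionLimit(annotated)
    report$counts$detection_limit <- metadata(annotated)$detectionLimit
    annotated <- occurrenceFilter(annotated,
                                  minSamples = config$minOccurrence)
    report$counts$features_after_occurrence_filter <- nrow(annotated)
    writeAnnotatedMatrix(annotated, file.path(outDir, "annotated.tsv"))
  })

  if (on("metrics")) .stageError("metrics", {
    if (is.null(annotated)) stop("no annotated matrix available")
    annotated <- addFormulaMetrics(annotated)
    summ <- weightedSampleSummary(annotated)
    utils::write.csv(summ, file.path(outDir, "sample_summaries.csv"),
                     row.names = FALSE)
    report$outputs$sample_summaries <- "sample_summaries.csv"
  })

  if (on("ordinate")) .stageError("ordinate", {
    if (is.null(annotated)) stop("no annotated matrix available")
    d <- brayCurtis(annotated)
    writeDistanceMatrix(d, file.path(outDir, "bray_curtis.csv"))
    nm <- runNMDS(d, k = config$k, nStarts = config$nStarts,
                  seed = config$seed)
    utils::write.csv(data.frame(sample = rownames(nm$points), nm$points),
                     file.path(outDir, "nmds.csv"), row.names = FALSE)
    ord <- list(nmds_stress = nm$stress, nmds_converged = nm$converged)
    if (!is.null(chem)) {
      pred <- chem[match(sampleIds(annotated), chem$sample),
                   intersect(.CHEM_VARS, colnames(chem)), drop = FALSE]
      db <- runDbRDA(d, pred, nPerm = config$nPerm, seed = config$seed)
      ord$dbrda <- db
    }
    jsonlite::write_json(ord, file.path(outDir, "ordination.json"),
                         auto_unbox = TRUE, digits = NA)
    report$outputs$ordination <- "ordination.json"
  })

  if (on("network")) .stageError("network", {
    if (is.null(annotated)) stop("no annotated matrix available")
    sim <- generateInterdomainData(nSamples = ncol(annotated),
                                   seed = config$seed + 1)
    flt <- prevalenceFilter(sim$mf, sim$asv,
                            minSamples = min(config$minSamples,
                                             ncol(sim$mf)),
                            minAbundance = config$minAbundance)
    report$counts$network_mfs <- nrow(flt$mf)
    report$counts$network_asvs <- nrow(flt$asv)
    mfClr <- clrTransform(replaceZeros(flt$mf))
    asvClr <- clrTransform(replaceZeros(flt$asv))
    cutoff <- config$cutoff
    if (is.na(cutoff))
      cutoff <- fdrCutoff(mfClr, asvClr, nPerm = max(config$nPerm, 10),
                          targetFdr = config$targetFdr,
                          seed = config$seed)$cutoff
    rho <- proportionalityRho(rbind(mfClr, asvClr))
    kinds <- c(rep("MF", nrow(mfClr)), rep("ASV", nrow(asvClr)))
    net <- buildNetwork(rho, kinds, cutoff = cutoff)
    if (nrow(networkEdges(net))) {
      net <- greedyModularity(net)
      net <- nodeRoles(net)
    }
    writeNetwork(net, file.path(outDir, "network.graphml"),
                 file.path(outDir, "network_edges.tsv"))
    report$counts$network_nodes <- nrow(networkNodes(net))
    report$counts$network_edges <- nrow(networkEdges(net))
    report$counts$network_cutoff <- cutoff
    if (!is.na(modularityScore(net)))
      report$counts$network_modularity <- modularityScore(net)
  })

  if (on("isotopes")) .stageError("isotopes", {
    path <- config$paths$isotopes
    wc <- if (!is.null(path)) utils::read.csv(path, comment.char = "#")
          else readWaterChemistry()
    gw <- wc$water_type != "Baltic Sea"
    iso <- data.frame(
      group = c("groundwater", "baltic"),
      mean_extraction_efficiency =
        c(mean(wc$extraction_efficiency[gw]),
          mean(wc$extraction_efficiency[!gw])))
    utils::write.csv(iso, file.path(outDir, "extraction_efficiency.csv"),
                     row.names = FALSE)
    report$outputs$extraction_efficiency <- "extraction_efficiency.csv"
  })

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

## reference two-endmember demo simulation used by the simulate stage and
## the examples: a lignin-dominated Baltic-like endmember versus an
## aliphatic, S-enriched saline endmember
.demoMixingSimulation <- function(formulaLib, nSamples = 12, seed = 1,
                                  ionMode = "neg", noiseCv = 0.05,
                                  massErrorPpm = 0.2) {
  shared <- formulaLib
  ligninHeavy <- ifelse(shared$class == "lignin-like", 3,
                        ifelse(shared$class %in%
                                 c("tannin-like", "condensed aromatics"),
                               1.5, 0.5))
  aliphatic <- ifelse(shared$class %in%
                        c("unsaturated oxygen-poor",
                          "unsaturated hydrocarbon-like"), 2.5,
                      ifelse(shared$class == "lignin-like", 1.2, 0.4))
  emA <- endmemberSpec(
    "Baltic-like", shared, ligninHeavy / sum(ligninHeavy),
    chem = c(na = 1500, k = 60, ca = 90, mg = 220, d18o = -6, d2h = -55,
             so4 = 470, cl = 3400), docMgL = 5.4)
  emB <- endmemberSpec(
    "Saline-like", shared, aliphatic / sum(aliphatic),
    chem = c(na = 3000, k = 12, ca = 5200, mg = 31, d18o = -12, d2h = -95,
             so4 = 600, cl = 14500), docMgL = 0.9)
  fractions <- seq(1, 0, length.out = nSamples)
  generateSamplePeakLists(list(emA, emB), fractions,
                          massErrorPpm = massErrorPpm, noiseCv = noiseCv,
                          mode = ionMode, seed = seed)
}
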