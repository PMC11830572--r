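#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic cohort, the contrast, the
#' retention filter, DhMR thresholds, the split, stability selection and the
#' classifier.
#'
#' @slot sim \linkS4class{SimConfig} for the synthetic cohort.
#' @slot contrast ordered group pair; the second entry is the positive class
#'   and fold changes are relative to the first.
#' @slot minSamples,maxWidth retention filter (support > minSamples,
#'   width < maxWidth).
#' @slot lfcMin,pMax DhMR thresholds.
#' @slot trainFraction split ratio (2:1 by default).
#' @slot nRounds,nRepeats,minRounds,withinRoundRule stability selection.
#' @slot stepFraction,lambdaGrid RFE and penalized logistic settings.
#' @slot topVarianceK rows entering PCA.
#' @slot seed global seed (split, folds, rounds derive their own streams).
#' @export
setClass("PipelineConfig", representation(
  sim = "SimConfig",
  contrast = "character",
  minSamples = "integer",
  maxWidth = "integer",
  lfcMin = "numeric",
  pMax = "numeric",
  trainFraction = "numeric",
  nRounds = "integer",
  nRepeats = "integer",
  minRounds = "integer",
  withinRoundRule = "numeric",
  stepFraction = "numeric",
  lambdaGrid = "numeric",
  topVarianceK = "integer",
  seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (length(object@contrast) != 2L ||
      !all(object@contrast %in% names(object@sim@groupSizes)))
    msg <- c(msg, "contrast must name two groups present in the sim config")
  if (object@lfcMin < 0 || object@pMax <= 0 || object@pMax > 1)
    msg <- c(msg, "thresholds must be positive (pMax in (0,1])")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param contrast ordered group pair (reference, positive).
#' @param minSamples,maxWidth,lfcMin,pMax,trainFraction,nRounds,nRepeats,minRounds,withinRoundRule,stepFraction,lambdaGrid,topVarianceK,seed
#'   see the class slots.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), contrast = c("PC", "MLM"),
                           minSamples = 10L, maxWidth = 1000L,
                           lfcMin = 0.5, pMax = 0.01, trainFraction = 2 / 3,
                           nRounds = 5L, nRepeats = 100L, minRounds = 3L,
                           withinRoundRule = 0.5, stepFraction = 0.1,
                           lambdaGrid = .defaultLambdaGrid,
                           topVarianceK = 50L, seed = 1L) {
  new("PipelineConfig", sim = sim, contrast = contrast,
      minSamples = as.integer(minSamples), maxWidth = as.integer(maxWidth),
      lfcMin = lfcMin, pMax = pMax, trainFraction = trainFraction,
      nRounds = as.integer(nRounds), nRepeats = as.integer(nRepeats),
      minRounds = as.integer(minRounds), withinRoundRule = withinRoundRule,
      stepFraction = stepFraction, lambdaGrid = lambdaGrid,
      topVarianceK = as.integer(topVarianceK), seed = as.integer(seed))
}

# size factors for validation samples against a training-derived reference,
# so no validation statistic leaks into training artifacts
.sfAgainstReference <- function(counts, refLogGeo) {
  ok <- is.finite(refLogGeo)
  apply(log(counts[ok, , drop = FALSE]) - refLogGeo[ok], 2L, function(v)
    exp(median(v[is.finite(v)])))
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> merge/filter regions -> annotate -> metagene -> split ->
#' DhMR calling on the training cohort -> stability-consensus selection ->
#' final model -> validation metrics -> survival stratification, writing all
#' intermediate artifacts under \code{outDir} and a machine-readable
#' \code{report.json} whose counts are validated against the artifacts.
#' Deterministic given the config (two runs produce byte-identical reports).
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir output directory (created if needed).
#' @return The run report, invisibly (also written as JSON).
#' @export
runPipeline <- function(config, outDir = tempfile("portal5hmc_run")) {
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "peaks"), showWarnings = FALSE)

  ## stage 1: simulate
  cohort <- simulateCohort(config@sim)
  exp <- cohort$experiment
  regionsOut <- cohort$regions
  names(regionsOut) <- paste(names(cohort$regions),
                             mcols(cohort$regions)$feature, sep = "|")
  writeBed(regionsOut, file.path(outDir, "regions.bed"))
  writeGeneModels(cohort$genes, file.path(outDir, "genes.bed12"))
  writeCountMatrix(exp, file.path(outDir, "counts.tsv"),
                   file.path(outDir, "library_sizes.tsv"))
  writeSampleTable(SummarizedExperiment::colData(exp),
                   file.path(outDir, "samples.tsv"))
  truth <- cohort$truth
  .writeTsv(data.frame(region = names(truth@trueLog2fc),
                       true_log2fc = truth@trueLog2fc,
                       true_dispersion = truth@trueDispersion,
                       differential = as.integer(
                         names(truth@trueLog2fc) %in% truth@differentialRegionIds)),
            file.path(outDir, "truth.tsv"))
  writeBedGraph(cohort$coverage, file.path(outDir, "coverage.bedGraph"))
  for (s in names(cohort$peaks))
    writeBed(cohort$peaks[[s]], file.path(outDir, "peaks", paste0(s, ".bed")))

  ## stage 2: regions
  merged <- mergePeaks(cohort$peaks)
  writeBed(merged, file.path(outDir, "merged_regions.bed"))
  retained <- filterRegions(merged, config@minSamples, config@maxWidth)
  quant <- .quantifyRegions(retained, exp)
  annotated <- annotateRegions(rowRanges(quant), cohort$genes)
  featDist <- featureDistribution(annotated)
  .writeTsv(data.frame(region = names(annotated),
                       chrom = as.character(seqnames(annotated)),
                       start = start(annotated) - 1L, end = end(annotated),
                       support = mcols(annotated)$support,
                       feature = mcols(annotated)$feature,
                       nearest_gene = mcols(annotated)$nearest_gene,
                       tss_distance = mcols(annotated)$tss_distance),
            file.path(outDir, "retained_regions.tsv"))

  ## stage 3: metagene
  prof <- metageneProfile(cohort$coverage, cohort$genes)
  .writeTsv(profileTable(prof), file.path(outDir, "metagene.tsv"))

  ## stage 4: split (contrast groups only)
  cd <- SummarizedExperiment::colData(exp)
  inContrast <- cd$group %in% config@contrast
  ids <- colnames(exp)[inContrast]
  grp <- factor(cd$group[inContrast], levels = config@contrast)
  split <- splitCohort(ids, grp, config@trainFraction, seed = config@seed)
  cnt <- SummarizedExperiment::assay(quant, "counts")
  trainIdx <- match(split$train, colnames(cnt))
  validIdx <- match(split$validation, colnames(cnt))
  yTrain <- factor(cd[split$train, "group"], levels = config@contrast)
  yValid <- factor(cd[split$validation, "group"], levels = config@contrast)

  ## stage 5: differential on the training cohort
  cntTr <- cnt[, trainIdx, drop = FALSE]
  sfTr <- medianOfRatios(cntTr)
  disp <- estimateDispersion(cntTr, sfTr, yTrain)
  res <- nbWaldTest(cntTr, sfTr, yTrain, disp)
  calls <- callDhmrs(res, config@lfcMin, config@pMax)
  res$call <- ifelse(res$id %in% calls$up, "up",
                     ifelse(res$id %in% calls$down, "down", "ns"))
  .writeTsv(res, file.path(outDir, "dhmr.tsv"))
  dhmrIds <- sort(c(calls$up, calls$down))

  ## stage 6-7: stability selection + final model
  allPos <- rowSums(cntTr == 0) == 0
  refLogGeo <- ifelse(allPos, rowMeans(log(cntTr)), NA_real_)
  sfVal <- .sfAgainstReference(cnt[, validIdx, drop = FALSE], refLogGeo)
  Xtrain <- markerFeatures(cntTr, sfTr)
  Xvalid <- markerFeatures(cnt[, validIdx, drop = FALSE], sfVal)
  panel <- NULL
  model <- NULL
  metrics <- list(trainingAuc = NA_real_, validationAuc = NA_real_,
                  sensitivity = NA_real_, specificity = NA_real_)
  panelDf <- data.frame(marker = character(0), rounds_observed = integer(0),
                        mean_frequency = numeric(0))
  perMarker <- data.frame(feature = character(0), auc = numeric(0))
  topMarker <- NA_character_
  if (length(dhmrIds) >= 1) {
    panel <- stabilitySelect(Xtrain[, dhmrIds, drop = FALSE], yTrain,
                             nRounds = config@nRounds,
                             nRepeats = config@nRepeats,
                             withinRoundRule = config@withinRoundRule,
                             minRounds = config@minRounds,
                             stepFraction = config@stepFraction,
                             lambdaGrid = config@lambdaGrid,
                             seed = config@seed)
    panelDf <- data.frame(marker = names(roundsObserved(panel)),
                          rounds_observed = unname(roundsObserved(panel)),
                          mean_frequency = rowMeans(selectionFrequencies(panel)))
    if (length(panelMarkers(panel))) {
      model <- trainFinalModel(Xtrain[, panelMarkers(panel), drop = FALSE],
                               yTrain, lambdaGrid = config@lambdaGrid,
                               seed = config@seed)
      pTr <- predictProbability(model, Xtrain)
      pVa <- predictProbability(model, Xvalid)
      cm <- confusionAt(pVa, yValid)
      metrics <- list(trainingAuc = roc(pTr, yTrain)$auc,
                      validationAuc = roc(pVa, yValid)$auc,
                      sensitivity = cm$sensitivity,
                      specificity = cm$specificity)
      perMarker <- perFeatureAuc(Xvalid[, panelMarkers(panel), drop = FALSE],
                                 yValid)
      topMarker <- panelMarkers(panel)[which.max(abs(model@weights))]
      jsonlite::write_json(list(markers = model@markerIds,
                                weights = model@weights,
                                intercept = model@intercept,
                                lambda = model@lambda,
                                center = model@featureCenter,
                                scale = model@featureScale,
                                positive_class = model@classLevels[2]),
                           file.path(outDir, "model.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  .writeTsv(panelDf, file.path(outDir, "panel.tsv"))

  ## stage 8: descriptive analyses
  sfAll <- medianOfRatios(cnt)
  logNorm <- log2(sweep(cnt, 2L, sfAll, "/") + 1)
  k <- min(config@topVarianceK, nrow(logNorm))
  pca <- pcaAnalysis(t(topVariance(logNorm[, inContrast, drop = FALSE], k)))
  survMarker <- if (!is.na(topMarker)) topMarker else truth@survivalMarkerId
  logrank <- list(chi2 = NA_real_, pvalue = NA_real_)
  if (survMarker %in% rownames(logNorm)) {
    lvl <- logNorm[survMarker, ]
    hl <- dichotomize(lvl)
    logrank <- kmLogrank(cd$os_months, cd$os_event, hl)[c("chi2", "pvalue")]
  }

  report <- list(
    stages = list(
      regions_simulated = length(cohort$regions),
      regions_merged = length(merged),
      regions_retained = length(retained),
      dhmr_up = length(calls$up),
      dhmr_down = length(calls$down),
      panel_size = if (is.null(panel)) 0L else length(panelMarkers(panel))
    ),
    metrics = c(metrics, list(
      per_marker_auc = if (nrow(perMarker))
        structure(as.list(perMarker$auc), names = perMarker$feature)
      else structure(list(), names = character(0)),
      top_marker = topMarker,
      logrank_chi2 = logrank$chi2,
      logrank_pvalue = logrank$pvalue,
      pca_explained = pca$explained,
      feature_proportions = structure(as.list(featDist$proportion),
                                      names = featDist$feature)
    )),
    provenance = list(
      seed = config@seed,
      package_version = as.character(utils::packageVersion("portal5hmc")),
      config_hash = unname(tools::md5sum(
        .writeConfigJson(config, file.path(outDir, "config.json"))))
    )
  )
  .validateReport(report, outDir)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.writeConfigJson <- function(config, path) {
  sim <- config@sim
  simList <- lapply(slotNames(sim), function(s) slot(sim, s))
  names(simList) <- slotNames(sim)
  cfg <- lapply(setdiff(slotNames(config), "sim"),
                function(s) slot(config, s))
  names(cfg) <- setdiff(slotNames(config), "sim")
  jsonlite::write_json(c(list(sim = simList), cfg), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

# every reported count must equal the corresponding artifact's row count
.validateReport <- function(report, outDir) {
  nRows <- function(f) length(readLines(file.path(outDir, f)))
  chk <- function(val, expect, what) {
    if (val != expect)
      stop("report/artifact mismatch for ", what, ": ", val, " vs ", expect)
  }
  chk(report$stages$regions_simulated, nRows("regions.bed"), "regions.bed")
  chk(report$stages$regions_merged, nRows("merged_regions.bed"),
      "merged_regions.bed")
  chk(report$stages$regions_retained, nRows("retained_regions.tsv") - 1L,
      "retained_regions.tsv")
  dh <- utils::read.delim(file.path(outDir, "dhmr.tsv"))
  chk(report$stages$dhmr_up, sum(dh$call == "up"), "dhmr.tsv up calls")
  chk(report$stages$dhmr_down, sum(dh$call == "down"), "dhmr.tsv down calls")
  if (report$stages$panel_size > 0) {
    mj <- jsonlite::read_json(file.path(outDir, "model.json"))
    chk(report$stages$panel_size, length(mj$markers), "model.json markers")
  }
  invisible(TRUE)
}
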