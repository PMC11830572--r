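#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' Simulation configuration for a synthetic 5hmC cohort
#'
#' Holds every parameter of the synthetic-data generator: genome layout
#' (chromosomes, gene models, candidate hMRs with planted feature labels),
#' the negative-binomial count model with planted differential regions,
#' per-sample peak emission, gene-body coverage with a TSS dip, and
#' exponential survival with a hazard tied to a marker's level.
#'
#' Counts for region \eqn{i} in sample \eqn{j} are drawn from
#' \eqn{NB(\mu = q_i s_j 2^{\beta_i x_j}, \alpha_i)} where \eqn{x_j}
#' indicates membership of the second (metastasis-like) group, \eqn{s_j} is a
#' log-normal library-size factor, and \eqn{\beta_i} (log2 units) is zero for
#' all but a planted fraction of regions.
#'
#' @slot seed integer; master seed, sub-generators use fixed offsets.
#' @slot nChromosomes,nGenes,nRegions integer sizes.
#' @slot chromosomeLength integer; bp per chromosome, 0 = sized automatically
#'   from the gene complement.
#' @slot geneLengthRange,regionWidthRange integer pairs (bp, low <= high).
#' @slot featureMix named numeric over promoter/exon/intron/intergenic,
#'   summing to 1 (intron-heavy by default, as observed for cfDNA hMRs).
#' @slot groupSizes named integer; cohort sizes per group (default
#'   PC 70, MLM 32, SLM 31).
#' @slot fracDifferential fraction of regions with a planted group effect.
#' @slot lfcMagnitudeRange |log2 fold change| range for planted effects.
#' @slot dispersionRange NB dispersion (alpha) range.
#' @slot baselineLogMean,baselineLogSd log-normal baseline abundance q_i.
#' @slot libsizeLogMean,libsizeLogSd log-normal library-size factor s_j.
#' @slot peakPresenceThreshold reads; a sample emits a peak for a region iff
#'   its count reaches this threshold.
#' @slot survivalBaselineHazard,survivalHazardRatio,censorRate exponential
#'   survival model: hazard = baseline * HR^{I(level > median)}; independent
#'   exponential censoring.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  nGenes = "integer",
  chromosomeLength = "integer",
  geneLengthRange = "integer",
  nRegions = "integer",
  regionWidthRange = "integer",
  featureMix = "numeric",
  groupSizes = "integer",
  fracDifferential = "numeric",
  lfcMagnitudeRange = "numeric",
  dispersionRange = "numeric",
  baselineLogMean = "numeric",
  baselineLogSd = "numeric",
  libsizeLogMean = "numeric",
  libsizeLogSd = "numeric",
  peakPresenceThreshold = "numeric",
  survivalBaselineHazard = "numeric",
  survivalHazardRatio = "numeric",
  censorRate = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chkRange <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      sprintf("%s must be an ordered pair low <= high", nm) else character()
  }
  msg <- c(msg,
           chkRange(object@geneLengthRange, "geneLengthRange"),
           chkRange(object@regionWidthRange, "regionWidthRange"),
           chkRange(object@lfcMagnitudeRange, "lfcMagnitudeRange"),
           chkRange(object@dispersionRange, "dispersionRange"))
  mix <- object@featureMix
  want <- c("promoter", "exon", "intron", "intergenic")
  if (!setequal(names(mix), want))
    msg <- c(msg, "featureMix must be named over promoter/exon/intron/intergenic")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "featureMix proportions must be non-negative and sum to 1")
  if (any(object@groupSizes < 2L))
    msg <- c(msg, "groupSizes must all be >= 2")
  if (is.null(names(object@groupSizes)) || anyDuplicated(names(object@groupSizes)))
    msg <- c(msg, "groupSizes must have unique group names")
  if (object@fracDifferential < 0 || object@fracDifferential > 1)
    msg <- c(msg, "fracDifferential must lie in [0, 1]")
  if (any(object@dispersionRange <= 0))
    msg <- c(msg, "dispersionRange must be positive")
  if (object@survivalHazardRatio <= 0)
    msg <- c(msg, "survivalHazardRatio must be positive")
  if (object@censorRate < 0 || object@survivalBaselineHazard <= 0)
    msg <- c(msg, "survival rates must be non-negative (baseline > 0)")
  if (object@peakPresenceThreshold < 0)
    msg <- c(msg, "peakPresenceThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate the portal-venous-blood cohort analysed downstream:
#' three groups sized 70/32/31 (primary cancer, metachronous and synchronous
#' liver metastasis), intron-enriched region placement, a planted fraction of
#' differential regions with |log2FC| >= 0.5, and log-normal library sizes.
#'
#' @param seed integer master seed.
#' @param nChromosomes,nGenes,nRegions,chromosomeLength genome sizing.
#' @param geneLengthRange,regionWidthRange bp pairs.
#' @param featureMix named proportions over promoter/exon/intron/intergenic.
#' @param groupSizes named integer vector of cohort sizes.
#' @param fracDifferential,lfcMagnitudeRange,dispersionRange count model.
#' @param baselineLogMean,baselineLogSd,libsizeLogMean,libsizeLogSd log-normal
#'   parameters for baseline abundance and library-size factors.
#' @param peakPresenceThreshold reads needed for a sample to emit a peak.
#' @param survivalBaselineHazard,survivalHazardRatio,censorRate survival model
#'   (per-month rates).
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 20L, nRegions = 50L)
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 3L,
                      nGenes = 150L,
                      chromosomeLength = 0L,
                      geneLengthRange = c(6000L, 20000L),
                      nRegions = 600L,
                      regionWidthRange = c(150L, 900L),
                      featureMix = c(promoter = 0.08, exon = 0.12,
                                     intron = 0.55, intergenic = 0.25),
                      groupSizes = c(PC = 70L, MLM = 32L, SLM = 31L),
                      fracDifferential = 0.05,
                      lfcMagnitudeRange = c(0.5, 2),
                      dispersionRange = c(0.05, 0.3),
                      baselineLogMean = log(60),
                      baselineLogSd = 0.8,
                      libsizeLogMean = 0,
                      libsizeLogSd = 0.25,
                      peakPresenceThreshold = 5,
                      survivalBaselineHazard = 0.02,
                      survivalHazardRatio = 3,
                      censorRate = 0.015) {
  new("SimConfig",
      seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      nGenes = as.integer(nGenes),
      chromosomeLength = as.integer(chromosomeLength),
      geneLengthRange = as.integer(geneLengthRange),
      nRegions = as.integer(nRegions),
      regionWidthRange = as.integer(regionWidthRange),
      featureMix = featureMix[c("promoter", "exon", "intron", "intergenic")],
      groupSizes = structure(as.integer(groupSizes), names = names(groupSizes)),
      fracDifferential = fracDifferential,
      lfcMagnitudeRange = as.numeric(lfcMagnitudeRange),
      dispersionRange = as.numeric(dispersionRange),
      baselineLogMean = baselineLogMean,
      baselineLogSd = baselineLogSd,
      libsizeLogMean = libsizeLogMean,
      libsizeLogSd = libsizeLogSd,
      peakPresenceThreshold = peakPresenceThreshold,
      survivalBaselineHazard = survivalBaselineHazard,
      survivalHazardRatio = survivalHazardRatio,
      censorRate = censorRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "\n")
  cat(" genome:", object@nChromosomes, "chromosomes,",
      object@nGenes, "genes,", object@nRegions, "candidate regions\n")
  cat(" groups:", paste(names(object@groupSizes), object@groupSizes,
                        sep = "=", collapse = ", "), "\n")
  cat(" differential:", format(object@fracDifferential), "of regions, |lfc| in [",
      paste(format(object@lfcMagnitudeRange), collapse = ", "), "]\n")
})

#' Planted ground truth of a synthetic cohort
#'
#' @slot differentialRegionIds region ids with a planted group effect.
#' @slot trueLog2fc named numeric; planted log2 fold change per region
#'   (0 for null regions).
#' @slot trueDispersion named numeric; planted NB dispersion per region.
#' @slot baselineMean named numeric; planted baseline abundance q per region.
#' @slot predictiveMarkerIds region ids predictive of group membership
#'   (a subset of the differential ids).
#' @slot survivalMarkerId id of the region whose level drives the simulated
#'   hazard ("" when survival was not simulated).
#' @export
setClass("GroundTruth", representation(
  differentialRegionIds = "character",
  trueLog2fc = "numeric",
  trueDispersion = "numeric",
  baselineMean = "numeric",
  predictiveMarkerIds = "character",
  survivalMarkerId = "character"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@predictiveMarkerIds %in% object@differentialRegionIds))
    msg <- c(msg, "predictiveMarkerIds must be a subset of differentialRegionIds")
  nz <- names(object@trueLog2fc)[abs(object@trueLog2fc) > 0]
  if (!all(nz %in% object@differentialRegionIds))
    msg <- c(msg, "every region with nonzero trueLog2fc must be differential")
  if (any(object@trueDispersion <= 0))
    msg <- c(msg, "trueDispersion must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@trueLog2fc), "regions,",
      length(object@differentialRegionIds), "differential,",
      length(object@predictiveMarkerIds), "predictive\n")
})

#' Regions-by-samples 5hmC count container
#'
#' A \linkS4class{RangedSummarizedExperiment} with a single "counts" assay of
#' non-negative integers, hMR coordinates as row ranges, the sample table as
#' column data, and per-sample library sizes (total mapped reads, which may
#' exceed the in-region column sums) in \code{colData()$library_size}.
#'
#' @export
setClass("HmcExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("HmcExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "region ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"library_size" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry a library_size column")
  else {
    ls <- SummarizedExperiment::colData(object)$library_size
    if (any(!is.finite(ls)) || any(ls <= 0))
      msg <- c(msg, "library sizes must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an HmcExperiment
#'
#' @param counts integer matrix, regions x samples, with rownames (region ids)
#'   and colnames (sample ids).
#' @param regions \link[GenomicRanges]{GRanges} parallel to rows (optional;
#'   unnamed placeholder ranges are used when absent).
#' @param sampleData data.frame / DataFrame of per-sample annotation.
#' @param librarySizes positive numeric per sample; defaults to column sums.
#' @return An \linkS4class{HmcExperiment}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("r", 1:3), paste0("s", 1:4)))
#' he <- HmcExperiment(m)
#' @export
HmcExperiment <- function(counts, regions = NULL, sampleData = NULL,
                          librarySizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    stop("counts must have rownames (region ids)")
  if (is.null(colnames(counts)))
    stop("counts must have colnames (sample ids)")
  if (is.null(regions)) {
    regions <- GRanges(rep("un", nrow(counts)),
                       IRanges(start = seq_len(nrow(counts)), width = 1))
    names(regions) <- rownames(counts)
  }
  if (is.null(names(regions))) names(regions) <- rownames(counts)
  if (!identical(names(regions), rownames(counts)))
    stop("regions must be named identically to counts rownames")
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(counts))
        else DataFrame(sampleData, row.names = colnames(counts))
  if (is.null(librarySizes)) {
    if (!"library_size" %in% colnames(cd))
      cd$library_size <- colSums(counts)
  } else {
    cd$library_size <- librarySizes
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = regions, colData = cd)
  new("HmcExperiment", se)
}

#' @describeIn HmcExperiment per-sample library sizes (total mapped reads).
#' @param x an HmcExperiment.
#' @export
librarySizes <- function(x) SummarizedExperiment::colData(x)$library_size

setMethod("show", "HmcExperiment", function(object) {
  cat("HmcExperiment with", nrow(object), "regions x", ncol(object), "samples\n")
  callNextMethod()
})

#' Stability-consensus marker panel
#'
#' Result of 5-round / 100-repeat recursive-feature-elimination stability
#' selection: per-round selection frequencies for every candidate marker, the
#' per-marker count of rounds in which it was "observed" (selected in at least
#' \code{withinRoundRule} of the round's repeats), and the retained panel
#' (observed in at least \code{minRounds} rounds).
#'
#' @slot markers retained marker ids (the panel), lexicographically sorted.
#' @slot roundsObserved named integer; rounds observed, for every candidate.
#' @slot frequencies numeric matrix, candidates x rounds, selection frequency.
#' @slot minRounds,withinRoundRule the consensus thresholds applied.
#' @export
setClass("MarkerPanel", representation(
  markers = "character",
  roundsObserved = "integer",
  frequencies = "matrix",
  minRounds = "integer",
  withinRoundRule = "numeric"
))

setValidity("MarkerPanel", function(object) {
  msg <- character()
  ro <- object@roundsObserved
  if (is.null(names(ro)))
    msg <- c(msg, "roundsObserved must be named by marker id")
  if (any(ro < 0L) || any(ro > ncol(object@frequencies)))
    msg <- c(msg, "roundsObserved out of [0, n_rounds]")
  expected <- sort(names(ro)[ro >= object@minRounds])
  if (!identical(sort(object@markers), expected))
    msg <- c(msg, "markers must be exactly those observed in >= minRounds rounds")
  if (length(msg)) msg else TRUE
})

#' @describeIn MarkerPanel retained marker ids.
#' @param x a MarkerPanel.
#' @export
panelMarkers <- function(x) x@markers

#' @describeIn MarkerPanel per-candidate count of rounds observed.
#' @export
roundsObserved <- function(x) x@roundsObserved

#' @describeIn MarkerPanel candidates x rounds selection-frequency matrix.
#' @export
selectionFrequencies <- function(x) x@frequencies

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", length(object@markers), "markers retained (",
      ">=", object@minRounds, "of", ncol(object@frequencies), "rounds )\n")
  if (length(object@markers))
    cat(" ", paste(utils::head(object@markers, 10), collapse = ", "),
        if (length(object@markers) > 10) "..." else "", "\n")
})

#' Penalized logistic classifier over a marker panel
#'
#' L2-penalized logistic regression with optional balanced class weights;
#' features are standardized with training-cohort statistics frozen into the
#' model (\code{featureCenter}, \code{featureScale}).
#'
#' @slot markerIds ordered feature ids.
#' @slot weights coefficient per marker (standardized scale).
#' @slot intercept scalar intercept.
#' @slot lambda L2 penalty strength used.
#' @slot featureCenter,featureScale training-cohort standardization.
#' @slot classWeighting "balanced" or "none".
#' @slot classLevels length-2 character; classLevels[2] is the positive class.
#' @export
setClass("HmcClassifier", representation(
  markerIds = "character",
  weights = "numeric",
  intercept = "numeric",
  lambda = "numeric",
  featureCenter = "numeric",
  featureScale = "numeric",
  classWeighting = "character",
  classLevels = "character"
))

setValidity("HmcClassifier", function(object) {
  msg <- character()
  p <- length(object@markerIds)
  if (length(object@weights) != p ||
      length(object@featureCenter) != p || length(object@featureScale) != p)
    msg <- c(msg, "weights/center/scale must match markerIds in length")
  if (any(object@featureScale <= 0))
    msg <- c(msg, "featureScale must be positive")
  if (length(object@classLevels) != 2L)
    msg <- c(msg, "classLevels must have length 2")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn HmcClassifier feature ids used by the model.
#' @param x an HmcClassifier.
#' @export
markerIds <- function(x) x@markerIds

#' @describeIn HmcClassifier coefficients on the standardized feature scale.
#' @export
classifierWeights <- function(x) structure(x@weights, names = x@markerIds)

setMethod("show", "HmcClassifier", function(object) {
  cat("HmcClassifier:", length(object@markerIds), "markers, lambda =",
      format(object@lambda), ", class weighting:", object@classWeighting, "\n")
  cat(" positive class:", object@classLevels[2], "\n")
})

#' Metagene coverage profile
#'
#' Mean per-bp coverage (RPM) in fixed-width flank bins and length-scaled gene
#' body bins, 5'-to-3' oriented.
#'
#' @slot values ordered bin values (upstream, body, downstream).
#' @slot upstreamBins,bodyBins,downstreamBins bin counts.
#' @slot flank flank width in bp.
#' @slot nGenes genes averaged; @slot nSkipped genes skipped (too short).
#' @export
setClass("MetageneProfile", representation(
  values = "numeric",
  upstreamBins = "integer",
  bodyBins = "integer",
  downstreamBins = "integer",
  flank = "numeric",
  nGenes = "integer",
  nSkipped = "integer"
))

setValidity("MetageneProfile", function(object) {
  n <- object@upstreamBins + object@bodyBins + object@downstreamBins
  msg <- character()
  if (length(object@values) != n)
    msg <- c(msg, "values length must equal total bin count")
  if (any(object@values < 0)) msg <- c(msg, "profile values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn MetageneProfile the bin values in 5'-to-3' order.
#' @param x a MetageneProfile.
#' @export
profileValues <- function(x) x@values

#' @describeIn MetageneProfile values of the gene-body bins only.
#' @export
bodyValues <- function(x)
  x@values[seq(x@upstreamBins + 1L, x@upstreamBins + x@bodyBins)]

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile:", object@upstreamBins, "+", object@bodyBins, "+",
      object@downstreamBins, "bins (flank", object@flank, "bp),",
      object@nGenes, "genes (", object@nSkipped, "skipped )\n")
})
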