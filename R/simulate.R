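#' @importFrom GenomicRanges GRanges promoters findOverlaps coverage
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqinfo
#' @importFrom stats rnbinom rexp rlnorm runif median
NULL

# segment a gene of length L into n_ex exons and n_ex-1 introns (>= minSeg bp
# each), first segment starting at 0, last ending at L; returns exon IRanges
# relative to the gene start (0 offset -> caller shifts)
.segmentGene <- function(L, n_ex, minSeg = 150L) {
  k <- 2L * n_ex - 1L
  while (k > 1L && L < k * minSeg) {
    n_ex <- n_ex - 1L
    k <- 2L * n_ex - 1L
  }
  if (n_ex == 1L) return(IRanges(1L, L))
  rem <- L - k * minSeg
  props <- rexp(k)
  wds <- minSeg + floor(rem * props / sum(props))
  wds[k] <- L - sum(wds[-k])
  ends <- cumsum(wds)
  starts <- c(1L, ends[-k] + 1L)
  keep <- seq(1L, k, by = 2L)  # odd segments are exons
  IRanges(starts[keep], ends[keep])
}

#' Simulate gene models and candidate hMRs with planted feature labels
#'
#' Places non-overlapping, stranded, multi-exon genes on a small synthetic
#' genome and then places mutually disjoint candidate regions whose planted
#' genomic-feature label (promoter / exon / intron / intergenic) follows
#' \code{featureMix} under the annotation rules used downstream (promoter =
#' TSS +/- 2 kb with any-overlap priority; midpoint containment otherwise;
#' downstream = up to 3 kb past the TTS, avoided for intergenic placement).
#' Intron-heavy defaults reflect the observed enrichment of cfDNA hMRs in
#' introns.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param promoterHalfwidth bp, promoter window half-width (default 2000).
#' @return list with \code{genes} (GRanges with \code{exons} IRangesList
#'   mcol, seqlengths set) and \code{regions} (disjoint named GRanges with a
#'   planted \code{feature} mcol).
#' @export
simulateGenome <- function(config, promoterHalfwidth = 2000L) {
  validObject(config)
  .withSeed(.deriveSeed(config@seed, "genome"), {
    nchr <- config@nChromosomes
    chroms <- sprintf("chrS%d", seq_len(nchr))
    geneChrom <- rep(seq_len(nchr), length.out = config@nGenes)
    glr <- config@geneLengthRange
    gapRange <- c(9000L, 18000L)
    geneList <- vector("list", config@nGenes)
    chromEnds <- integer(nchr)
    gi <- 0L
    for (ci in seq_len(nchr)) {
      cursor <- 10000L
      for (g in which(geneChrom == ci)) {
        gi <- gi + 1L
        L <- sample(glr[1]:glr[2], 1L)
        gap <- sample(gapRange[1]:gapRange[2], 1L)
        gstart <- cursor + gap
        n_ex <- sample(2:8, 1L)
        ex <- IRanges::shift(.segmentGene(L, n_ex), gstart - 1L)
        geneList[[gi]] <- list(chrom = chroms[ci], start = gstart,
                               end = gstart + L - 1L,
                               strand = sample(c("+", "-"), 1L), exons = ex)
        cursor <- gstart + L - 1L
      }
      chromEnds[ci] <- cursor + 15000L
    }
    if (config@chromosomeLength > 0L) {
      if (any(chromEnds > config@chromosomeLength))
        stop("cannot place ", config@nGenes, " genes of length up to ",
             glr[2], " bp in chromosomes of length ", config@chromosomeLength)
      chromEnds <- rep(config@chromosomeLength, nchr)
    }
    sinfo <- GenomeInfoDb::Seqinfo(chroms, chromEnds)
    genes <- GRanges(vapply(geneList, `[[`, "", "chrom"),
                     IRanges(vapply(geneList, function(g) g$start, 0L),
                             vapply(geneList, function(g) g$end, 0L)),
                     strand = vapply(geneList, `[[`, "", "strand"),
                     seqinfo = sinfo)
    names(genes) <- sprintf("gene%04d", seq_along(genes))
    mcols(genes)$exons <- IRangesList(lapply(geneList, `[[`, "exons"))

    # interval tables (plain integers, keyed by chromosome) mirroring the
    # annotation rules downstream; promoter windows match
    # GenomicRanges::promoters() on either strand
    hw <- as.integer(promoterHalfwidth)
    plus <- as.character(strand(genes)) == "+"
    tss <- tssPositions(genes)
    gchr <- as.character(seqnames(genes))
    exn <- mcols(genes)$exons
    chrTab <- function(s, e, chr)
      lapply(split(data.frame(s = s, e = e), factor(chr, chroms)), as.list)
    promBy <- chrTab(pmax(1L, ifelse(plus, tss - hw, tss - hw + 1L)),
                     ifelse(plus, tss + hw - 1L, tss + hw), gchr)
    geneBy <- chrTab(start(genes), end(genes), gchr)
    downBy <- chrTab(ifelse(plus, end(genes) + 1L, pmax(1L, start(genes) - 3000L)),
                     ifelse(plus, end(genes) + 3000L, pmax(1L, start(genes) - 1L)),
                     gchr)
    exBy <- chrTab(unlist(lapply(exn, IRanges::start)),
                   unlist(lapply(exn, IRanges::end)),
                   rep(gchr, lengths(exn)))
    intronList <- lapply(seq_along(genes), function(g) {
      ir <- IRanges::setdiff(IRanges(start(genes)[g], end(genes)[g]), exn[[g]])
      list(s = IRanges::start(ir), e = IRanges::end(ir))
    })
    anyOvl <- function(s, e, tab) any(s <= tab$e & e >= tab$s)
    contains <- function(p, tab) any(p >= tab$s & p <= tab$e)

    labels <- sample(names(config@featureMix), config@nRegions, replace = TRUE,
                     prob = config@featureMix)
    wrng <- config@regionWidthRange
    pS <- lapply(chroms, function(x) integer(0)); names(pS) <- chroms
    pE <- pS
    outChr <- character(config@nRegions)
    outS <- integer(config@nRegions)
    outE <- integer(config@nRegions)
    for (i in seq_len(config@nRegions)) {
      lab <- labels[i]
      ok <- FALSE
      for (try in seq_len(400L)) {
        w <- sample(wrng[1]:wrng[2], 1L)
        if (lab == "promoter") {
          g <- sample(length(genes), 1L)
          ch <- gchr[g]
          mid <- tss[g] + sample((-hw + 500L):(hw - 500L), 1L)
          s <- max(1L, mid - w %/% 2L); e <- s + w - 1L
          if (!anyOvl(s, e, promBy[[ch]])) next
        } else if (lab %in% c("exon", "intron")) {
          g <- sample(length(genes), 1L)
          ch <- gchr[g]
          pool <- if (lab == "exon")
            list(s = IRanges::start(exn[[g]]), e = IRanges::end(exn[[g]]))
          else intronList[[g]]
          if (!length(pool$s)) next
          k <- sample(length(pool$s), 1L)
          if (pool$e[k] - pool$s[k] < 10L) next
          mid <- sample(pool$s[k]:pool$e[k], 1L)
          s <- max(1L, mid - w %/% 2L); e <- s + w - 1L
          if (anyOvl(s, e, promBy[[ch]])) next
          mid2 <- (s + e) %/% 2L  # midpoint as annotation computes it
          inExon <- contains(mid2, exBy[[ch]])
          if (lab == "exon" && !inExon) next
          if (lab == "intron" && (inExon || !contains(mid2, geneBy[[ch]]))) next
        } else {  # intergenic
          ci <- sample(nchr, 1L)
          ch <- chroms[ci]
          mid <- sample(1000L:(chromEnds[ci] - 1000L), 1L)
          s <- max(1L, mid - w %/% 2L); e <- s + w - 1L
          if (anyOvl(s, e, promBy[[ch]])) next
          mid2 <- (s + e) %/% 2L
          if (contains(mid2, geneBy[[ch]]) || contains(mid2, downBy[[ch]])) next
        }
        if (length(pS[[ch]]) && any(s <= pE[[ch]] & e >= pS[[ch]])) next
        pS[[ch]] <- c(pS[[ch]], s)
        pE[[ch]] <- c(pE[[ch]], e)
        outChr[i] <- ch; outS[i] <- s; outE[i] <- e
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place region ", i, " with label '", lab,
             "'; genome too crowded for nRegions = ", config@nRegions)
    }
    ord <- order(outChr, outS, outE)
    placed <- GRanges(outChr[ord], IRanges(outS[ord], outE[ord]),
                      seqinfo = sinfo)
    mcols(placed)$feature <- labels[ord]
    names(placed) <- sprintf("hmr%04d", seq_along(placed))
    list(genes = genes, regions = placed)
  })
}

#' Simulate a negative-binomial count matrix with planted differential regions
#'
#' Counts follow \eqn{NB(\mu_{ij} = q_i s_j 2^{\beta_i x_j}, \alpha_i)}:
#' log-normal baseline abundance \eqn{q_i}, log-normal library-size factor
#' \eqn{s_j}, NB dispersion \eqn{\alpha_i} uniform on
#' \code{dispersionRange}, and a planted log2 effect \eqn{\beta_i} (random
#' sign, magnitude uniform on \code{lfcMagnitudeRange}) for a random
#' \code{fracDifferential} of regions between the first (reference) and
#' second group of \code{groupSizes}; any further group reuses the reference
#' parameters. Library sizes are the realized column totals.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param regions named GRanges of candidate regions (from
#'   [simulateGenome()]).
#' @return list with \code{experiment} (\linkS4class{HmcExperiment}, colData
#'   columns \code{group} and \code{compartment}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateCounts <- function(config, regions) {
  validObject(config)
  if (!length(regions)) stop("regions must be non-empty")
  .withSeed(.deriveSeed(config@seed, "counts"), {
    nR <- length(regions)
    ids <- names(regions)
    gs <- config@groupSizes
    groups <- rep(names(gs), gs)
    sampleIds <- unlist(lapply(names(gs), function(g)
      sprintf("%s_%03d", g, seq_len(gs[[g]]))))
    x <- as.numeric(groups == names(gs)[2])  # affected (metastasis-like) group
    nS <- length(sampleIds)

    q <- rlnorm(nR, config@baselineLogMean, config@baselineLogSd)
    alpha <- runif(nR, config@dispersionRange[1], config@dispersionRange[2])
    s <- rlnorm(nS, config@libsizeLogMean, config@libsizeLogSd)

    nDiff <- as.integer(round(config@fracDifferential * nR))
    beta <- numeric(nR)
    diffIdx <- integer(0)
    if (nDiff > 0) {
      diffIdx <- sort(sample.int(nR, nDiff))
      mag <- runif(nDiff, config@lfcMagnitudeRange[1],
                   config@lfcMagnitudeRange[2])
      beta[diffIdx] <- mag * sample(c(-1, 1), nDiff, replace = TRUE)
    }

    mu <- outer(q, s) * 2^(outer(beta, x))
    counts <- matrix(rnbinom(nR * nS, mu = as.vector(mu),
                             size = rep(1 / alpha, nS)),
                     nrow = nR, dimnames = list(ids, sampleIds))
    truth <- new("GroundTruth",
                 differentialRegionIds = ids[diffIdx],
                 trueLog2fc = structure(beta, names = ids),
                 trueDispersion = structure(alpha, names = ids),
                 baselineMean = structure(q, names = ids),
                 predictiveMarkerIds = ids[diffIdx],
                 survivalMarkerId = if (nDiff > 0) ids[diffIdx[1]] else ids[1])
    exp <- HmcExperiment(counts, regions = regions,
                         sampleData = DataFrame(group = groups,
                                                compartment = "PVB"))
    list(experiment = exp, truth = truth)
  })
}

#' Emit per-sample peak lists from a count matrix
#'
#' A sample emits a peak for a region iff its count is at least
#' \code{threshold}; each list is BED-convention sorted.
#'
#' @param experiment an \linkS4class{HmcExperiment} (row ranges used as peak
#'   intervals).
#' @param threshold reads (default: the config's presence threshold is passed
#'   by [simulateCohort()]).
#' @return Named list of GRanges, one per sample.
#' @export
simulatePeaks <- function(experiment, threshold = 5) {
  if (threshold < 0) stop("threshold must be >= 0")
  cnt <- SummarizedExperiment::assay(experiment, "counts")
  rr <- rowRanges(experiment)
  out <- lapply(colnames(cnt), function(j) {
    keep <- cnt[, j] >= threshold
    .sortRegions(rr[keep])
  })
  names(out) <- colnames(cnt)
  out
}

#' Simulate a gene-body coverage track with a TSS dip
#'
#' Coverage is a flat background, elevated over gene bodies, with a V-shaped
#' multiplicative dip centred on each TSS (multiplier \code{dipFactor} at the
#' TSS, rising linearly to 1 at \code{dipHalfwidth}) — the shape observed for
#' 5hmC enrichment throughout gene bodies with depletion around the
#' transcription start site. Strand-aware through the TSS position.
#'
#' @param genes gene-model GRanges with seqlengths set.
#' @param background,bodyLevel coverage levels outside/inside gene bodies.
#' @param dipFactor multiplier at the TSS (1 = no dip).
#' @param dipHalfwidth bp, half-width of the dip window.
#' @return GRanges coverage track with a \code{score} column (bedGraph-ready).
#' @export
simulateCoverage <- function(genes, background = 0.5, bodyLevel = 3,
                             dipFactor = 0.3, dipHalfwidth = 1000L) {
  if (!length(genes)) stop("genes must be non-empty")
  sl <- seqlengths(genes)
  if (any(is.na(sl))) stop("genes must carry seqlengths")
  tss <- tssPositions(genes)
  W <- as.integer(dipHalfwidth)
  v <- background + (bodyLevel - background) * coverage(granges(genes))
  names(v) <- names(sl)
  gchr <- as.character(seqnames(genes))
  for (ch in names(sl)) {
    mult <- S4Vectors::Rle(1, sl[[ch]])
    for (tp in tss[gchr == ch]) {
      lo <- max(1L, tp - W)
      hi <- min(sl[[ch]], tp + W - 1L)
      ramp <- dipFactor + (1 - dipFactor) * abs(seq(lo, hi) - tp) / W
      mult[lo:hi] <- pmin(as.numeric(mult[lo:hi]), ramp)
    }
    v[[ch]] <- v[[ch]] * mult
  }
  gr <- GRanges(v)
  names(gr) <- NULL
  mcols(gr)$score <- as.numeric(mcols(gr)$score)
  seqlengths(gr) <- sl
  gr
}

#' Simulate overall and event-free survival driven by a marker level
#'
#' Event times are exponential with hazard
#' \eqn{h_0 \cdot HR^{I(\mathrm{level} > \mathrm{median})}}; censoring times
#' are exponential with rate \code{censorRate} (none when 0); the observed
#' time is the minimum, with the event flag set accordingly. EFS uses a 1.5x
#' baseline hazard (events precede deaths) with the same hazard ratio.
#'
#' @param markerLevel per-sample numeric marker level (names kept).
#' @param config a \linkS4class{SimConfig} (hazard parameters + seed).
#' @return data.frame with \code{os_months}, \code{os_event},
#'   \code{efs_months}, \code{efs_event}.
#' @export
simulateSurvival <- function(markerLevel, config) {
  validObject(config)
  .withSeed(.deriveSeed(config@seed, "survival"), {
    n <- length(markerLevel)
    high <- markerLevel > median(markerLevel)
    draw <- function(h0) {
      hz <- h0 * config@survivalHazardRatio^as.numeric(high)
      t_event <- rexp(n, hz)
      t_cens <- if (config@censorRate > 0) rexp(n, config@censorRate)
                else rep(Inf, n)
      data.frame(months = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
    }
    os <- draw(config@survivalBaselineHazard)
    efs <- draw(1.5 * config@survivalBaselineHazard)
    data.frame(row.names = names(markerLevel),
               os_months = os$months, os_event = os$event,
               efs_months = efs$months, efs_event = efs$event)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulateGenome()], [simulateCounts()], [simulatePeaks()],
#' [simulateCoverage()] and [simulateSurvival()] (hazard driven by the RPM
#' level of the ground-truth survival marker: the first planted differential
#' region) and returns all artifacts.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{genes}, \code{regions}, \code{experiment} (survival
#'   columns merged into colData), \code{truth}, \code{peaks},
#'   \code{coverage}.
#' @examples
#' cohort <- simulateCohort(simConfig(seed = 1, nChromosomes = 1L,
#'                                    nGenes = 10L, nRegions = 40L,
#'                                    groupSizes = c(PC = 6L, MLM = 6L)))
#' @export
simulateCohort <- function(config) {
  geno <- simulateGenome(config)
  cc <- simulateCounts(config, geno$regions)
  exp <- cc$experiment
  peaks <- simulatePeaks(exp, config@peakPresenceThreshold)
  coverage <- simulateCoverage(geno$genes)
  lvl <- rpm(SummarizedExperiment::assay(exp, "counts")[cc$truth@survivalMarkerId, ],
             librarySizes(exp))
  surv <- simulateSurvival(structure(lvl, names = colnames(exp)), config)
  cd <- SummarizedExperiment::colData(exp)
  SummarizedExperiment::colData(exp) <- cbind(cd, DataFrame(surv))
  list(genes = geno$genes, regions = geno$regions, experiment = exp,
       truth = cc$truth, peaks = peaks, coverage = coverage)
}
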