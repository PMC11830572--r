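#' @importFrom GenomicRanges reduce countOverlaps distance
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Merge per-sample peak lists into a supported region set
#'
#' The union of all peaks is partitioned into maximal overlapping-or-abutting
#' runs (0-gap merge, the bedtools-merge default; configurable via
#' \code{gap}); each merged region records its support = number of samples
#' contributing at least one overlapping peak.
#'
#' @param peakLists named list of GRanges, one per sample.
#' @param gap maximal distance (bp) still merged; 0 merges abutting peaks.
#' @return Sorted, disjoint GRanges with a \code{support} mcol, named
#'   \code{"chrom:start-end"} (0-based half-open display).
#' @export
mergePeaks <- function(peakLists, gap = 0L) {
  stopifnot(is.list(peakLists))
  all <- suppressWarnings(do.call(c, lapply(unname(peakLists), granges)))
  if (!length(all)) {
    out <- GRanges()
    mcols(out)$support <- integer(0)
    return(out)
  }
  strand(all) <- "*"
  merged <- reduce(all, min.gapwidth = gap + 1L)
  merged <- .sortRegions(merged)
  support <- Reduce(`+`, lapply(peakLists, function(p)
    as.integer(countOverlaps(merged, p) > 0)))
  mcols(merged)$support <- support
  names(merged) <- .autoName(merged)
  merged
}

#' Retention filter for merged regions
#'
#' Keeps a region iff its support exceeds \code{minSamples} (strictly), its
#' width is below \code{maxWidth} (strictly), and it does not overlap the
#' blacklist by a single bp — i.e. peak regions that appeared in more than 10
#' samples and span less than 1000 bp, with artefact regions excluded.
#'
#' @param merged GRanges with a \code{support} mcol (from [mergePeaks()]).
#' @param minSamples support must be > this (default 10).
#' @param maxWidth width must be < this, in bp (default 1000).
#' @param blacklist optional GRanges of excluded regions.
#' @return The retained subset, order preserved.
#' @export
filterRegions <- function(merged, minSamples = 10L, maxWidth = 1000L,
                          blacklist = NULL) {
  keep <- mcols(merged)$support > minSamples & width(merged) < maxWidth
  if (!is.null(blacklist) && length(blacklist))
    keep <- keep & countOverlaps(merged, blacklist) == 0
  merged[keep]
}

#' Annotate regions with genomic features and nearest genes
#'
#' Fixed priority promoter > exon > intron > downstream > intergenic:
#' a region is a promoter if it overlaps any TSS +/- \code{promoterHalfwidth}
#' window by any amount; otherwise the region midpoint decides containment in
#' an exon, an intron (inside a gene span but not an exon), or a downstream
#' window (up to 3 kb past the TTS). The nearest gene minimizes
#' |midpoint - TSS| with ties broken by lexicographic gene name;
#' \code{tss_distance} is signed positive in the direction of transcription.
#'
#' @param regions GRanges to annotate.
#' @param genes gene-model GRanges with an \code{exons} mcol (may be empty:
#'   everything becomes intergenic with no nearest gene).
#' @param promoterHalfwidth bp (default 2000).
#' @return \code{regions} with mcols \code{feature}, \code{nearest_gene},
#'   \code{tss_distance}.
#' @export
annotateRegions <- function(regions, genes, promoterHalfwidth = 2000L) {
  n <- length(regions)
  feature <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  tssDist <- rep(NA_integer_, n)
  if (length(genes)) {
    mid <- (start(regions) + end(regions)) %/% 2L
    midq <- GRanges(seqnames(regions), IRanges(mid, width = 1L))
    promWin <- suppressWarnings(GenomicRanges::trim(
      promoters(genes, promoterHalfwidth, promoterHalfwidth)))
    isProm <- countOverlaps(regions, promWin, ignore.strand = TRUE) > 0
    exonsAbs <- GRanges(rep(as.character(seqnames(genes)),
                            lengths(mcols(genes)$exons)),
                        unlist(mcols(genes)$exons))
    inExon <- countOverlaps(midq, exonsAbs, ignore.strand = TRUE) > 0
    inGene <- countOverlaps(midq, genes, ignore.strand = TRUE) > 0
    plus <- as.character(strand(genes)) == "+"
    downWin <- GRanges(seqnames(genes),
                       IRanges(ifelse(plus, end(genes) + 1L,
                                      pmax(1L, start(genes) - 3000L)),
                               ifelse(plus, end(genes) + 3000L,
                                      pmax(1L, start(genes) - 1L))))
    inDown <- countOverlaps(midq, downWin, ignore.strand = TRUE) > 0
    feature <- unname(ifelse(isProm, "promoter",
               ifelse(inExon, "exon",
               ifelse(inGene, "intron",
               ifelse(inDown, "downstream", "intergenic")))))
    # nearest gene by |midpoint - TSS| on the same chromosome,
    # ties -> lexicographic gene name
    tss <- tssPositions(genes)
    gname <- names(genes)
    gchrom <- as.character(seqnames(genes))
    gord <- order(gname)
    rchrom <- as.character(seqnames(regions))
    for (ch in unique(rchrom)) {
      gi <- gord[gchrom[gord] == ch]
      ri <- which(rchrom == ch)
      if (!length(gi) || !length(ri)) next
      d <- abs(outer(mid[ri], tss[gi], `-`))
      best <- apply(d, 1L, which.min)  # first minimum = lexicographic tie-break
      nearest[ri] <- gname[gi][best]
      raw <- mid[ri] - tss[gi][best]
      sgn <- ifelse(as.character(strand(genes))[gi][best] == "+", 1L, -1L)
      tssDist[ri] <- raw * sgn
    }
  }
  mcols(regions)$feature <- feature
  mcols(regions)$nearest_gene <- nearest
  mcols(regions)$tss_distance <- tssDist
  regions
}

#' Feature-label distribution of annotated regions
#'
#' @param annotated GRanges with a \code{feature} mcol.
#' @return data.frame with \code{feature}, \code{count}, \code{proportion}
#'   (proportions sum to 1), in fixed feature order.
#' @export
featureDistribution <- function(annotated) {
  if (!length(annotated)) stop("no regions to summarize")
  lev <- c("promoter", "exon", "intron", "downstream", "intergenic")
  f <- factor(mcols(annotated)$feature, levels = lev)
  cnt <- as.integer(table(f))
  data.frame(feature = lev, count = cnt, proportion = cnt / sum(cnt))
}

#' Fragments per kilobase per million mapped reads
#'
#' \eqn{FPKM_{ij} = c_{ij} / (w_i/1000) / (L_j/10^6)} with region widths
#' \eqn{w_i} (bp) and library sizes \eqn{L_j} (total mapped reads).
#'
#' @param experiment an \linkS4class{HmcExperiment}, or a count matrix if
#'   \code{widths} and \code{librarySizes} are given.
#' @param widths,librarySizes overrides (required for a bare matrix).
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(experiment, widths = NULL, librarySizes = NULL) {
  if (is(experiment, "SummarizedExperiment")) {
    cnt <- SummarizedExperiment::assay(experiment, "counts")
    if (is.null(widths)) widths <- width(rowRanges(experiment))
    if (is.null(librarySizes)) librarySizes <- portal5hmc::librarySizes(experiment)
  } else cnt <- as.matrix(experiment)
  if (is.null(widths) || is.null(librarySizes))
    stop("widths and librarySizes are required")
  if (any(widths <= 0)) stop("zero or negative region width")
  if (any(librarySizes <= 0)) stop("zero or negative library size")
  cnt / (widths / 1e3) / rep(librarySizes / 1e6, each = nrow(cnt))
}

#' Reads per million mapped reads
#'
#' @param value read count(s).
#' @param librarySize total mapped reads (> 0).
#' @return \code{value / (librarySize / 1e6)}.
#' @export
rpm <- function(value, librarySize) {
  if (any(librarySize <= 0)) stop("library size must be > 0")
  value / (librarySize / 1e6)
}

# Map merged/filtered regions back onto the experiment's candidate rows by
# summing counts of candidate regions overlapping each merged region.
# When merged regions coincide exactly with candidates this is a row subset.
.quantifyRegions <- function(retained, experiment) {
  rr <- rowRanges(experiment)
  hits <- findOverlaps(retained, rr)
  if (!length(hits)) stop("no retained region overlaps the count matrix rows")
  cnt <- SummarizedExperiment::assay(experiment, "counts")
  agg <- rowsum(cnt[subjectHits(hits), , drop = FALSE],
                group = queryHits(hits), reorder = TRUE)
  keep <- as.integer(rownames(agg))
  out <- retained[keep]
  m <- as.matrix(agg)
  rownames(m) <- names(out)
  HmcExperiment(m, regions = out,
                sampleData = SummarizedExperiment::colData(experiment),
                librarySizes = librarySizes(experiment))
}
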