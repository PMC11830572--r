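#' Metagene coverage profile across scaled gene bodies
#'
#' For each gene the body is rescaled to \code{bodyBins} equal fractions and
#' each flank is cut into \code{flankBins} fixed-width bins; minus-strand
#' genes are reversed so bin 1 is 5'-most. Bin value = mean per-bp coverage
#' inside the bin (so unequal body lengths are comparable), averaged across
#' genes, then converted to RPM by \code{librarySize}.
#'
#' @param track coverage GRanges with a \code{score} mcol (raw read counts or
#'   already-normalized values).
#' @param genes gene-model GRanges.
#' @param bodyBins number of gene-body bins (default 100).
#' @param flank flank width in bp (default 2000).
#' @param flankBins number of bins per flank (default 20).
#' @param librarySize total mapped reads used for RPM conversion; the default
#'   1e6 leaves already-normalized tracks unchanged.
#' @return A \linkS4class{MetageneProfile}. Genes shorter than
#'   \code{bodyBins} bp are skipped with a warning and counted in
#'   \code{nSkipped}.
#' @export
metageneProfile <- function(track, genes, bodyBins = 100L, flank = 2000L,
                            flankBins = 20L, librarySize = 1e6) {
  if (!length(genes)) stop("genes must be non-empty")
  if (flank < 0) stop("flank must be >= 0")
  bodyBins <- as.integer(bodyBins)
  flankBins <- if (flank == 0) 0L else as.integer(flankBins)
  cov <- coverage(track, weight = "score")
  nbin <- 2L * flankBins + bodyBins
  acc <- numeric(nbin)
  used <- 0L
  skipped <- 0L
  bodyIdx <- function(len) 1L + ((seq_len(len) - 1L) * bodyBins) %/% len
  for (g in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[g]
    gs <- start(genes)[g]
    ge <- end(genes)[g]
    len <- ge - gs + 1L
    if (len < bodyBins) {
      skipped <- skipped + 1L
      next
    }
    chcov <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0, ge + flank)
    clen <- length(chcov)
    grab <- function(from, to) {
      # zero-padded window [from, to] on the chromosome vector
      v <- numeric(to - from + 1L)
      lo <- max(1L, from)
      hi <- min(clen, to)
      if (lo <= hi) v[(lo - from + 1L):(hi - from + 1L)] <- as.numeric(chcov[lo:hi])
      v
    }
    body <- grab(gs, ge)
    up <- if (flankBins > 0) grab(gs - flank, gs - 1L) else numeric(0)
    down <- if (flankBins > 0) grab(ge + 1L, ge + flank) else numeric(0)
    if (as.character(strand(genes))[g] == "-") {
      body <- rev(body)
      tmp <- rev(up)
      up <- rev(down)
      down <- tmp
    }
    bv <- as.numeric(tapply(body, bodyIdx(len), mean))
    fb <- function(v) {
      if (!flankBins) return(numeric(0))
      idx <- 1L + ((seq_along(v) - 1L) * flankBins) %/% length(v)
      as.numeric(tapply(v, idx, mean))
    }
    acc <- acc + c(fb(up), bv, fb(down))
    used <- used + 1L
  }
  if (skipped > 0)
    warning(skipped, " gene(s) shorter than ", bodyBins, " bp skipped")
  if (used == 0L) stop("no gene long enough for the requested binning")
  vals <- (acc / used) / (librarySize / 1e6)
  new("MetageneProfile", values = vals, upstreamBins = flankBins,
      bodyBins = bodyBins, downstreamBins = flankBins, flank = as.numeric(flank),
      nGenes = used, nSkipped = skipped)
}

#' Compare two metagene profiles
#'
#' @param a,b \linkS4class{MetageneProfile}s with identical binning.
#' @return list with \code{difference} (per-bin \code{a - b}) and
#'   \code{fractionLowerBody}: the fraction of gene-body bins where
#'   \code{a < b} (e.g. 1 when one group's 5hmC density is lower than the
#'   other's throughout the gene body).
#' @export
compareProfiles <- function(a, b) {
  if (a@upstreamBins != b@upstreamBins || a@bodyBins != b@bodyBins ||
      a@downstreamBins != b@downstreamBins)
    stop("profiles have mismatched binning")
  list(difference = a@values - b@values,
       fractionLowerBody = mean(bodyValues(a) < bodyValues(b)))
}

#' Export a metagene profile as a plotting-ready data.frame
#'
#' @param x a \linkS4class{MetageneProfile}.
#' @return data.frame with \code{bin}, \code{zone}
#'   (upstream/body/downstream) and \code{rpm}.
#' @export
profileTable <- function(x) {
  zone <- c(rep("upstream", x@upstreamBins), rep("body", x@bodyBins),
            rep("downstream", x@downstreamBins))
  data.frame(bin = seq_along(x@values), zone = zone, rpm = x@values)
}
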