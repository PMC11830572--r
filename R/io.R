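#' @importFrom GenomicRanges GRanges strand strand<- mcols mcols<- seqnames
#'   start end width
#' @importFrom IRanges IRanges IRangesList
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse
#' @importFrom utils read.delim write.table head
NULL

.VALID_GROUPS <- c("PC", "MLM", "SLM")
.VALID_COMPARTMENTS <- c("PVB", "PB", "PT", "PN", "SPT", "SPN",
                         "SMT", "SMN", "MPT", "MPN")

# lexicographic (chrom, start, end) ordering used by all writers
.sortRegions <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr)), ]
}

.autoName <- function(gr) {
  # 0-based half-open display, matching BED
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Read a BED3/BED6 file of regions
#'
#' Track/browser lines and '#' comments are skipped; fields are
#' tab-separated. Missing names are auto-assigned \code{"chrom:start-end"}
#' (0-based half-open, as displayed in BED). The result is sorted by
#' (chrom, start, end) and carries \code{score} and strand when present.
#'
#' @param path file path.
#' @return A named \link[GenomicRanges]{GRanges}.
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(GRanges())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("BED parse error at line ", idx[which(nf < 3)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  startc <- vapply(parts, `[[`, "", 2L)
  endc <- vapply(parts, `[[`, "", 3L)
  s <- suppressWarnings(as.integer(startc))
  e <- suppressWarnings(as.integer(endc))
  bad <- suppressWarnings(which(is.na(s) | is.na(e) |
                                  s != as.numeric(startc) |
                                  e != as.numeric(endc)))
  if (length(bad))
    stop("BED parse error at line ", idx[bad[1]], ": non-integer coordinate")
  bad <- which(s < 0 | e < 0)
  if (length(bad))
    stop("BED parse error at line ", idx[bad[1]], ": negative coordinate")
  bad <- which(s >= e)
  if (length(bad))
    stop("BED parse error at line ", idx[bad[1]], ": start >= end")
  gr <- GRanges(chrom, IRanges(start = s + 1L, end = e))
  nm <- ifelse(nf >= 4, vapply(parts, function(p) p[min(4L, length(p))], ""),
               NA_character_)
  nm[is.na(nm) | nm == "." | nm == ""] <- .autoName(gr)[is.na(nm) | nm == "." | nm == ""]
  sc <- rep(0, length(gr))
  has5 <- nf >= 5
  sc[has5] <- suppressWarnings(as.numeric(vapply(parts[has5], `[[`, "", 5L)))
  sc[is.na(sc)] <- 0
  st <- rep("*", length(gr))
  has6 <- nf >= 6
  st6 <- vapply(parts[has6], `[[`, "", 6L)
  st[has6] <- ifelse(st6 %in% c("+", "-"), st6, "*")
  strand(gr) <- st
  mcols(gr)$score <- sc
  names(gr) <- nm
  gr <- .sortRegions(gr)
  if (anyDuplicated(names(gr)))
    stop("duplicate region name: ",
         names(gr)[duplicated(names(gr))][1])
  gr
}

#' Write regions as BED6
#'
#' Deterministic canonical form: sorted by (chrom, start, end), tab-separated,
#' LF line endings. \code{writeBed(readBed(p))} reproduces canonical form.
#'
#' @param gr a named GRanges; \code{score} mcol used when present.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  gr <- .sortRegions(gr)
  nm <- if (is.null(names(gr))) .autoName(gr) else names(gr)
  sc <- if ("score" %in% colnames(mcols(gr))) mcols(gr)$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(gr))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                       nm, format(sc, trim = TRUE, scientific = FALSE), st),
               con, sep = "\n")
  invisible(path)
}

#' Read BED12 gene models
#'
#' Parses BED12 via \pkg{rtracklayer}, expands block starts/sizes to absolute
#' exon intervals, and enforces the gene-model invariants: exons ordered and
#' disjoint within the gene span, first exon starting at the gene start, last
#' exon ending at the gene end, strand + or -.
#'
#' @param path BED12 file.
#' @return A named GRanges of gene spans with an \code{exons}
#'   \link[IRanges]{IRangesList} metadata column (absolute coordinates).
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!"blocks" %in% colnames(mcols(gr)))
    stop("gene models must be BED12 (block fields missing)")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ex <- rtracklayer::blocks(gr)  # absolute GRangesList
  exr <- IRanges::ranges(ex)
  firsts <- vapply(exr, function(r) min(IRanges::start(r)), 0L)
  lasts <- vapply(exr, function(r) max(IRanges::end(r)), 0L)
  bad <- which(firsts != start(gr) | lasts != end(gr))
  if (length(bad))
    stop("BED12 parse error: block arithmetic inconsistent with gene span ",
         "for record ", bad[1])
  disj <- vapply(exr, function(r) {
    r <- BiocGenerics::sort(r)
    length(r) < 2 || all(IRanges::start(r)[-1] > IRanges::end(r)[-length(r)])
  }, TRUE)
  if (!all(disj))
    stop("BED12 parse error: overlapping exon blocks in record ",
         which(!disj)[1])
  genes <- GenomicRanges::granges(gr)
  names(genes) <- mcols(gr)$name
  if (anyDuplicated(names(genes)))
    stop("duplicate gene name: ", names(genes)[duplicated(names(genes))][1])
  mcols(genes)$exons <- exr
  .sortRegions(genes)
}

#' Write gene models as BED12
#'
#' @param genes GRanges with an \code{exons} IRangesList mcol, as returned by
#'   [readGeneModels()] or [simulateGenome()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneModels <- function(genes, path) {
  genes <- .sortRegions(genes)
  ex <- mcols(genes)$exons
  lines <- vapply(seq_along(genes), function(i) {
    r <- BiocGenerics::sort(ex[[i]])
    sizes <- paste0(paste(IRanges::width(r), collapse = ","), ",")
    starts <- paste0(paste(IRanges::start(r) - start(genes)[i], collapse = ","),
                     ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            as.character(seqnames(genes))[i], start(genes)[i] - 1L,
            end(genes)[i], names(genes)[i], as.character(strand(genes))[i],
            start(genes)[i] - 1L, end(genes)[i], length(r), sizes, starts)
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' TSS positions of gene models
#'
#' TSS is the 5' end: the gene start on the + strand, the gene end on the -
#' strand (1-based coordinates).
#'
#' @param genes gene-model GRanges.
#' @return Integer vector of TSS positions, named by gene.
#' @export
tssPositions <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
  structure(as.integer(pos), names = names(genes))
}

#' Read a regions-by-samples count matrix
#'
#' TSV with a header; the first column holds region ids, remaining columns one
#' sample each. Library sizes (total mapped reads, allowed to exceed in-region
#' sums) come from a sidecar TSV with columns \code{sample} and
#' \code{library_size}; when absent, column sums are used.
#'
#' @param path counts TSV.
#' @param librarySizePath optional sidecar TSV.
#' @param regions optional GRanges named like the rows.
#' @param sampleData optional per-sample annotation.
#' @return An \linkS4class{HmcExperiment}.
#' @export
readCountMatrix <- function(path, librarySizePath = NULL, regions = NULL,
                            sampleData = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate region id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1])
  if (any(is.na(m)) || any(m < 0))
    stop("counts must be non-negative and complete")
  if (any(m != round(m)))
    stop("counts must be integers")
  rownames(m) <- ids
  ls <- NULL
  if (!is.null(librarySizePath)) {
    lsdf <- read.delim(librarySizePath, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (!all(c("sample", "library_size") %in% colnames(lsdf)))
      stop("library-size sidecar needs columns 'sample' and 'library_size'")
    missing <- setdiff(colnames(m), lsdf$sample)
    if (length(missing))
      stop("library size missing for sample: ", missing[1])
    ls <- lsdf$library_size[match(colnames(m), lsdf$sample)]
  }
  HmcExperiment(m, regions = regions, sampleData = sampleData,
                librarySizes = ls)
}

#' Write a count matrix (and library-size sidecar)
#'
#' @param x an HmcExperiment (or integer matrix).
#' @param path counts TSV path.
#' @param librarySizePath optional sidecar path.
#' @return Invisibly, \code{path}.
#' @export
writeCountMatrix <- function(x, path, librarySizePath = NULL) {
  m <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts") else x
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  .writeTsv(df, path)
  if (!is.null(librarySizePath)) {
    ls <- if (is(x, "SummarizedExperiment")) librarySizes(x) else colSums(m)
    .writeTsv(data.frame(sample = colnames(m), library_size = ls), librarySizePath)
  }
  invisible(path)
}

.writeTsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE,
                                  digits = 15) else as.character(col)
    }), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a sample table
#'
#' TSV with at least \code{sample} and \code{group} columns; optional
#' \code{compartment}, \code{age}, \code{sex} and survival columns
#' (\code{os_months}, \code{os_event}, \code{efs_months}, \code{efs_event}).
#' Group labels must be PC, MLM or SLM; compartments one of the cohort's
#' blood/tissue compartment codes.
#'
#' @param path TSV path.
#' @return A \link[S4Vectors]{DataFrame} with sample ids as row names.
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("sample table needs 'sample' and 'group' columns")
  if (anyDuplicated(df$sample))
    stop("duplicate sample id: ", df$sample[duplicated(df$sample)][1])
  badg <- setdiff(unique(df$group), .VALID_GROUPS)
  if (length(badg))
    stop("unknown group label: '", badg[1], "' (expected ",
         paste(.VALID_GROUPS, collapse = "/"), ")")
  if ("compartment" %in% colnames(df)) {
    badc <- setdiff(unique(df$compartment), .VALID_COMPARTMENTS)
    if (length(badc)) stop("unknown compartment label: '", badc[1], "'")
  }
  for (col in c("os_months", "efs_months")) {
    if (col %in% colnames(df) && any(df[[col]] < 0, na.rm = TRUE))
      stop(col, " must be >= 0")
  }
  for (col in c("os_event", "efs_event")) {
    if (col %in% colnames(df)) {
      v <- df[[col]]
      if (!all(v %in% c(0, 1, TRUE, FALSE, NA)))
        stop(col, " must be boolean (0/1)")
      df[[col]] <- as.integer(v)
    }
  }
  DataFrame(df[, setdiff(colnames(df), "sample"), drop = FALSE],
            row.names = df$sample)
}

#' Write a sample table
#'
#' @param x DataFrame/data.frame with sample ids as row names.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleTable <- function(x, path) {
  df <- as.data.frame(x)
  df <- cbind(sample = rownames(df), df)
  rownames(df) <- NULL
  .writeTsv(df, path)
}

#' Read a bedGraph coverage track
#'
#' Intervals must be sorted and non-overlapping; gaps imply a value of 0.
#'
#' @param path bedGraph path.
#' @return GRanges with a \code{score} column.
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
  if (!identical(ord, seq_along(gr)))
    stop("bedGraph parse error: intervals not sorted by (chrom, start)")
  if (length(gr) > 1) {
    same <- as.character(seqnames(gr))[-1] == as.character(seqnames(gr))[-length(gr)]
    if (any(same & start(gr)[-1] <= end(gr)[-length(gr)]))
      stop("bedGraph parse error: overlapping intervals")
  }
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param track GRanges with a \code{score} column.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedGraph <- function(track, path) {
  track <- .sortRegions(track)
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(track))
    writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(track)),
                       start(track) - 1L, end(track),
                       format(mcols(track)$score, trim = TRUE,
                              scientific = FALSE, digits = 10)),
               con, sep = "\n")
  invisible(path)
}

#' Point query into a coverage track
#'
#' @param track GRanges with \code{score}.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return The track value at \code{pos}, 0 outside all intervals.
#' @export
bedgraphValue <- function(track, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos, width = 1))
  hit <- suppressWarnings(GenomicRanges::findOverlaps(q, track))
  if (!length(hit)) 0 else mcols(track)$score[S4Vectors::subjectHits(hit)[1]]
}
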