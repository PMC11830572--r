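#' @importFrom stats pnorm median var t.test wilcox.test p.adjust
#' @importFrom BiocGenerics sizeFactors counts sort
NULL

.asCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive regions of the ratio between
#' its count and the region's geometric mean across samples — the
#' normalization underlying NB differential analysis of count matrices.
#' The median is taken on the log scale, so with an even number of reference
#' regions the two central ratios combine geometrically (the convention of
#' the reference implementation); for odd counts the two definitions agree
#' exactly.
#'
#' @param counts regions x samples count matrix (or
#'   \linkS4class{HmcExperiment}).
#' @return Positive numeric vector, one size factor per sample.
#' @examples
#' m <- matrix(c(2, 4, 8, 16), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' medianOfRatios(m)  # s2 = 2 * s1
#' @export
medianOfRatios <- function(counts) {
  m <- .asCounts(counts)
  allPos <- rowSums(m == 0) == 0
  if (!any(allPos))
    stop("no region with nonzero counts in all samples; ",
         "median-of-ratios is undefined (consider a pseudo-reference)")
  lm <- log(m[allPos, , drop = FALSE])
  logGeo <- rowMeans(lm)
  sf <- apply(lm - logGeo, 2L, median)
  exp(sf)
}

#' @describeIn HmcExperiment median-of-ratios size factors of the counts.
#' @export
setMethod("sizeFactors", "HmcExperiment", function(object) {
  structure(medianOfRatios(object), names = colnames(object))
})

#' Method-of-moments NB dispersion per region
#'
#' On size-factor-normalized counts with group means removed:
#' \eqn{\hat\alpha = \max((v - \bar z) / \bar z^2, 10^{-8})} with the pooled
#' within-group variance \eqn{v} (denominator n - G) and the overall mean
#' \eqn{\bar z}, capped at 10. A deliberately simple gene-wise estimator with
#' no empirical-Bayes shrinkage; see the package vignette for the
#' consequences in small samples.
#'
#' @param counts count matrix or \linkS4class{HmcExperiment}.
#' @param sizeFactors per-sample positive size factors.
#' @param groups group label per sample (2+ samples per group).
#' @return Numeric dispersion per region, in \code{[1e-8, 10]}.
#' @export
estimateDispersion <- function(counts, sizeFactors, groups) {
  m <- .asCounts(counts)
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  z <- sweep(m, 2L, sizeFactors, "/")
  G <- nlevels(groups)
  n <- ncol(z)
  ssq <- 0
  for (g in levels(groups)) {
    zg <- z[, groups == g, drop = FALSE]
    mg <- rowMeans(zg)
    ssq <- ssq + rowSums((zg - mg)^2)
  }
  v <- ssq / (n - G)
  mu <- rowMeans(z)
  alpha <- ifelse(mu > 0, (v - mu) / mu^2, 0)
  pmin(pmax(alpha, 1e-8), 10)
}

#' Negative-binomial Wald test for differential hydroxymethylation
#'
#' Fits, per region, the NB GLM with log link, design intercept + group
#' indicator, per-sample offsets \eqn{\log s_j} and fixed dispersion, and
#' reports the Wald test of the group coefficient. Because the two-group
#' design is saturated, the fit factorises into two one-parameter Fisher
#' scoring problems solved vectorised across all regions
#' (convergence |delta| < 1e-10, max 100 iterations). Standard errors come
#' from the observed Fisher information; p-values are two-sided normal.
#'
#' @param counts count matrix or \linkS4class{HmcExperiment}.
#' @param sizeFactors per-sample size factors (default: median-of-ratios).
#' @param groups two-level group label per sample; the first level (or
#'   \code{reference}) is the denominator of the fold change.
#' @param dispersions per-region NB dispersion (default: method of moments).
#' @param reference optional reference group label.
#' @return data.frame with \code{id}, \code{baseMean}, \code{log2fc},
#'   \code{se} (log2 scale), \code{waldZ}, \code{pvalue}, \code{padj}
#'   (Benjamini-Hochberg, provided for convenience; the DhMR call uses raw
#'   p), \code{dispersion} and \code{status} ("ok", "all-zero",
#'   "zero-group"). All-zero regions are flagged with p = 1 and log2fc = 0.
#' @export
nbWaldTest <- function(counts, sizeFactors = NULL, groups, dispersions = NULL,
                       reference = NULL) {
  m <- .asCounts(counts)
  groups <- as.factor(groups)
  if (!is.null(reference)) groups <- stats::relevel(groups, reference)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(m)
  if (is.null(dispersions)) dispersions <- estimateDispersion(m, sizeFactors, groups)
  if (length(dispersions) == 1L) dispersions <- rep(dispersions, nrow(m))
  alpha <- pmax(dispersions, 1e-12)
  lev <- levels(groups)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))

  fitGroup <- function(y, s) {
    # per-region scalar Fisher scoring for theta = log mean, offsets log s
    tot <- rowSums(y)
    theta <- log(pmax(tot / sum(s), 1e-8))
    active <- tot > 0
    for (it in seq_len(100L)) {
      mu <- exp(theta) %o% s
      denom <- 1 + alpha * mu
      U <- rowSums((y - mu) / denom)
      I <- rowSums(mu / denom)
      delta <- ifelse(active & I > 0, U / I, 0)
      delta <- pmax(pmin(delta, 5), -5)
      theta <- theta + delta
      if (max(abs(delta)) < 1e-10) break
    }
    mu <- exp(theta) %o% s
    J <- rowSums(mu * (1 + alpha * y) / (1 + alpha * mu)^2)  # observed info
    list(theta = theta, J = J, zero = !active)
  }
  j1 <- groups == lev[1]
  j2 <- groups == lev[2]
  f1 <- fitGroup(m[, j1, drop = FALSE], sizeFactors[j1])
  f2 <- fitGroup(m[, j2, drop = FALSE], sizeFactors[j2])

  beta <- f2$theta - f1$theta            # natural-log scale
  varB <- 1 / f1$J + 1 / f2$J
  log2fc <- beta / log(2)
  se <- sqrt(varB) / log(2)
  waldZ <- beta / sqrt(varB)
  pvalue <- 2 * pnorm(-abs(waldZ))
  baseMean <- rowMeans(sweep(m, 2L, sizeFactors, "/"))

  allZero <- f1$zero & f2$zero
  status <- ifelse(allZero, "all-zero",
                   ifelse(f1$zero | f2$zero, "zero-group", "ok"))
  log2fc[allZero] <- 0
  se[allZero] <- NA_real_
  waldZ[allZero] <- 0
  pvalue[allZero] <- 1
  data.frame(id = ids, baseMean = baseMean, log2fc = log2fc, se = se,
             waldZ = waldZ, pvalue = pvalue,
             padj = p.adjust(pvalue, "BH"),
             dispersion = alpha, status = status, row.names = NULL)
}

#' Call differentially hydroxymethylated regions
#'
#' Up = \{log2fc >= lfcMin and p < pMax\}; down = \{log2fc <= -lfcMin and
#' p < pMax\}. The fold-change threshold is inclusive, the p threshold
#' strict, and raw (unadjusted) p-values are used. Presets in use are
#' \code{lfcMin = 0.35} and \code{0.5} with \code{pMax = 0.01}.
#'
#' @param results data.frame from [nbWaldTest()].
#' @param lfcMin minimal |log2 fold change| (default 0.5).
#' @param pMax exclusive p-value threshold (default 0.01).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDhmrs <- function(results, lfcMin = 0.5, pMax = 0.01) {
  sig <- results$pvalue < pMax
  list(up = results$id[sig & results$log2fc >= lfcMin],
       down = results$id[sig & results$log2fc <= -lfcMin])
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (wraps \code{\link[stats]{t.test}}).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (var(x) == 0 && var(y) == 0)
    stop("both samples have zero variance; the Welch statistic is undefined")
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' \eqn{U = \#\{(i,j): x_i > y_j\} + \frac12 \#ties}; exact p when
#' \eqn{n_x n_y \le 10^4} and there are no ties, otherwise the tie-corrected
#' normal approximation (wraps \code{\link[stats]{wilcox.test}}).
#'
#' @param x,y numeric vectors, non-empty.
#' @return list with \code{U} and \code{p}.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) * length(y) <= 1e4
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}
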