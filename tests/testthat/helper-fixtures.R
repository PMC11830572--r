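suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# a small two-group config used across tests; any simConfig() argument
# may be overridden
tinyConfig <- function(...) {
  args <- list(seed = 1L, nChromosomes = 2L, nGenes = 24L, nRegions = 90L,
               groupSizes = c(PC = 10L, MLM = 8L))
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

# GRanges -> plain data.frame with character seqnames/strand, for
# order-insensitive equality checks
grDf <- function(gr) {
  d <- as.data.frame(gr)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  rownames(d) <- NULL
  d
}

# placeholder candidate regions when genome placement is irrelevant
flatRegions <- function(n, width = 200L) {
  gr <- GRanges("chrS1", IRanges(start = seq_len(n) * 1000L, width = width))
  names(gr) <- sprintf("hmr%05d", seq_len(n))
  gr
}

# hand-built gene set: one + strand and one - strand gene with two exons each
toyGenes <- function() {
  g <- GRanges(c("chrT", "chrT"), IRanges(c(5001L, 40001L), c(15000L, 50000L)),
               strand = c("+", "-"))
  names(g) <- c("geneA", "geneB")
  mcols(g)$exons <- IRangesList(
    IRanges(c(5001L, 12001L), c(6000L, 15000L)),
    IRanges(c(40001L, 47001L), c(42000L, 50000L)))
  seqlengths(g) <- c(chrT = 60000L)
  g
}

# negative log-likelihood of the two-group NB GLM with offsets log(s),
# used as the independent optimization oracle for the Wald fit
nbNegLogLik <- function(par, y, x, s, alpha) {
  mu <- exp(par[1] + par[2] * x) * s
  -sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

nbNegLogLikGrad <- function(par, y, x, s, alpha) {
  mu <- exp(par[1] + par[2] * x) * s
  r <- (y - mu) / (1 + alpha * mu)
  -c(sum(r), sum(r * x))
}

# the penalized logistic objective used as the optimization oracle
ridgeLogisticObjective <- function(par, X, y, lambda, balanced) {
  b0 <- par[1]
  beta <- par[-1]
  eta <- b0 + drop(X %*% beta)
  w <- rep(1, length(y))
  if (balanced) {
    n1 <- sum(y == 1)
    n0 <- sum(y == 0)
    w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  }
  sum(w * (log1p(exp(eta)) - y * eta)) + lambda / 2 * sum(beta^2)
}
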