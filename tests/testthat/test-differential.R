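test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(rep(c(10L, 20L, 40L), 3), 3, 3, byrow = FALSE,
              dimnames = list(letters[1:3], c("s1", "s2", "s3")))
  expect_equal(unname(medianOfRatios(m)), rep(1, 3))  # identical columns

  m2 <- cbind(s1 = c(10L, 20L), s2 = c(20L, 40L))
  rownames(m2) <- c("a", "b")
  sf <- medianOfRatios(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)

  # random matrix vs a direct double-loop oracle (odd row count, where the
  # linear and log-scale median of ratios coincide exactly)
  set.seed(1)
  m3 <- matrix(rpois(306, 40) + 1L, 51, 6,
               dimnames = list(sprintf("r%02d", 1:51), sprintf("s%d", 1:6)))
  oracle <- vapply(seq_len(ncol(m3)), function(j) {
    ratios <- numeric(0)
    for (i in seq_len(nrow(m3))) {
      gm <- exp(mean(log(m3[i, ])))
      ratios <- c(ratios, m3[i, j] / gm)
    }
    median(ratios)
  }, 0)
  expect_equal(unname(medianOfRatios(m3)), oracle)
  # all-zero rows everywhere -> informative error
  expect_error(medianOfRatios(matrix(c(0L, 1L, 2L, 0L), 2, 2)),
               "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, 100, 6,
              dimnames = list(sprintf("r%03d", 1:100), sprintf("s%d", 1:6)))
  expect_equal(unname(medianOfRatios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("dispersion estimation hits its floor and recovers Poisson data", {
  m <- matrix(7L, 20, 8, dimnames = list(sprintf("r%02d", 1:20), NULL))
  grp <- rep(c("A", "B"), each = 4)
  a <- estimateDispersion(m, rep(1, 8), grp)
  expect_true(all(a == 1e-8))

  set.seed(5)
  n <- 200
  mp <- matrix(rpois(500 * 2 * n, lambda = 100), 500, 2 * n)
  rownames(mp) <- sprintf("r%03d", 1:500)
  ap <- estimateDispersion(mp, rep(1, 2 * n), rep(c("A", "B"), each = n))
  expect_gte(mean(ap <= 0.01), 0.95)
})

test_that("the NB Wald fit matches closed-form limits and is antisymmetric", {
  set.seed(8)
  n <- 300
  m <- rbind(r1 = c(rpois(n, 100), rpois(n, 400)))
  grp <- rep(c("A", "B"), each = n)
  res <- nbWaldTest(m, rep(1, 2 * n), grp, dispersions = 1e-8)
  expect_equal(res$log2fc, 2, tolerance = 0.05)

  resSwap <- nbWaldTest(m, rep(1, 2 * n), grp, dispersions = 1e-8,
                        reference = "B")
  expect_equal(resSwap$log2fc, -res$log2fc, tolerance = 1e-10)
  expect_equal(resSwap$pvalue, res$pvalue, tolerance = 1e-10)

  # all-zero regions are flagged, p = 1, lfc = 0
  m0 <- rbind(r1 = rep(0L, 8), r2 = rpois(8, 50))
  r0 <- nbWaldTest(m0, rep(1, 8), rep(c("A", "B"), each = 4),
                   dispersions = 0.1)
  expect_equal(r0$status, c("all-zero", "ok"))
  expect_equal(r0$pvalue[1], 1)
  expect_equal(r0$log2fc[1], 0)
})

test_that("the NB GLM estimate matches an independent likelihood optimizer", {
  set.seed(11)
  for (rep in 1:5) {
    y <- rnbinom(6, mu = 60, size = 10)
    if (sum(y[1:3]) == 0 || sum(y[4:6]) == 0) next
    s <- exp(runif(6, -0.3, 0.3))
    x <- c(0, 0, 0, 1, 1, 1)
    alpha <- 0.1
    res <- nbWaldTest(rbind(r1 = y), s, c("A", "A", "A", "B", "B", "B"),
                      dispersions = alpha)
    opt <- optim(c(0, 0), nbNegLogLik, gr = nbNegLogLikGrad, y = y, x = x,
                 s = s, alpha = alpha, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 500))
    expect_equal(res$log2fc * log(2), opt$par[2], tolerance = 1e-6)
  }
})

test_that("Wald results track DESeq2 with matched normalization and dispersion", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  nR <- 80
  n <- 10
  mu <- rep(100, nR) * matrix(1, nR, 2 * n)
  mu[1:10, (n + 1):(2 * n)] <- 300
  m <- matrix(rnbinom(nR * 2 * n, mu = mu, size = 1 / 0.05), nR, 2 * n)
  rownames(m) <- sprintf("r%03d", seq_len(nR))
  colnames(m) <- sprintf("s%02d", seq_len(2 * n))
  grp <- factor(rep(c("A", "B"), each = n))
  sf <- medianOfRatios(m)
  res <- nbWaldTest(m, sf, grp, dispersions = 0.05)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(m, data.frame(cond = grp), ~cond)
    DESeq2::sizeFactors(dds) <- sf
    DESeq2::dispersions(dds) <- rep(0.05, nR)
    dds <- DESeq2::nbinomWaldTest(dds, betaPrior = FALSE)
    dres <- DESeq2::results(dds)
  })
  expect_equal(res$log2fc, dres$log2FoldChange, tolerance = 1e-3)
  expect_gt(cor(-log10(res$pvalue), -log10(dres$pvalue)), 0.999)
})

test_that("DhMR calling uses an inclusive lfc and strict p threshold", {
  res <- data.frame(id = c("a", "b", "c", "d", "e"),
                    log2fc = c(0.5, 0.49, -0.5, 2, -2),
                    pvalue = c(0.009, 0.001, 0.0099, 0.01, 0.5))
  calls <- callDhmrs(res, lfcMin = 0.5, pMax = 0.01)
  expect_equal(calls$up, "a")        # lfc exactly 0.5 is included
  expect_equal(calls$down, "c")      # p = 0.01 (d) and p = .5 (e) excluded
  empty <- callDhmrs(res, lfcMin = Inf, pMax = 0.01)
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("the Welch t-test matches the textbook formula", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6, 8)
  wt <- welchT(x, y)
  se2 <- var(x) / 3 + var(y) / 4
  tHand <- (mean(x) - mean(y)) / sqrt(se2)
  dfHand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 4)^2 / 3)
  expect_equal(wt$t, tHand)
  expect_equal(wt$df, dfHand)
  expect_equal(wt$p, 2 * pt(-abs(tHand), dfHand))

  swapped <- welchT(y, x)
  expect_equal(swapped$t, -wt$t)
  expect_equal(swapped$p, wt$p)
  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welchT(c(1, 1), c(2, 2)), "zero variance")
})

test_that("the rank-sum statistic equals a brute-force pair count", {
  x <- c(5, 6, 7)
  y <- c(1, 2)
  expect_equal(wilcoxonRankSum(x, y)$U, 6)       # all x above y
  expect_equal(wilcoxonRankSum(c(1, 2), c(1, 2))$U, 2)  # identical multisets

  set.seed(3)
  for (rep in 1:10) {
    a <- sample(1:8, 7, replace = TRUE)
    b <- sample(1:8, 5, replace = TRUE)
    u <- wilcoxonRankSum(a, b)$U
    oracle <- 0
    for (i in seq_along(a)) for (j in seq_along(b))
      oracle <- oracle + (a[i] > b[j]) + 0.5 * (a[i] == b[j])
    expect_equal(unname(u), oracle)
  }
})
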