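test_that("genome simulation is deterministic and honours a degenerate mix", {
  cfg <- tinyConfig(seed = 11)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.data.frame(g1$regions), as.data.frame(g2$regions))
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  expect_identical(mcols(g1$genes)$exons, mcols(g2$genes)$exons)

  pureIntron <- tinyConfig(seed = 2,
                           featureMix = c(promoter = 0, exon = 0,
                                          intron = 1, intergenic = 0),
                           nRegions = 40L)
  gi <- simulateGenome(pureIntron)
  expect_true(all(mcols(gi$regions)$feature == "intron"))

  # genes are non-overlapping within a chromosome, stranded, multi-exon
  genes <- g1$genes
  for (ch in unique(as.character(seqnames(genes)))) {
    gg <- genes[seqnames(genes) == ch]
    gg <- gg[order(start(gg))]
    if (length(gg) > 1)
      expect_true(all(start(gg)[-1] > end(gg)[-length(gg)]))
  }
  expect_true(all(as.character(strand(genes)) %in% c("+", "-")))
  expect_true(all(lengths(mcols(genes)$exons) >= 1))
  # candidate regions are pairwise disjoint
  expect_true(all(countOverlaps(g1$regions, g1$regions) == 1))
})

test_that("planted feature proportions track the configured mix", {
  cfg <- simConfig(seed = 7, nGenes = 50L, nRegions = 500L)
  g <- simulateGenome(cfg)
  prop <- table(factor(mcols(g$regions)$feature,
                       names(cfg@featureMix))) / length(g$regions)
  expect_true(all(abs(as.numeric(prop) - cfg@featureMix) <= 0.05))
})

test_that("count simulation respects the NB generative model", {
  regions <- flatRegions(60)
  # no planted effects -> empty ground truth
  cfg0 <- tinyConfig(seed = 5, fracDifferential = 0)
  cc0 <- simulateCounts(cfg0, regions)
  expect_length(cc0$truth@differentialRegionIds, 0)
  expect_true(all(cc0$truth@trueLog2fc == 0))

  # Poisson limit: dispersion ~ 0 makes normalized variance track the mean
  cfgP <- simConfig(seed = 9, dispersionRange = c(1e-8, 1e-8),
                    libsizeLogSd = 0, fracDifferential = 0,
                    groupSizes = c(PC = 100L, MLM = 100L))
  ccP <- simulateCounts(cfgP, flatRegions(300))
  m <- assay(ccP$experiment, "counts")
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(median(ratio) - 1), 0.1)

  # library sizes are realized column totals
  expect_equal(unname(librarySizes(cc0$experiment)),
               unname(colSums(assay(cc0$experiment, "counts"))))

  # null data: group-mean log2 ratios center at zero
  cfgN <- simConfig(seed = 13, fracDifferential = 0,
                    groupSizes = c(PC = 20L, MLM = 20L))
  ccN <- simulateCounts(cfgN, flatRegions(1000))
  mN <- assay(ccN$experiment, "counts")
  sf <- medianOfRatios(mN)
  z <- sweep(mN, 2, sf, "/")
  grp <- colData(ccN$experiment)$group
  lr <- log2(rowMeans(z[, grp == "MLM"]) + 0.5) -
        log2(rowMeans(z[, grp == "PC"]) + 0.5)
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("NB moment fidelity holds at fixed (q, alpha)", {
  # 1e4 draws per region at s_j = 1; mean within 3 SE of q and variance
  # within 3 SE of q + alpha q^2 (SE of the variance from empirical moments)
  cfg <- simConfig(seed = 21, dispersionRange = c(0.2, 0.2),
                   libsizeLogSd = 0, libsizeLogMean = 0,
                   fracDifferential = 0,
                   groupSizes = c(PC = 5000L, MLM = 5000L))
  cc <- simulateCounts(cfg, flatRegions(5))
  m <- assay(cc$experiment, "counts")
  q <- cc$truth@baselineMean
  alpha <- cc$truth@trueDispersion
  n <- ncol(m)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    seMean <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - q[i]), 3 * seMean)
    v <- var(x)
    m4 <- mean((x - mean(x))^4)
    seVar <- sqrt(pmax(m4 - v^2 * (n - 3) / (n - 1), 0) / n)
    expect_lt(abs(v - (q[i] + alpha[i] * q[i]^2)), 3 * seVar)
  }
})

test_that("peak emission follows the presence threshold exactly", {
  m <- matrix(c(5L, 9L, 12L), 1, 3,
              dimnames = list(names(flatRegions(1)), c("s1", "s2", "s3")))
  he <- HmcExperiment(m, regions = flatRegions(1))
  pk <- simulatePeaks(he, 10)
  expect_equal(lengths(pk), c(s1 = 0L, s2 = 0L, s3 = 1L))
  expect_true(all(lengths(simulatePeaks(he, 0)) == 1))
  expect_true(all(lengths(simulatePeaks(he, max(m) + 1)) == 0))
})

test_that("coverage simulation produces a body plateau with a TSS dip", {
  cfg <- tinyConfig(seed = 31)
  genes <- simulateGenome(cfg)$genes
  # no dip -> uniform coverage across every gene body
  flat <- simulateCoverage(genes, background = 1, bodyLevel = 4, dipFactor = 1)
  covs <- coverage(flat, weight = "score")
  g1 <- genes[1]
  body <- as.numeric(covs[[as.character(seqnames(g1))]][start(g1):end(g1)])
  expect_true(all(body == 4))
  # background-only configuration -> flat track everywhere
  bg <- simulateCoverage(genes, background = 2, bodyLevel = 2, dipFactor = 1)
  expect_true(all(mcols(bg)$score == 2))
  # with a dip, the metagene minimum falls at the body 5' boundary
  dip <- simulateCoverage(genes, background = 0.5, bodyLevel = 3,
                          dipFactor = 0.2, dipHalfwidth = 1000L)
  prof <- metageneProfile(dip, genes, bodyBins = 100L, flank = 2000L,
                          flankBins = 20L)
  amin <- which.min(profileValues(prof))
  boundary <- prof@upstreamBins + 1L
  expect_lte(abs(amin - boundary), 2L)
})

test_that("survival simulation ties hazard to the marker level", {
  lvl <- structure(seq_len(40), names = sprintf("p%02d", 1:40))
  cfgNoCens <- simConfig(seed = 3, censorRate = 0)
  sv <- simulateSurvival(lvl, cfgNoCens)
  expect_true(all(sv$os_event == 1))
  expect_true(all(sv$efs_event == 1))
  expect_identical(sv, simulateSurvival(lvl, cfgNoCens))  # deterministic

  # HR = 4: the high group's KM median falls below the low group's
  lvl200 <- seq_len(200)
  worse <- 0L
  for (k in 1:100) {
    cfg <- simConfig(seed = 1000 + k, survivalHazardRatio = 4,
                     censorRate = 0.005)
    sv <- simulateSurvival(lvl200, cfg)
    hl <- dichotomize(lvl200)
    fit <- survival::survfit(survival::Surv(sv$os_months, sv$os_event) ~ hl)
    med <- summary(fit)$table[, "median"]
    if (med[["hl=high"]] < med[["hl=low"]]) worse <- worse + 1L
  }
  expect_gte(worse, 95L)
})
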