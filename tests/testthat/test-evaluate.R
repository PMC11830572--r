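test_that("ROC curves and AUC match a pair-enumeration oracle", {
  r <- roc(c(.9, .8, .7, .6), c(1, 1, 0, 1))
  expect_equal(r$auc, 2 / 3)
  expect_equal(roc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)   # separated
  expect_equal(roc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)  # all tied
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))

  pairAuc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (k in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)  # ties likely
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc(s, y)$auc, pairAuc(s, y))
    # complement rule for tie-free scores
    s2 <- rnorm(12)
    expect_equal(roc(s2, y)$auc + roc(-s2, y)$auc, 1)
    # cross-module identity: U / (n+ n-) equals the AUC
    u <- wilcoxonRankSum(s[y == 1], s[y == 0])$U
    expect_equal(unname(u) / (sum(y) * sum(1 - y)), roc(s, y)$auc)
  }
  expect_error(roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  s <- rnorm(60)
  y <- rbinom(60, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s,
                                                         direction = "<"))))
  expect_equal(roc(s, y)$auc, ref)
})

test_that("confusion matrices count the >= threshold rule", {
  cm <- confusionAt(c(.9, .4, .6, .2), c(1, 0, 1, 0), 0.5)
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 2, FP = 0, TN = 2, FN = 0))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(confusionAt(c(.9, .4), c(1, 0), 0)$sensitivity, 1)
  hi <- confusionAt(c(.9, .4), c(1, 0), 2)
  expect_equal(hi$specificity, 1)
  expect_equal(hi$sensitivity, 0)
})

test_that("per-feature AUC reports the folded orientation with a flag", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(up = c(rnorm(10, 0), rnorm(10, 3)),
             down = c(rnorm(10, 3), rnorm(10, 0)),
             flat = rep(1, 20))
  pf <- perFeatureAuc(X, y)
  expect_equal(pf$orientation, c("positive", "negative", "constant"))
  expect_true(all(pf$auc >= 0.5))
  expect_equal(pf$auc[2], 1 - pf$rawAuc[2])
  expect_equal(pf$auc[3], 0.5)
  # a perfectly rank-aligned feature scores 1
  pf2 <- perFeatureAuc(cbind(f = 1:10), rep(c(0, 1), each = 5))
  expect_equal(pf2$auc, 1)
})

test_that("Pearson correlation matches the product-moment formula", {
  expect_equal(pearsonR(1:5, 1:5), 1)
  expect_equal(pearsonR(1:5, -(1:5)), -1)
  x <- c(1, 2, 3)
  y <- c(1, 2, 4)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), hand)
  expect_equal(round(hand, 4), 0.9820)
  expect_error(pearsonR(c(1, 1, 1), 1:3), "zero variance")
})

test_that("top-variance selection matches a brute-force sort", {
  set.seed(16)
  m <- matrix(rnorm(100), 20, 5,
              dimnames = list(sprintf("r%02d", 1:20), NULL))
  k <- 7
  tv <- topVariance(m, k)
  v <- apply(m, 1, var)
  oracle <- names(sort(v, decreasing = TRUE))[seq_len(k)]
  expect_setequal(rownames(tv), oracle)
  expect_identical(topVariance(m, nrow(m))[rownames(m), ], m)  # k = n
  # constant rows are never preferred over varying rows
  m2 <- rbind(m, rconst1 = rep(0, 5), rconst2 = rep(3, 5))
  expect_false(any(grepl("rconst", rownames(topVariance(m2, 20)))))
  expect_error(topVariance(m, 21), "exceeds")
})

test_that("PCA reconstructs its input and orders components", {
  set.seed(17)
  m <- matrix(rnorm(15), 5, 3)
  p <- pcaAnalysis(m, 3)
  rec <- p$scores %*% t(p$loadings) + rep(p$center, each = 5)
  expect_equal(rec, m, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  # variation along one axis puts everything on PC1
  m1 <- cbind(seq(1, 5), rep(2, 5), rep(-1, 5))
  expect_equal(pcaAnalysis(m1, 2)$explained[1], 1)

  # an orthogonal rotation leaves the spectrum unchanged
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(pcaAnalysis(m %*% q, 3)$explained, pcaAnalysis(m, 3)$explained)
})

test_that("Kaplan-Meier log-rank matches a hand-built risk table", {
  t1 <- c(5, 8, 12, 20)
  t2 <- c(30, 34, 40, 50)
  times <- c(t1, t2)
  events <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  km <- kmLogrank(times, events, grp)
  # hand-computed log-rank: observed vs expected under hypergeometric risk sets
  o1 <- 0; e1 <- 0; v <- 0
  for (tt in sort(times)) {
    atRisk1 <- sum(t1 >= tt); atRisk <- sum(times >= tt); d <- 1
    o1 <- o1 + (tt %in% t1)
    e1 <- e1 + d * atRisk1 / atRisk
    v <- v + d * (atRisk1 / atRisk) * (1 - atRisk1 / atRisk) *
      (atRisk - d) / max(atRisk - 1, 1)
  }
  expect_equal(km$chi2, (o1 - e1)^2 / v, tolerance = 1e-10)
  expect_equal(km$pvalue, pchisq((o1 - e1)^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical groups: chi-square 0, p = 1
  km0 <- kmLogrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(km0$chi2, 0, tolerance = 1e-12)
  expect_equal(km0$pvalue, 1, tolerance = 1e-12)

  # with no censoring the KM curve is the empirical survival function
  cu <- km$curves[km$curves$group == "a", ]
  expect_equal(cu$survival, 1 - seq_along(t1) / length(t1))
  expect_error(kmLogrank(times, rep(0, 8), grp), "no events")
})

test_that("dichotomization splits strictly above the cutoff", {
  expect_equal(unname(dichotomize(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(dichotomize(c(1, 1, 2))), c("low", "low", "high"))
  q75 <- dichotomize(1:8, q = 0.75)
  expect_equal(names(which(q75 == "high")), NULL)
  expect_equal(sum(q75 == "high"), 2)   # {7, 8}
  expect_equal(unname(q75[7:8]), c("high", "high"))
  expect_error(dichotomize(rep(2, 5)), "identical")
})
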