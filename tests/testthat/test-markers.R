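test_that("the stratified split follows per-class round-half-even allocation", {
  ids <- c(paste0("a", 1:6), paste0("b", 1:3))
  grp <- rep(c("A", "B"), c(6, 3))
  sp <- splitCohort(ids, grp, 2 / 3, seed = 4)
  expect_length(sp$train, 6)       # 4 A + 2 B
  expect_length(sp$validation, 3)  # 2 A + 1 B
  expect_equal(sum(grepl("^a", sp$train)), 4)
  expect_equal(sum(grepl("^b", sp$train)), 2)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, splitCohort(ids, grp, 2 / 3, seed = 4))
  expect_false(identical(sp, splitCohort(ids, grp, 2 / 3, seed = 5)))

  # cohort-sized split: 70 + 32 at 2:1 gives 47 + 21 training
  ids2 <- c(sprintf("PC%02d", 1:70), sprintf("MLM%02d", 1:32))
  grp2 <- rep(c("PC", "MLM"), c(70, 32))
  sp2 <- splitCohort(ids2, grp2, 2 / 3, seed = 1)
  expect_equal(sum(grepl("^PC", sp2$train)), 47)
  expect_equal(sum(grepl("^MLM", sp2$train)), 21)

  # a class that would lose all validation samples is an error
  expect_error(splitCohort(ids[1:9], grp, 0.95, seed = 1), "validation")
})

test_that("the penalized logistic fit matches an independent optimizer", {
  # 2-point, 1-feature dataset at lambda = 1
  X <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "f1"))
  y <- c(0, 1)
  fit <- fitPenalizedLogistic(X, y, lambda = 1)
  opt <- optim(c(0, 0), ridgeLogisticObjective, X = X, y = y, lambda = 1,
               balanced = TRUE, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(unname(fit$beta), opt$par[2], tolerance = 1e-5)
  expect_equal(fit$intercept, opt$par[1], tolerance = 1e-5)

  # a larger random problem, balanced and unbalanced weighting
  set.seed(9)
  X2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y2 <- c(rep(0, 12), rep(1, 8))
  for (bal in c(TRUE, FALSE)) {
    f <- fitPenalizedLogistic(X2, y2, lambda = 0.5,
                              classWeighting = if (bal) "balanced" else "none")
    o <- optim(rep(0, 4), ridgeLogisticObjective, X = X2, y = y2,
               lambda = 0.5, balanced = bal, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
    expect_equal(unname(c(f$intercept, f$beta)), o$par, tolerance = 1e-5)
  }

  # heavy regularization shrinks the coefficients away
  fBig <- fitPenalizedLogistic(X2, y2, lambda = 1e6)
  expect_lt(sqrt(sum(fBig$beta^2)), 1e-3)

  # balanced weighting is a no-op for perfectly balanced classes
  y3 <- rep(c(0, 1), 10)
  fb <- fitPenalizedLogistic(X2, y3, 0.3, "balanced")
  fn <- fitPenalizedLogistic(X2, y3, 0.3, "none")
  expect_equal(fb$beta, fn$beta, tolerance = 1e-9)
})

test_that("cross-validated accuracy behaves at the extremes", {
  set.seed(10)
  # separable data scores 1.0
  Xs <- matrix(c(rnorm(20, -4), rnorm(20, 4)), ncol = 1,
               dimnames = list(NULL, "f"))
  ys <- rep(c(0, 1), each = 20)
  cv <- cvScore(Xs, ys, lambdaGrid = c(0.01, 1), seed = 2)
  expect_equal(max(cv$accuracy), 1)

  # a single lambda is returned unchanged
  cv1 <- cvScore(Xs, ys, lambdaGrid = 0.5, seed = 2)
  expect_equal(cv1$bestLambda, 0.5)

  # random labels, noise features: accuracy near the majority frequency
  Xr <- matrix(rnorm(400 * 3), 400, 3, dimnames = list(NULL, c("a", "b", "c")))
  yr <- rep(c(0, 1), each = 200)
  cvr <- cvScore(Xr, yr, lambdaGrid = c(0.1, 1, 10), seed = 3)
  expect_lt(abs(max(cvr$accuracy) - 0.5), 0.12)
})

test_that("RFE keeps planted informative features and handles edge cases", {
  # two planted markers, each individually imperfect (unit shift on unit
  # noise) but jointly much stronger, among 48 noise features: the selected
  # set must contain both. (With a single overwhelming marker the
  # smallest-size-at-max-accuracy rule would legitimately keep only it.)
  set.seed(20)
  n <- 200
  found <- 0L
  for (k in 1:20) {
    X <- matrix(rnorm(n * 50), n, 50)
    colnames(X) <- sprintf("f%02d", 1:50)
    y <- rep(c(0, 1), each = n / 2)
    X[, "f01"] <- X[, "f01"] + ifelse(y == 1, 1, -1)
    X[, "f02"] <- X[, "f02"] + ifelse(y == 1, 1, -1)
    sel <- rfe(X, y, seed = 100 + k)$selected
    if (all(c("f01", "f02") %in% sel)) found <- found + 1L
  }
  expect_gte(found, 19L)

  # single feature: selected trivially
  X1 <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "only"))
  y1 <- rep(c(0, 1), each = 20)
  expect_equal(rfe(X1, y1, seed = 1)$selected, "only")

  # a duplicated informative feature never grows the selected size
  X <- matrix(rnorm(200 * 10), 200, 10)
  colnames(X) <- sprintf("g%02d", 1:10)
  y <- rep(c(0, 1), each = 100)
  X[, "g01"] <- X[, "g01"] + ifelse(y == 1, 2, -2)
  X[, "g02"] <- X[, "g01"]
  r <- rfe(X, y, seed = 7)
  expect_lte(length(r$selected), ncol(X))
  expect_true(any(c("g01", "g02") %in% r$selected))
})

test_that("stability selection applies the within-round and consensus rules", {
  set.seed(30)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- sprintf("m%d", 1:6)
  y <- rep(c(0, 1), each = n / 2)
  X[, "m1"] <- X[, "m1"] + ifelse(y == 1, 5, -5)  # perfectly predictive
  panel <- stabilitySelect(X, y, nRepeats = 10L, seed = 42)
  expect_true("m1" %in% panelMarkers(panel))
  expect_equal(unname(roundsObserved(panel)["m1"]), 5L)
  expect_true(all(selectionFrequencies(panel)["m1", ] == 1))

  # deterministic under a fixed seed
  panel2 <- stabilitySelect(X, y, nRepeats = 10L, seed = 42)
  expect_identical(selectionFrequencies(panel), selectionFrequencies(panel2))
  expect_identical(panelMarkers(panel), panelMarkers(panel2))

  # the panel shrinks (weakly) as minRounds rises
  sizes <- vapply(1:5, function(k) {
    length(panelMarkers(stabilitySelect(X, y, nRepeats = 5L, minRounds = k,
                                        seed = 42)))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the >=3-of-5 consensus rule retains and drops markers correctly", {
  freq <- matrix(c(1, 0, 1, 0, 1,     # observed rounds {1,3,5} -> retained
                   0, 1, 0, 1, 0),    # observed rounds {2,4}   -> dropped
                 2, 5, byrow = TRUE,
                 dimnames = list(c("mKeep", "mDrop"), paste0("round", 1:5)))
  panel <- new("MarkerPanel", markers = "mKeep",
               roundsObserved = c(mKeep = 3L, mDrop = 2L),
               frequencies = freq, minRounds = 3L, withinRoundRule = 0.5)
  expect_identical(panelMarkers(panel), "mKeep")
  # the class enforces consistency between markers and roundsObserved
  expect_error(new("MarkerPanel", markers = c("mKeep", "mDrop"),
                   roundsObserved = c(mKeep = 3L, mDrop = 2L),
                   frequencies = freq, minRounds = 3L,
                   withinRoundRule = 0.5),
               "minRounds")
})

test_that("the final model freezes training statistics and predicts monotonically", {
  set.seed(40)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  y <- factor(rep(c("PC", "MLM"), each = n / 2), levels = c("PC", "MLM"))
  X[, "m1"] <- X[, "m1"] + ifelse(y == "MLM", 4, -4)
  model <- trainFinalModel(X, y, seed = 6)
  expect_s4_class(model, "HmcClassifier")
  expect_equal(model@classLevels[2], "MLM")

  # probabilities are monotone in the dominant marker
  grid <- cbind(m1 = seq(-5, 5, length.out = 11), m2 = 0, m3 = 0)
  pr <- predictProbability(model, grid)
  expect_true(all(diff(pr) > 0))

  # refitting with the same seed reproduces the weights exactly
  model2 <- trainFinalModel(X, y, seed = 6)
  expect_identical(model@weights, model2@weights)
  expect_identical(model@lambda, model2@lambda)

  # validation data never feeds back into the model (no leakage)
  Xv <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  p1 <- predictProbability(model, Xv)
  p2 <- predictProbability(model, Xv[sample(10), ])
  expect_setequal(round(p1, 12), round(p2, 12))
  expect_equal(model@featureCenter, unname(colMeans(X)))
})
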