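#' Stratified 2:1 cohort split
#'
#' Randomly partitions samples of two groups into training and validation
#' cohorts. With stratification each class contributes
#' \code{round(trainFraction * n)} training samples (round-half-even), so a
#' 70/32 cohort splits 47/21 for training at the default 2:1 ratio.
#'
#' @param sampleIds character sample ids.
#' @param groups class label per sample (exactly two classes, each >= 3).
#' @param trainFraction default 2/3.
#' @param stratified default TRUE (per-class allocation); otherwise the
#'   overall count is allocated at random.
#' @param seed integer; the partition is deterministic given the seed.
#' @return list with \code{train} and \code{validation} id vectors
#'   (exhaustive and disjoint).
#' @export
splitCohort <- function(sampleIds, groups, trainFraction = 2 / 3,
                        stratified = TRUE, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1)")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 samples")
  .withSeed(.deriveSeed(seed, "split"), {
    train <- character(0)
    if (stratified) {
      for (g in levels(groups)) {
        ids <- sampleIds[groups == g]
        nTr <- round(trainFraction * length(ids))
        if (nTr >= length(ids))
          stop("class '", g, "' would get no validation samples")
        if (nTr < 1L) stop("class '", g, "' would get no training samples")
        train <- c(train, sample(ids)[seq_len(nTr)])
      }
    } else {
      nTr <- round(trainFraction * length(sampleIds))
      train <- sample(sampleIds)[seq_len(nTr)]
    }
    validation <- setdiff(sampleIds, train)
    for (g in levels(groups)) {
      if (!any(groups[match(validation, sampleIds)] == g))
        stop("class '", g, "' would get no validation samples")
    }
    list(train = sort(train), validation = sort(validation))
  })
}

# stratified fold assignment (0-based, for the C++ kernels)
.stratifiedFolds <- function(y, nfold) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(nfold) - 1L, length.out = length(idx))
  }
  if (any(vapply(split(y, fold), function(v) length(unique(v)), 0L) < 2L))
    stop("a fold lost one of the classes; too few samples for ", nfold,
         "-fold stratified CV")
  fold
}

#' Fit an L2-penalized logistic regression
#'
#' Minimizes \eqn{\sum_i w_i\,\ell(y_i, \beta_0 + x_i'\beta) +
#' (\lambda/2)\|\beta\|^2} with an unpenalized intercept by damped Newton
#' iterations (gradient inf-norm < 1e-8 at the solution). With
#' \code{classWeighting = "balanced"}, \eqn{w_i = n / (2 n_{class(i)})}.
#' Features should be standardized beforehand ([trainFinalModel()] does this
#' and freezes the training statistics).
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1, logical, or 2-level factor with the second
#'   level positive).
#' @param lambda L2 penalty strength (>= 0).
#' @param classWeighting "balanced" or "none".
#' @param maxit maximum Newton iterations (default 100).
#' @return list with \code{intercept}, \code{beta}, \code{converged},
#'   \code{grad_norm}. Non-convergence is an error carrying the gradient
#'   norm.
#' @export
fitPenalizedLogistic <- function(X, y, lambda, classWeighting = "balanced",
                                 maxit = 100L) {
  X <- as.matrix(X)
  y01 <- .binLabels(y)
  if (length(unique(y01)) < 2L) stop("labels are constant")
  fit <- .ridge_logistic_cpp(X, y01, lambda,
                             balanced = classWeighting == "balanced",
                             tol = 1e-8, maxit = as.integer(maxit))
  if (!fit$converged)
    stop("penalized logistic fit did not converge in ", maxit,
         " iterations (gradient norm ", format(fit$grad_norm), ")")
  names(fit$beta) <- colnames(X)
  fit
}

.binLabels <- function(y) {
  if (is.factor(y)) as.numeric(y == levels(y)[2])
  else if (is.logical(y)) as.numeric(y)
  else as.numeric(y != 0)
}

#' Cross-validated accuracy over a lambda grid
#'
#' Mean held-out accuracy of the penalized logistic model per lambda under
#' stratified k-fold CV; the best lambda has the highest mean accuracy, ties
#' resolved toward the larger (more regularized) lambda.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param lambdaGrid positive lambdas to score.
#' @param folds number of folds (default 2, stratified).
#' @param classWeighting passed to the fit.
#' @param seed fold-assignment seed.
#' @return list with \code{bestLambda} and named \code{accuracy} per lambda.
#' @export
cvScore <- function(X, y, lambdaGrid = .defaultLambdaGrid, folds = 2L,
                    classWeighting = "balanced", seed = 1L) {
  X <- as.matrix(X)
  y01 <- .binLabels(y)
  fold <- .withSeed(.deriveSeed(seed, "folds"),
                    .stratifiedFolds(y01, folds))
  acc <- .cv_accuracy_cpp(X, y01, fold, lambdaGrid,
                          balanced = classWeighting == "balanced")
  names(acc) <- as.character(lambdaGrid)
  best <- max(acc)
  bestLambda <- max(lambdaGrid[acc >= best - 1e-12])
  list(bestLambda = bestLambda, accuracy = acc)
}

.defaultLambdaGrid <- 10^seq(-2, 2)

#' Recursive feature elimination with internal CV
#'
#' Iteratively fits the penalized logistic model (lambda chosen by internal
#' stratified CV at every size), drops the
#' \code{ceiling(stepFraction * remaining)} features with the smallest
#' absolute weight (ties eliminated in lexicographic id order), and records
#' the CV accuracy at each size. Selected is the smallest feature-set size
#' whose accuracy is within 1e-12 of the maximum. The CV fold assignment is
#' drawn once per call from \code{seed} and reused at every size.
#'
#' @param X samples x features matrix with column names (feature ids).
#' @param y binary labels.
#' @param stepFraction fraction of surviving features dropped per step
#'   (default 0.1).
#' @param folds internal CV folds (default 2).
#' @param lambdaGrid lambdas scored at each size.
#' @param classWeighting passed to the fits.
#' @param seed fold-assignment seed.
#' @return list with \code{sizes}, \code{accuracy}, \code{lambda} (per
#'   size), \code{selected} (feature ids), \code{ranking} (elimination
#'   order, first out first) and \code{featureSets}.
#' @export
rfe <- function(X, y, stepFraction = 0.1, folds = 2L,
                lambdaGrid = .defaultLambdaGrid, classWeighting = "balanced",
                seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)))
  ord <- order(colnames(X))  # lexicographic column order fixes tie-breaks
  X <- X[, ord, drop = FALSE]
  y01 <- .binLabels(y)
  if (ncol(X) < 1L) stop("need at least one feature")
  if (ncol(X) == 1L) {
    cv <- cvScore(X, y01, lambdaGrid, folds, classWeighting, seed)
    return(list(sizes = 1L, accuracy = unname(max(cv$accuracy)),
                lambda = cv$bestLambda, selected = colnames(X),
                ranking = character(0),
                featureSets = list(colnames(X))))
  }
  fold <- .withSeed(.deriveSeed(seed, "folds"),
                    .stratifiedFolds(y01, folds))
  res <- .rfe_cpp(X, y01, fold, lambdaGrid, stepFraction,
                  balanced = classWeighting == "balanced")
  nm <- colnames(X)
  list(sizes = res$sizes, accuracy = res$accuracy, lambda = res$lambda,
       selected = nm[res$selected],
       ranking = nm[res$elimination_order],
       featureSets = lapply(res$feature_sets, function(i) nm[i]))
}

#' Stability-consensus marker selection
#'
#' The selection procedure applied to the DhMRs called on the training
#' cohort: in each of \code{nRounds} rounds a stratified
#' \code{roundFraction} subset of the training samples is drawn and [rfe()]
#' is run \code{nRepeats} times with distinct derived seeds; a marker is
#' "observed" in a round iff it is selected in at least
#' \code{withinRoundRule} of the round's repeats, and the panel retains
#' markers observed in at least \code{minRounds} rounds.
#'
#' @param X training samples x candidate-marker matrix (column names are
#'   marker ids).
#' @param y binary labels.
#' @param nRounds default 5.
#' @param roundFraction subset fraction per round (default 4/5, stratified).
#' @param nRepeats RFE repeats per round (default 100).
#' @param withinRoundRule within-round selection-frequency threshold
#'   (default 0.5).
#' @param minRounds consensus threshold (default 3).
#' @param stepFraction,folds,lambdaGrid,classWeighting passed to [rfe()].
#' @param seed master seed; rounds and repeats derive their own streams.
#' @return A \linkS4class{MarkerPanel}. An empty panel is a valid result
#'   (the frequencies are still reported).
#' @export
stabilitySelect <- function(X, y, nRounds = 5L, roundFraction = 4 / 5,
                            nRepeats = 100L, withinRoundRule = 0.5,
                            minRounds = 3L, stepFraction = 0.1, folds = 2L,
                            lambdaGrid = .defaultLambdaGrid,
                            classWeighting = "balanced", seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must carry marker ids as column names")
  y01 <- .binLabels(y)
  markers <- sort(colnames(X))
  X <- X[, markers, drop = FALSE]
  freq <- matrix(0, length(markers), nRounds,
                 dimnames = list(markers, paste0("round", seq_len(nRounds))))
  for (r in seq_len(nRounds)) {
    sub <- .withSeed(.deriveSeed(seed, "stability", r), {
      idx <- integer(0)
      for (cls in unique(y01)) {
        ci <- which(y01 == cls)
        k <- max(2L, round(roundFraction * length(ci)))
        idx <- c(idx, sample(ci)[seq_len(k)])
      }
      sort(idx)
    })
    Xr <- X[sub, , drop = FALSE]
    yr <- y01[sub]
    hits <- numeric(length(markers))
    for (k in seq_len(nRepeats)) {
      rs <- .deriveSeed(seed, "stability", r * 100003L + k)
      sel <- rfe(Xr, yr, stepFraction = stepFraction, folds = folds,
                 lambdaGrid = lambdaGrid, classWeighting = classWeighting,
                 seed = rs)$selected
      hits[markers %in% sel] <- hits[markers %in% sel] + 1
    }
    freq[, r] <- hits / nRepeats
  }
  observed <- rowSums(freq >= withinRoundRule)
  retained <- sort(markers[observed >= minRounds])
  new("MarkerPanel", markers = retained,
      roundsObserved = structure(as.integer(observed), names = markers),
      frequencies = freq, minRounds = as.integer(minRounds),
      withinRoundRule = withinRoundRule)
}

#' Train the final marker-panel classifier
#'
#' Standardizes the training features (statistics frozen into the model),
#' chooses lambda by [cvScore()] and fits the penalized logistic model on
#' the full training cohort.
#'
#' @param X training samples x features matrix restricted to the panel
#'   (column names are marker ids).
#' @param y binary labels; if a factor, the second level is the positive
#'   class.
#' @param lambdaGrid lambdas for internal CV.
#' @param folds internal CV folds (default 2).
#' @param classWeighting "balanced" (default) or "none".
#' @param seed CV fold seed.
#' @return An \linkS4class{HmcClassifier}.
#' @export
trainFinalModel <- function(X, y, lambdaGrid = .defaultLambdaGrid, folds = 2L,
                            classWeighting = "balanced", seed = 1L) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("the marker panel is empty")
  if (is.null(colnames(X))) stop("X must carry marker ids as column names")
  lv <- if (is.factor(y)) levels(y) else as.character(sort(unique(.binLabels(y))))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  cv <- cvScore(Xs, y, lambdaGrid, folds, classWeighting, seed)
  fit <- fitPenalizedLogistic(Xs, y, cv$bestLambda, classWeighting)
  new("HmcClassifier", markerIds = colnames(X), weights = unname(fit$beta),
      intercept = fit$intercept, lambda = cv$bestLambda,
      featureCenter = unname(ctr), featureScale = unname(scl),
      classWeighting = classWeighting, classLevels = lv)
}

#' Predicted positive-class probabilities
#'
#' Applies the frozen training standardization and the logistic link; the
#' validation data never re-estimates any statistic.
#'
#' @param model an \linkS4class{HmcClassifier}.
#' @param X samples x features matrix containing the model's markers.
#' @return Numeric probabilities in (0, 1), named by sample.
#' @export
predictProbability <- function(model, X) {
  X <- as.matrix(X)[, model@markerIds, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model@featureCenter, "-"), 2L,
              model@featureScale, "/")
  eta <- model@intercept + drop(Xs %*% model@weights)
  stats::plogis(eta)
}

#' Marker feature matrix from counts
#'
#' The feature representation entering selection and classification:
#' \code{log2(normalized count + 1)} per sample, where normalized counts are
#' raw counts divided by the provided size factors.
#'
#' @param counts count matrix or \linkS4class{HmcExperiment}.
#' @param sizeFactors per-sample size factors (default: median-of-ratios).
#' @param ids optional subset of region ids (rows).
#' @return samples x regions numeric matrix (transposed, ready for the
#'   classifier).
#' @export
markerFeatures <- function(counts, sizeFactors = NULL, ids = NULL) {
  m <- .asCounts(counts)
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(m)
  z <- sweep(m, 2L, sizeFactors, "/")
  if (!is.null(ids)) z <- z[ids, , drop = FALSE]
  t(log2(z + 1))
}
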