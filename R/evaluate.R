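#' @importFrom stats cor prcomp pchisq quantile sd
#' @importFrom survival survfit survdiff Surv
NULL

#' ROC curve and trapezoidal AUC
#'
#' Curve over all distinct score thresholds (ties grouped, yielding diagonal
#' segments); AUC by the trapezoidal rule, which equals the rank-sum
#' identity \eqn{U/(n_+ n_-)}.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (1/TRUE/second factor level = positive).
#' @return list with \code{thresholds}, \code{fpr}, \code{tpr} (both
#'   non-decreasing along the curve) and \code{auc}.
#' @export
roc <- function(scores, labels) {
  y <- .binLabels(labels)
  nPos <- sum(y == 1)
  nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy)
  fp <- cumsum(1 - yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Confusion matrix at a probability threshold
#'
#' Predicts positive iff \code{score >= threshold}.
#'
#' @param scores numeric scores or probabilities.
#' @param labels binary labels.
#' @param threshold default 0.5.
#' @return list with \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{sensitivity} = TP/(TP+FN), \code{specificity} = TN/(TN+FP).
#' @export
confusionAt <- function(scores, labels, threshold = 0.5) {
  y <- .binLabels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pred <- as.numeric(scores >= threshold)
  TP <- sum(pred == 1 & y == 1)
  FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = TP / (TP + FN), specificity = TN / (TN + FP))
}

#' Per-feature AUC
#'
#' The ROC AUC of each feature column as a univariate score. Orientation is
#' fixed to the reported class-1-high direction: the returned \code{auc} is
#' \code{max(a, 1 - a)} with \code{orientation} recording whether the raw
#' direction was "positive" or "negative" (a constant feature reports 0.5,
#' flagged "constant").
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @return data.frame with \code{feature}, \code{auc}, \code{rawAuc},
#'   \code{orientation}.
#' @export
perFeatureAuc <- function(X, y) {
  X <- as.matrix(X)
  out <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (sd(v) == 0)
      return(data.frame(feature = colnames(X)[j], auc = 0.5, rawAuc = 0.5,
                        orientation = "constant"))
    a <- roc(v, y)$auc
    data.frame(feature = colnames(X)[j], auc = max(a, 1 - a), rawAuc = a,
               orientation = if (a >= 0.5) "positive" else "negative")
  })
  do.call(rbind, out)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y, method = "pearson")
}

#' Top-variance row subset
#'
#' The k rows of largest sample variance, ties broken lexicographically by
#' row name.
#'
#' @param m numeric matrix with row names.
#' @param k number of rows to keep (k <= nrow).
#' @return Row subset of \code{m}, ordered by decreasing variance.
#' @export
topVariance <- function(m, k) {
  if (k > nrow(m)) stop("k exceeds the number of rows")
  v <- apply(m, 1L, var)
  ord <- order(-v, rownames(m))
  m[ord[seq_len(k)], , drop = FALSE]
}

#' Principal component analysis
#'
#' Column-centered SVD of a samples x features matrix.
#'
#' @param m samples x features numeric matrix.
#' @param nComponents number of components (<= min(dim)).
#' @return list with \code{scores} (samples x components), \code{loadings},
#'   \code{explained} (variance fractions, non-increasing, summing to <= 1)
#'   and \code{center}.
#' @export
pcaAnalysis <- function(m, nComponents = 2L) {
  m <- as.matrix(m)
  if (nComponents > min(dim(m))) stop("nComponents exceeds min(dim)")
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  list(scores = pr$x[, k, drop = FALSE],
       loadings = pr$rotation[, k, drop = FALSE],
       explained = (pr$sdev^2 / sum(pr$sdev^2))[k],
       center = pr$center)
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit estimator per group and the unstratified two-sample
#' log-rank chi-square (1 df) with the standard hypergeometric variance,
#' via \pkg{survival}.
#'
#' @param times non-negative event/censoring times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @param group binary group per sample.
#' @return list with \code{curves} (data.frame: group, time, survival),
#'   \code{chi2}, \code{pvalue} and the underlying \code{fit}.
#' @export
kmLogrank <- function(times, events, group) {
  if (any(times < 0)) stop("times must be >= 0")
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0))
    stop("two non-empty groups are required")
  if (sum(events) == 0) stop("no events; the log-rank test is undefined")
  fit <- survfit(Surv(times, events) ~ group)
  sd <- survdiff(Surv(times, events) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, survival = fit$surv)
  list(curves = curves, chi2 = unname(sd$chisq),
       pvalue = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
       fit = fit)
}

#' Median (or quantile) dichotomization into high/low groups
#'
#' High iff value > cutoff (strictly); ties go low. The default cutoff is
#' the median; \code{q} selects another quantile (type 7).
#'
#' @param values numeric vector with >= 2 distinct values.
#' @param q quantile in (0, 1), default 0.5.
#' @return character vector "high"/"low", names preserved.
#' @export
dichotomize <- function(values, q = 0.5) {
  if (length(unique(values)) < 2L)
    stop("all values identical; dichotomization is undefined")
  cut <- quantile(values, q, names = FALSE)
  structure(ifelse(values > cut, "high", "low"), names = names(values))
}
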