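#' PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis for a binary response, fit by
#' the NIPALS algorithm with deflation. The response is coded +/-1 and
#' centered; `X` is centered (it is normally already z-scored from
#' [preprocess()]). For a single response the first weight vector is
#' proportional to `t(X) %*% y`. Class prediction thresholds the fitted
#' response at 0.
#'
#' @param X numeric matrix, samples x features (preprocessed).
#' @param y binary response: +/-1, logical, or two-level factor.
#' @param nComp number of components; truncated with a warning when the
#'   residual matrix runs out of rank.
#' @return object of class `PlsdaModel`: weights `W` (columns normalized to
#'   unit length), scores `Tmat`, loadings `P`, response loadings `q`,
#'   per-component explained response sum of squares `ssy`, centers, `vip`
#'   (see [vipScores()]), coefficient vector `b`, levels.
#' @export
plsdaFit <- function(X, y, nComp = 2) {
  X <- as.matrix(X)
  yc <- .codeY(y)
  if (nrow(X) != length(yc$y)) stop("X rows and y length differ")
  if (nComp < 1) stop("nComp must be >= 1")
  xm <- colMeans(X)
  ym <- mean(yc$y)
  E <- sweep(X, 2, xm)
  f <- yc$y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tmat <- matrix(0, nrow(X), 0)
  q <- ssy <- numeric(0)
  for (a in seq_len(nComp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("nComp truncated to ", a - 1L, " (residual rank exhausted)")
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pa <- drop(crossprod(E, tt)) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pa)
    f <- f - tt * qa
    W <- cbind(W, w); P <- cbind(P, pa); Tmat <- cbind(Tmat, tt)
    q <- c(q, qa); ssy <- c(ssy, qa^2 * tt2)
  }
  if (ncol(W) == 0) stop("no usable PLS component (X is constant)")
  # regression vector on centered X: b = W (P'W)^-1 q
  b <- drop(W %*% solve(crossprod(P, W), q))
  model <- list(W = W, P = P, Tmat = Tmat, q = q, ssy = ssy,
                xMeans = xm, yMean = ym, b = b, nComp = ncol(W),
                levels = yc$levels)
  model$vip <- vipScores(model)
  class(model) <- "PlsdaModel"
  model
}

.codeY <- function(y) {
  if (is.logical(y)) y <- factor(y)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2) stop("y must be binary")
    list(y = ifelse(y == levels(y)[2], 1, -1), levels = levels(y))
  } else {
    u <- sort(unique(y))
    if (!all(u %in% c(-1, 1))) stop("numeric y must be coded +/-1")
    list(y = as.numeric(y), levels = c("-1", "1"))
  }
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_aj / ||w_a||)^2 / sum_a SSY_a )`,
#' where `SSY_a` is the response sum of squares explained by component `a`.
#' Mean squared VIP is 1 by construction (`sum(VIP^2) = p`).
#'
#' @param model a fitted `PlsdaModel`.
#' @return named numeric vector of per-feature VIP scores.
#' @export
vipScores <- function(model) {
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("zero explained response sum of squares")
  W <- model$W
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(wn^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(W)
  vip
}

#' Predict classes from a PLS-DA model
#'
#' @param model a `PlsdaModel`.
#' @param X new data, samples x features (same columns as at fit time).
#' @return list with `score` (fitted centered response) and `class` (second
#'   factor level where score > 0).
#' @export
plsdaPredict <- function(model, X) {
  X <- as.matrix(X)
  sc <- drop(sweep(X, 2, model$xMeans) %*% model$b)
  cls <- ifelse(sc > 0, model$levels[2], model$levels[1])
  list(score = sc + model$yMean, class = cls)
}

#' Cross-validated PLS-DA accuracy
#'
#' Stratified k-fold cross-validation; out-of-fold class predictions are
#' pooled into one accuracy.
#'
#' @inheritParams plsdaFit
#' @param kFolds folds (capped at the smaller class size).
#' @param seed integer seed for the fold assignment.
#' @return list with `accuracy` and the pooled `predictions`.
#' @export
plsdaCvAccuracy <- function(X, y, nComp = 2, kFolds = 10, seed = 1) {
  y <- factor(y)
  folds <- .stratifiedFolds(y, kFolds, seed)
  pred <- character(length(y))
  for (k in sort(unique(folds))) {
    te <- folds == k
    fit <- plsdaFit(X[!te, , drop = FALSE], y[!te], nComp = nComp)
    pred[te] <- plsdaPredict(fit, X[te, , drop = FALSE])$class
  }
  list(accuracy = mean(pred == as.character(y)), predictions = pred)
}

.stratifiedFolds <- function(y, kFolds, seed) {
  y <- factor(y)
  kFolds <- min(kFolds, min(table(y)))
  if (kFolds < 2) stop("kFolds must be >= 2 and <= the smaller class size")
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(kFolds), length(idx)))
  }
  folds
}

#' Select metabolites by PLS-DA VIP
#'
#' Fits a PLS-DA on the preprocessed table and returns the metabolites with
#' VIP above a threshold (default 1, the conventional
#' "above-average-contribution" cutoff).
#'
#' @param x a preprocessed [MetaboliteExperiment-class].
#' @param groupA,groupB group labels to contrast.
#' @param nComp components (default 2).
#' @param vipThreshold selection cutoff on VIP.
#' @return list with `selected` ids, `vip` vector and the fitted `model`.
#' @export
plsdaSelect <- function(x, groupA = "HC", groupB = "cART", nComp = 2,
                        vipThreshold = 1) {
  g <- sampleGroups(x)
  keep <- g %in% c(groupA, groupB)
  X <- t(abundanceMatrix(x)[, keep, drop = FALSE])
  y <- factor(g[keep], levels = c(groupA, groupB))
  model <- plsdaFit(X, y, nComp = nComp)
  vip <- model$vip
  list(selected = names(vip)[vip > vipThreshold], vip = vip, model = model)
}
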