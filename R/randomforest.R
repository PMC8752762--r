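#' @importFrom ranger ranger
NULL

.balancedWeights <- function(y) {
  tab <- table(y)
  w <- as.numeric(length(y) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

.rangerFit <- function(X, y, nTrees, probability = FALSE) {
  df <- data.frame(X, check.names = FALSE)
  df$.y <- y
  ranger(dependent.variable.name = ".y", data = df, num.trees = nTrees,
         importance = "impurity", probability = probability,
         class.weights = .balancedWeights(y), respect.unordered.factors = TRUE)
}

#' Boruta-style all-relevant feature selection
#'
#' Iterative shadow-feature selection: at each iteration every still-undecided
#' feature is paired with a permuted ("shadow") copy, a balanced random
#' forest is fit on real + shadow features, and a feature scores a hit when
#' its importance exceeds the best shadow importance. After each iteration a
#' two-sided binomial test of the hit count against Binomial(iterations, 0.5)
#' confirms (significantly many hits) or rejects (significantly few) features
#' at level `alpha`; the loop runs until everything is decided or `maxIter`
#' is reached, leaving the remainder tentative.
#'
#' @param X samples x features numeric matrix.
#' @param y two-level factor (>= 5 samples per class).
#' @param nTrees trees per forest (default 500).
#' @param maxIter iteration cap (default 100).
#' @param alpha binomial test level (default 0.01). As `alpha` approaches 1
#'   every feature is decided at the first iteration.
#' @param seed integer seed; the procedure is deterministic given it.
#' @return list with `confirmed`, `tentative`, `rejected` (feature-name
#'   partitions of the candidates), `importance` (mean impurity importance of
#'   the real features over iterations), `hits`, `nIter`.
#' @export
borutaSelect <- function(X, y, nTrees = 500, maxIter = 100, alpha = 0.01,
                         seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (min(table(y)) < 5) stop("need >= 5 samples per class")
  if (maxIter < 1) stop("maxIter must be >= 1")
  set.seed(as.integer(seed))
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  status <- setNames(rep("undecided", length(feats)), feats)
  hits <- setNames(integer(length(feats)), feats)
  impSum <- setNames(numeric(length(feats)), feats)
  impN <- setNames(integer(length(feats)), feats)
  iter <- 0
  while (any(status == "undecided") && iter < maxIter) {
    iter <- iter + 1
    cand <- names(status)[status == "undecided"]
    Xc <- X[, cand, drop = FALSE]
    # at least 5 shadows, so a lucky survivor cannot outrun a thin shadow max
    shadowSrc <- cand
    while (length(shadowSrc) < 5)
      shadowSrc <- c(shadowSrc, cand[sample.int(length(cand), 1)])
    Xs <- apply(X[, shadowSrc, drop = FALSE], 2, sample)
    colnames(Xs) <- paste0(".shadow.", seq_along(shadowSrc))
    fit <- .rangerFit(cbind(Xc, Xs), y, nTrees)
    imp <- fit$variable.importance
    shadowMax <- max(imp[colnames(Xs)])
    realImp <- imp[cand]
    hits[cand] <- hits[cand] + (realImp > shadowMax)
    impSum[cand] <- impSum[cand] + realImp
    impN[cand] <- impN[cand] + 1L
    # two-sided binomial decision on the hit trajectories
    for (f in cand) {
      pUp <- stats::pbinom(hits[f] - 1, iter, 0.5, lower.tail = FALSE)
      pDown <- stats::pbinom(hits[f], iter, 0.5)
      pTwo <- min(1, 2 * min(pUp, pDown))
      if (pTwo <= alpha)
        status[f] <- if (hits[f] > iter / 2) "confirmed" else "rejected"
    }
  }
  status[status == "undecided"] <- "tentative"
  list(confirmed = names(status)[status == "confirmed"],
       tentative = names(status)[status == "tentative"],
       rejected = names(status)[status == "rejected"],
       importance = ifelse(impN > 0, impSum / pmax(impN, 1L), NA),
       hits = hits, nIter = iter)
}

#' Cross-validated random-forest accuracy
#'
#' Stratified k-fold cross-validation of a balanced random forest;
#' out-of-fold predictions are pooled into one accuracy, confusion matrix and
#' AUROC.
#'
#' @param X samples x features matrix.
#' @param y two-level factor; `kFolds` must not exceed the smaller class.
#' @param kFolds folds (default 10).
#' @param nTrees trees (default 500).
#' @param seed integer seed.
#' @return list with `accuracy`, `confusion` (2x2 table over all samples),
#'   `auroc`, and the pooled out-of-fold class probabilities.
#' @export
rfCvAccuracy <- function(X, y, kFolds = 10, nTrees = 500, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("y has a single class")
  folds <- .stratifiedFolds(y, kFolds, seed)
  prob <- numeric(length(y))
  for (k in sort(unique(folds))) {
    te <- folds == k
    fit <- .rangerFit(X[!te, , drop = FALSE], droplevels(y[!te]), nTrees,
                      probability = TRUE)
    pr <- stats::predict(fit, data.frame(X[te, , drop = FALSE],
                                         check.names = FALSE))$predictions
    prob[te] <- pr[, levels(y)[2]]
  }
  pred <- factor(ifelse(prob > 0.5, levels(y)[2], levels(y)[1]),
                 levels = levels(y))
  confusion <- table(truth = y, predicted = pred)
  auroc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                          levels = levels(y),
                                          direction = "<", quiet = TRUE)))
  list(accuracy = mean(pred == y), confusion = confusion, auroc = auroc,
       probabilities = prob)
}

#' Pathway-term importance for metabolite-level labels
#'
#' Trains a balanced random forest to predict a per-metabolite binary label
#' (e.g. "differs between groups") from one-hot encoded super- and
#' sub-pathway terms, then ranks the terms by permutation feature importance:
#' the mean drop in prediction accuracy over `nPermutations` shuffles of each
#' term's column.
#'
#' @param labels per-metabolite binary labels (logical or two-level factor),
#'   named by metabolite id or aligned with `annotations` rows.
#' @param annotations data.frame with `super_pathway` and `sub_pathway`.
#' @param nTrees trees (default 500).
#' @param nPermutations shuffles per term (default 50).
#' @param seed integer seed.
#' @return list with `importance` (data.frame of term, importance, ranked
#'   descending) and `confusion` (in-bag confusion matrix of the fitted
#'   model).
#' @export
pathwayTermImportance <- function(labels, annotations, nTrees = 500,
                                  nPermutations = 50, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")
  terms <- c(paste0("sp:", annotations$super_pathway),
             paste0("sub:", annotations$sub_pathway))
  dim(terms) <- c(nrow(annotations), 2)
  allTerms <- unique(c(terms))
  Xoh <- vapply(allTerms,
                function(tm) as.numeric(terms[, 1] == tm | terms[, 2] == tm),
                numeric(nrow(annotations)))
  empty <- colSums(Xoh) == 0
  if (any(empty)) {
    warning("dropping term(s) with zero members: ",
            paste(allTerms[empty], collapse = ", "))
    Xoh <- Xoh[, !empty, drop = FALSE]
  }
  set.seed(as.integer(seed))
  fit <- .rangerFit(Xoh, y, nTrees)
  base <- stats::predict(fit, data.frame(Xoh,
                                         check.names = FALSE))$predictions
  baseAcc <- mean(base == y)
  imp <- vapply(colnames(Xoh), function(tm) {
    drops <- vapply(seq_len(nPermutations), function(i) {
      Xp <- Xoh
      Xp[, tm] <- sample(Xp[, tm])
      pr <- stats::predict(fit, data.frame(Xp,
                                           check.names = FALSE))$predictions
      baseAcc - mean(pr == y)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  ord <- order(imp, decreasing = TRUE)
  list(importance = data.frame(term = colnames(Xoh)[ord],
                               importance = unname(imp[ord]),
                               stringsAsFactors = FALSE),
       confusion = table(truth = y, predicted = base))
}

#' Select metabolites by Boruta-confirmed random-forest importance
#'
#' Convenience wrapper running [borutaSelect()] on a preprocessed table for
#' a two-group contrast; the selection set is the "confirmed" features only
#' (tentative features are excluded).
#'
#' @inheritParams plsdaSelect
#' @param nTrees,maxIter,alpha,seed passed to [borutaSelect()].
#' @return list with `selected` ids and the full boruta `result`.
#' @export
rfSelect <- function(x, groupA = "HC", groupB = "cART", nTrees = 500,
                     maxIter = 100, alpha = 0.01, seed = 1) {
  g <- sampleGroups(x)
  keep <- g %in% c(groupA, groupB)
  X <- t(abundanceMatrix(x)[, keep, drop = FALSE])
  y <- factor(g[keep], levels = c(groupA, groupB))
  res <- borutaSelect(X, y, nTrees = nTrees, maxIter = maxIter,
                      alpha = alpha, seed = seed)
  list(selected = res$confirmed, result = res)
}
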