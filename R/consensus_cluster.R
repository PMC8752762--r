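#' Monti-style resampled consensus clustering
#'
#' Repeatedly subsamples `floor(pItem * n)` samples without replacement,
#' clusters them by agglomerative hierarchical clustering on the
#' `1 - Spearman` correlation distance between sample profiles over the
#' chosen feature set, cuts at `k`, and tallies how often each sample pair
#' co-clusters among the repetitions drawing both. Final labels come from
#' reclustering `1 - M` with the same linkage. Deterministic under the seed.
#'
#' Sample pairs never drawn together (possible at low `reps`) are reported
#' as `NA` in `M`; the final clustering requires a complete `M` and errors
#' with advice to raise `reps` otherwise. At `pItem = 1` every repetition is
#' identical and `M` is exactly binary.
#'
#' @param x a preprocessed (log- and z-transformed)
#'   [MetaboliteExperiment-class], or a features x samples numeric matrix.
#' @param featureIds metabolite ids to cluster on (>= 2); all must exist.
#' @param k cluster count (default 2: the case/control question); must not
#'   exceed the per-repetition sample draw.
#' @param reps subsampling repetitions (default 1000).
#' @param pItem sample subsampling fraction in (0, 1] (default 0.8).
#' @param linkage hierarchical linkage (default "average").
#' @param seed integer seed.
#' @param groupLabels optional known labels; when given, the adjusted Rand
#'   index of the final labels against them fills the `separation` slot.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(x, featureIds = NULL, k = 2, reps = 1000,
                             pItem = 0.8, linkage = "average", seed = 1,
                             groupLabels = NULL) {
  X <- if (is(x, "MetaboliteExperiment")) abundanceMatrix(x) else as.matrix(x)
  if (!is.null(featureIds)) {
    miss <- setdiff(featureIds, rownames(X))
    if (length(miss))
      stop("feature id(s) missing: ", paste(miss, collapse = ", "))
    X <- X[featureIds, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("need >= 2 features")
  n <- ncol(X)
  stopifnot(pItem > 0, pItem <= 1)
  nDraw <- floor(pItem * n)
  if (k > nDraw) stop("k exceeds the per-repetition sample draw")
  set.seed(as.integer(seed))
  coCluster <- matrix(0L, n, n, dimnames = list(colnames(X), colnames(X)))
  coSampled <- coCluster
  for (r in seq_len(reps)) {
    idx <- if (nDraw == n) seq_len(n) else sort(sample(n, nDraw))
    D <- 1 - stats::cor(X[, idx, drop = FALSE], method = "spearman")
    lab <- stats::cutree(stats::hclust(stats::as.dist(D), method = linkage),
                         k = k)
    coSampled[idx, idx] <- coSampled[idx, idx] + 1L
    same <- outer(lab, lab, "==")
    coCluster[idx, idx] <- coCluster[idx, idx] + same
  }
  M <- ifelse(coSampled > 0, coCluster / coSampled, NA)
  diag(M)[diag(coSampled) > 0] <- 1
  if (anyNA(M))
    stop("some sample pairs were never co-sampled; increase reps ",
         "(or pItem) for a complete consensus matrix")
  finalLabels <- stats::cutree(
    stats::hclust(stats::as.dist(1 - M), method = linkage), k = k)
  sep <- if (is.null(groupLabels)) NA_real_
         else separationScore(finalLabels, groupLabels)
  new("ConsensusResult", M = M, coCluster = coCluster, coSampled = coSampled,
      k = as.integer(k), finalLabels = finalLabels, separation = sep)
}

#' Adjusted Rand index between a clustering and known groups
#'
#' Chance-corrected agreement in [-1, 1]; 1 exactly when the partitions are
#' identical up to relabeling, about 0 for unrelated partitions.
#'
#' @param finalLabels,groupLabels equal-length label vectors (>= 2 samples).
#' @return numeric ARI.
#' @export
separationScore <- function(finalLabels, groupLabels) {
  if (length(finalLabels) != length(groupLabels))
    stop("label vectors must have equal length")
  if (length(finalLabels) < 2) stop("need >= 2 samples")
  mclust::adjustedRandIndex(finalLabels, groupLabels)
}
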