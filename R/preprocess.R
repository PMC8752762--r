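#' Preprocess a metabolite table
#'
#' Standard untargeted-metabolomics preprocessing: per-metabolite imputation
#' of left-censored missing values, log transform, and optional per-metabolite
#' z-scoring. The three steps are applied in that order. The imputed,
#' unlogged matrix is kept as assay `"imputed"` so that fold changes can be
#' computed on the measurement scale after scaling has destroyed it.
#'
#' Scaling is per metabolite across all samples of the table; tables are one
#' cohort each and are never pooled, so scaling never crosses a cohort
#' boundary.
#'
#' @param x a raw [MetaboliteExperiment-class].
#' @param logBase base of the log transform (default 2).
#' @param impute `"min"` (per-metabolite observed minimum, the default),
#'   `"halfmin"`, or `"none"`.
#' @param scale logical, z-score each metabolite after the log transform.
#' @return A MetaboliteExperiment with updated `abundance` assay, flags set,
#'   the `imputed` assay added, and the per-metabolite imputation count in
#'   `rowData(x)$n_imputed`.
#'
#' A second call on an already-logged table is refused (error): the flags
#' make preprocessing non-repeatable by construction.
#' @export
preprocess <- function(x, logBase = 2, impute = c("min", "halfmin", "none"),
                       scale = TRUE) {
  stopifnot(is(x, "MetaboliteExperiment"))
  impute <- match.arg(impute)
  if (isLogged(x) || isScaled(x))
    stop("table is already preprocessed (isLogged/isScaled set); refusing ",
         "to re-apply")
  a <- abundanceMatrix(x)
  allMissing <- rowSums(!is.na(a)) == 0
  if (any(allMissing))
    stop("metabolite(s) entirely missing: ",
         paste(rownames(a)[allMissing], collapse = ", "))
  nImputed <- rowSums(is.na(a))
  if (impute != "none") {
    mins <- apply(a, 1, min, na.rm = TRUE)
    fill <- if (impute == "min") mins else mins / 2
    idx <- which(is.na(a), arr.ind = TRUE)
    if (nrow(idx)) a[idx] <- fill[idx[, 1]]
  }
  imputed <- a
  if (any(a <= 0, na.rm = TRUE))
    stop("non-positive abundances cannot be log-transformed")
  lg <- log(a, base = logBase)
  if (scale) {
    mu <- rowMeans(lg, na.rm = TRUE)
    sd_ <- apply(lg, 1, stats::sd, na.rm = TRUE)
    flat <- which(sd_ == 0)
    if (length(flat)) {
      warning("zero-variance metabolite(s) scaled to all-zeros: ",
              paste(rownames(lg)[flat], collapse = ", "))
      sd_[flat] <- 1
    }
    lg <- (lg - mu) / sd_
  }
  assay(x, "abundance") <- lg
  assay(x, "imputed", withDimnames = TRUE) <- imputed
  rowData(x)$n_imputed <- nImputed
  x@isLogged <- TRUE
  x@isScaled <- scale
  validObject(x)
  x
}

#' Super-pathway composition of a metabolite set
#'
#' Counts and percentages of each annotation super-pathway within a
#' metabolite subset (or the whole table), the tabulation behind
#' composition bar plots such as "46% lipids, 22% amino acids, 17%
#' xenobiotics" over a detected-metabolite universe.
#'
#' @param x a [MetaboliteExperiment-class].
#' @param subset character vector of metabolite ids, or `"all"`.
#' @return data.frame with columns `super_pathway`, `count`, `percent`,
#'   ordered by decreasing count. Counts sum to the subset size, percents to
#'   100 (up to rounding noise). An empty subset gives an empty table.
#' @export
superpathwayProportions <- function(x, subset = "all") {
  ann <- annotations(x)
  ids <- if (identical(subset, "all")) ann$metabolite_id else subset
  if (length(ids) == 0)
    return(data.frame(super_pathway = character(), count = integer(),
                      percent = numeric()))
  missing <- setdiff(ids, ann$metabolite_id)
  if (length(missing))
    stop("subset ids not in table: ", paste(missing, collapse = ", "))
  sp <- ann$super_pathway[match(ids, ann$metabolite_id)]
  tab <- sort(table(sp), decreasing = TRUE)
  data.frame(super_pathway = names(tab),
             count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(ids),
             row.names = NULL)
}
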