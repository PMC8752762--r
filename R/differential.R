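#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of `x` versus `y`. The exact null distribution is
#' enumerated when `n1 * n2 <= 400` and the data carry no ties; otherwise the
#' normal approximation with tie and continuity correction is used. The
#' switch can be forced either way via `exact`.
#'
#' @param x,y numeric vectors, at least 2 non-missing values each.
#' @param exact logical or `NULL` (automatic switch as above).
#' @return list with `U` (the statistic for `x`, in `[0, n1 * n2]`) and `p`
#'   (two-sided). All values tied across both groups gives `p = 1` with a
#'   warning.
#' @export
mannWhitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 non-missing values")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied across both groups; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  if (is.null(exact)) exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in [0, 1]; `NA` allowed (propagated).
#' @return q-values in the input order; `q >= p` elementwise and monotone
#'   along the p-ranking. Empty input gives empty output.
#' @export
bhFdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Glass-delta effect size
#'
#' `D = (mean(xArt) - mean(xHc)) / sd(xHc)`: the group mean difference
#' standardized by the control group's sample (n-1) standard deviation,
#' appropriate when the groups' spreads differ. `|D|` is categorized as
#' negligible (< 0.2), small (< 0.5), medium (< 0.8) or large.
#'
#' @param xArt,xHc numeric vectors (treated, control); missing values
#'   dropped.
#' @return list with `D` and `category`.
#' @export
glassDelta <- function(xArt, xHc) {
  xArt <- xArt[!is.na(xArt)]; xHc <- xHc[!is.na(xHc)]
  sdHc <- stats::sd(xHc)
  if (is.na(sdHc) || sdHc == 0)
    stop("control group SD is zero; Glass delta undefined")
  D <- (mean(xArt) - mean(xHc)) / sdHc
  list(D = D, category = effectCategory(D))
}

#' @rdname glassDelta
#' @param D numeric Glass-delta value(s).
#' @export
effectCategory <- function(D) {
  cut(abs(D), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |>
    as.character()
}

#' Covariate-adjusted group test
#'
#' Ordinary least squares of a metabolite's values on the group indicator
#' plus covariates, with a two-sided t-test on the group coefficient — the
#' confounder-adjusted complement to the rank test (e.g. adjusting for
#' exercise imbalance between groups).
#'
#' @param values numeric response.
#' @param group two-level factor or character.
#' @param covariates data.frame of covariates (may be empty).
#' @return list with `beta` (group coefficient, second level vs first) and
#'   `p`. A rank-deficient design errors, naming the collinear columns.
#' @export
adjustedGroupTest <- function(values, group,
                              covariates = data.frame()[seq_along(values), ,
                                                        drop = FALSE]) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  df <- data.frame(.y = values, .g = group, covariates)
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("design matrix rank deficient; collinear column(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  s <- summary(fit)$coefficients
  term <- grep("^\\.g", rownames(s), value = TRUE)
  list(beta = unname(s[term, "Estimate"]), p = unname(s[term, "Pr(>|t|)"]))
}

#' Two-sample t-test from printed summaries
#'
#' Student (pooled-variance) t-test recovered from per-group mean and 95%
#' confidence interval, as printed in clinical characteristics tables. The
#' SD is reconstructed as `(CI half-width) * sqrt(n) / t_{0.975, n-1}`.
#'
#' @param mean1,mean2 group means.
#' @param ci1,ci2 length-2 95% CI bounds.
#' @param n1,n2 group sizes.
#' @return list with `t`, `df`, `p`.
#' @export
summaryTTest <- function(mean1, ci1, n1, mean2, ci2, n2) {
  sdFromCi <- function(ci, n) (ci[2] - ci[1]) / 2 * sqrt(n) /
    stats::qt(0.975, n - 1)
  s1 <- sdFromCi(ci1, n1); s2 <- sdFromCi(ci2, n2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Chi-square test on 2x2 counts
#'
#' Yates-corrected chi-square on a `k/n` vs `k/n` comparison (the correction
#' is floored at zero, never inverting the sign of a deviation). A warning is
#' attached when any expected cell is below 1.
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @return list with `statistic` and `p`.
#' @export
chiSquareCounts <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) warning("expected cell count below 1")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Group-comparison table for sample metadata
#'
#' Per-variable two-group comparison as in a clinical characteristics table:
#' continuous variables by Student t-test, two-level categorical or logical
#' variables by Yates-corrected chi-square on the 2x2 table.
#'
#' @param metadata data.frame with a `group` column and the variables to
#'   test.
#' @param groupA,groupB the two group labels to compare.
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
tableOne <- function(metadata, groupA = "HC", groupB = "cART") {
  keep <- metadata$group %in% c(groupA, groupB)
  metadata <- metadata[keep, , drop = FALSE]
  g <- factor(metadata$group, levels = c(groupA, groupB))
  vars <- setdiff(colnames(metadata), c("group", "sample_id", "cohort"))
  out <- lapply(vars, function(v) {
    x <- metadata[[v]]
    if (is.numeric(x)) {
      tt <- stats::t.test(x[g == groupA], x[g == groupB], var.equal = TRUE)
      data.frame(variable = v, test = "t",
                 statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      x <- factor(x)
      if (nlevels(x) != 2)
        return(data.frame(variable = v, test = "skipped",
                          statistic = NA_real_, p = NA_real_))
      cs <- chiSquareCounts(sum(x[g == groupA] == levels(x)[2]),
                            sum(g == groupA),
                            sum(x[g == groupB] == levels(x)[2]),
                            sum(g == groupB))
      data.frame(variable = v, test = "chisq",
                 statistic = cs$statistic, p = cs$p)
    }
  })
  do.call(rbind, out)
}

#' Per-metabolite differential abundance
#'
#' Mann-Whitney U test per metabolite between two groups, BH FDR across
#' metabolites, log2 fold change on the measurement scale, and the
#' Glass-delta effect size with the control group as the standardizer.
#'
#' Rank statistics and the effect size are computed on the working
#' (preprocessed) assay; per-metabolite z-scoring does not alter either
#' (ranks are scale-free and Glass delta is invariant under a common affine
#' map). The fold change uses the `imputed` assay (unlogged scale) when
#' present, otherwise the raw abundances with missing values dropped.
#'
#' @param x a [MetaboliteExperiment-class].
#' @param groupA control group label (default `"HC"`).
#' @param groupB treated group label (default `"cART"`); fold change and
#'   effect sign are `groupB` over/minus `groupA`.
#' @param exact passed to [mannWhitney()].
#' @return data.frame with one row per metabolite: `metabolite_id`, `U`,
#'   `p`, `q`, `log2fc`, `direction` (`up`/`down`), `D`, `category`.
#' @export
differentialAbundance <- function(x, groupA = "HC", groupB = "cART",
                                  exact = NULL) {
  g <- sampleGroups(x)
  ia <- which(g == groupA); ib <- which(g == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 samples in each group")
  work <- abundanceMatrix(x)
  raw <- if ("imputed" %in% assayNames(x)) abundanceMatrix(x, "imputed")
         else abundanceMatrix(x)
  res <- lapply(seq_len(nrow(work)), function(i) {
    xb <- work[i, ib]; xa <- work[i, ia]
    mw <- mannWhitney(xb, xa, exact = exact)
    gd <- tryCatch(glassDelta(xb, xa),
                   error = function(e) list(D = NA_real_,
                                            category = NA_character_))
    mb <- mean(raw[i, ib], na.rm = TRUE); ma <- mean(raw[i, ia], na.rm = TRUE)
    lfc <- log2(mb / ma)
    data.frame(metabolite_id = rownames(work)[i], U = mw$U, p = mw$p,
               log2fc = lfc, direction = ifelse(lfc >= 0, "up", "down"),
               D = gd$D, category = gd$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out[, c("metabolite_id", "U", "p", "q", "log2fc", "direction", "D",
          "category")]
}
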