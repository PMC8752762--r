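#' Cross-method, cross-cohort consensus panel
#'
#' For each selection method, intersects the selected metabolite sets across
#' cohorts; the consensus panel is the intersection of those per-method sets
#' over all methods. Deterministic and order-invariant in both cohorts and
#' methods; adding a method can only shrink (or preserve) the consensus.
#'
#' @param selections nested named list: `selections[[cohort]][[method]]` is a
#'   character vector of metabolite ids. At least two cohorts, every cohort
#'   carrying the same methods; a missing (cohort, method) cell is an error.
#' @return a [SelectionReport-class].
#' @export
intersectSelections <- function(selections) {
  if (length(selections) < 2) stop("need >= 2 cohorts")
  methods <- names(selections[[1]])
  if (is.null(methods) || !length(methods)) stop("need >= 1 named method")
  for (co in names(selections)) {
    miss <- setdiff(methods, names(selections[[co]]))
    extra <- setdiff(names(selections[[co]]), methods)
    if (length(miss) || length(extra))
      stop("cohort '", co, "' has mismatched method cells: ",
           paste(c(miss, extra), collapse = ", "))
  }
  perMethod <- lapply(methods, function(m) {
    Reduce(intersect, lapply(selections, `[[`, m))
  })
  names(perMethod) <- methods
  consensus <- Reduce(intersect, perMethod)
  new("SelectionReport", selections = selections, perMethod = perMethod,
      consensus = as.character(consensus), excludedDrugs = character(),
      concordance = logical())
}

#' Remove drug metabolites from a panel
#'
#' Drops panel members flagged as drugs: annotation `is_drug` is `TRUE`, the
#' sub-pathway string contains "Drug", or the id appears in an explicit
#' exclusion list (e.g. a named antiviral).
#'
#' @param panel character vector of metabolite ids, or a
#'   [SelectionReport-class] (whose consensus is filtered in place).
#' @param annotations data.frame with `metabolite_id`, `sub_pathway`,
#'   `is_drug`; must cover every panel id.
#' @param extraDrugIds additional ids to exclude.
#' @return For a character panel, list with `panel` (retained) and
#'   `excluded`; for a SelectionReport, the updated report.
#' @export
excludeDrugs <- function(panel, annotations, extraDrugIds = character()) {
  if (is(panel, "SelectionReport")) {
    res <- excludeDrugs(panel@consensus, annotations, extraDrugIds)
    panel@consensus <- res$panel
    panel@excludedDrugs <- res$excluded
    return(panel)
  }
  idx <- match(panel, annotations$metabolite_id)
  if (anyNA(idx))
    stop("panel ids without annotations: ",
         paste(panel[is.na(idx)], collapse = ", "))
  isDrug <- annotations$is_drug[idx] |
    grepl("Drug", annotations$sub_pathway[idx], fixed = TRUE) |
    panel %in% extraDrugIds
  if (all(isDrug) && length(panel))
    warning("all panel members are drugs; empty panel returned")
  list(panel = panel[!isDrug], excluded = panel[isDrug])
}

#' Cross-cohort direction concordance
#'
#' A panel metabolite is concordant when the sign of its fold change is
#' identical in every cohort — the sanity check that nominated biomarkers
#' move the same way in each replication cohort.
#'
#' @param panel character vector of metabolite ids, or a
#'   [SelectionReport-class].
#' @param diffResultsByCohort named list of [differentialAbundance()] result
#'   data.frames, one per cohort; each must contain every panel id.
#' @return For a character panel, list with `concordance` (named logical) and
#'   `fraction`; for a SelectionReport, the updated report.
#' @export
directionConcordance <- function(panel, diffResultsByCohort) {
  if (is(panel, "SelectionReport")) {
    res <- directionConcordance(panel@consensus, diffResultsByCohort)
    panel@concordance <- res$concordance
    return(panel)
  }
  signs <- vapply(names(diffResultsByCohort), function(co) {
    d <- diffResultsByCohort[[co]]
    idx <- match(panel, d$metabolite_id)
    if (anyNA(idx))
      stop("missing differential result for id(s) ",
           paste(panel[is.na(idx)], collapse = ", "), " in cohort '", co, "'")
    sign(d$log2fc[idx])
  }, numeric(length(panel)))
  if (length(panel) == 1) signs <- matrix(signs, nrow = 1)
  conc <- apply(signs, 1, function(s) length(unique(s)) == 1)
  names(conc) <- panel
  list(concordance = conc,
       fraction = if (length(conc)) mean(conc) else NA_real_)
}
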