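#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<- rowData<-
#' @importFrom stats setNames
NULL

.SUPERPATHWAY_VOCAB <- c(
  "Lipid", "Amino Acid", "Xenobiotics", "Nucleotide", "Energy",
  "Carbohydrate", "Cofactors and Vitamins", "Peptide",
  "Partially Characterized Molecules"
)

.GROUP_LEVELS <- c("HC", "cART", "naive")

#' Container for a metabolomics cohort
#'
#' `MetaboliteExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] for plasma metabolomics
#' abundance data. Metabolites are rows, samples are columns (on disk the
#' conventional layout is samples x metabolites; [readAbundance()]
#' transposes). Per-metabolite annotations (Metabolon-style super- and
#' sub-pathway, HMDB id, drug flag) live in `rowData`; per-sample metadata
#' (cohort, group, covariates) in `colData`. Two logical slots record whether
#' the abundance assay has been log-transformed and z-scaled, so that
#' [preprocess()] can refuse re-application.
#'
#' @slot isLogged logical(1), `TRUE` once abundances are on the log scale.
#' @slot isScaled logical(1), `TRUE` once abundances are z-scored per
#'   metabolite.
#'
#' @seealso [MetaboliteExperiment()] for construction, [readAbundance()],
#'   [preprocess()].
#' @export
setClass("MetaboliteExperiment",
  contains = "SummarizedExperiment",
  slots = c(isLogged = "logical", isScaled = "logical"),
  prototype = prototype(isLogged = FALSE, isScaled = FALSE)
)

setValidity("MetaboliteExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "metabolite and sample ids must be set as dimnames")
  rd <- rowData(object)
  need_rd <- c("super_pathway", "sub_pathway", "hmdb_id", "is_drug")
  miss <- setdiff(need_rd, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks annotation column(s): ",
                         paste(miss, collapse = ", ")))
  cd <- colData(object)
  need_cd <- c("cohort", "group")
  miss <- setdiff(need_cd, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("group" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$group)), .GROUP_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
    if (anyNA(cd$group))
      msg <- c(msg, "every sample needs a group label")
  }
  if (all(c("super_pathway", "is_drug") %in% colnames(rd))) {
    vocab <- metadata(object)$superpathway_vocab
    if (is.null(vocab)) vocab <- .SUPERPATHWAY_VOCAB
    bad <- setdiff(unique(as.character(rd$super_pathway)), vocab)
    if (length(bad))
      msg <- c(msg, paste0("super_pathway outside controlled vocabulary: ",
                           paste(bad, collapse = ", ")))
    off <- which(rd$is_drug & rd$super_pathway != "Xenobiotics")
    if (length(off))
      msg <- c(msg, paste0("is_drug implies super_pathway 'Xenobiotics'; ",
                           "violated by: ",
                           paste(rownames(object)[off], collapse = ", ")))
  }
  if ("abundance" %in% assayNames(object) && !isTRUE(object@isLogged)) {
    a <- assay(object, "abundance")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "raw abundances must be >= 0 or missing")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-method, cross-cohort selection report
#'
#' Holds the per-(cohort, method) selected metabolite sets, the per-method
#' cross-cohort intersections, and the final consensus panel, together with
#' the drug-exclusion and direction-concordance bookkeeping filled in by
#' [excludeDrugs()] and [directionConcordance()].
#'
#' @slot selections nested list, `selections[[cohort]][[method]]` is a
#'   character vector of metabolite ids.
#' @slot perMethod named list of per-method cross-cohort intersections.
#' @slot consensus character, the intersection over methods.
#' @slot excludedDrugs character, ids dropped as drugs.
#' @slot concordance named logical, cross-cohort direction agreement.
#' @export
setClass("SelectionReport",
  slots = c(selections = "list", perMethod = "list", consensus = "character",
            excludedDrugs = "character", concordance = "logical"))

#' Metabolite co-abundance network
#'
#' Undirected graph whose nodes are metabolites and whose edges are
#' significant positive Spearman correlations (rho > 0, BH q below the edge
#' FDR), with a Leiden community partition and per-community summaries.
#'
#' @slot graph the underlying [igraph::graph] object.
#' @slot edges data.frame with columns `from`, `to`, `rho`, `q`.
#' @slot partition named integer, community id per node (ids numbered by
#'   decreasing community size).
#' @slot communityStats data.frame of per-community size and mean full-graph
#'   degree.
#' @slot annotations data.frame of node annotations (super_pathway etc.).
#' @export
setClass("CoabundanceNetwork",
  slots = c(graph = "ANY", edges = "data.frame", partition = "integer",
            communityStats = "data.frame", annotations = "data.frame"))

#' Monti consensus clustering result
#'
#' @slot M numeric matrix of co-clustering proportions, samples x samples;
#'   `M[i, j]` is the fraction of subsampling repetitions in which samples i
#'   and j fell in the same cluster, among repetitions drawing both. Pairs
#'   never drawn together are `NA` (flagged, not silently zeroed).
#' @slot coCluster,coSampled integer matrices of the underlying tallies.
#' @slot k integer, cluster count.
#' @slot finalLabels named integer, consensus labels from reclustering
#'   `1 - M`.
#' @slot separation numeric, adjusted Rand index of `finalLabels` against
#'   known group labels (`NA` when no labels were supplied).
#' @export
setClass("ConsensusResult",
  slots = c(M = "matrix", coCluster = "matrix", coSampled = "matrix",
            k = "integer", finalLabels = "integer", separation = "numeric"))
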