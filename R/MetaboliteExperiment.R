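#' Construct a MetaboliteExperiment
#'
#' @param abundance numeric matrix, metabolites x samples (the
#'   SummarizedExperiment convention; note that delimited files use
#'   samples x metabolites and are transposed by [readAbundance()]).
#'   Raw values must be non-negative or `NA`.
#' @param annotations data.frame or DataFrame keyed by `metabolite_id`, with
#'   columns `super_pathway`, `sub_pathway`, `hmdb_id`, `is_drug`. Missing
#'   optional columns are filled with empty values.
#' @param metadata data.frame or DataFrame keyed by `sample_id`, with columns
#'   `cohort` and `group` (one of `"HC"`, `"cART"`, `"naive"`) plus any
#'   covariates.
#' @param isLogged,isScaled logical flags describing the state of
#'   `abundance`.
#' @param superpathwayVocab character, the controlled vocabulary for
#'   `super_pathway`; defaults to the Metabolon-style nine super-pathways.
#'
#' @return A [MetaboliteExperiment-class] object.
#' @export
MetaboliteExperiment <- function(abundance, annotations, metadata,
                                 isLogged = FALSE, isScaled = FALSE,
                                 superpathwayVocab = .SUPERPATHWAY_VOCAB) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs metabolite rownames and sample colnames")
  annotations <- .completeAnnotations(as.data.frame(annotations),
                                      rownames(abundance))
  metadata <- as.data.frame(metadata)
  key <- if ("sample_id" %in% colnames(metadata)) metadata$sample_id
         else rownames(metadata)
  if (anyDuplicated(key)) stop("duplicate sample ids in metadata")
  idx <- match(colnames(abundance), key)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(abundance)[is.na(idx)], collapse = ", "))
  metadata <- metadata[idx, setdiff(colnames(metadata), "sample_id"),
                       drop = FALSE]
  rownames(metadata) <- colnames(abundance)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(annotations),
    colData = DataFrame(metadata))
  out <- new("MetaboliteExperiment", se,
             isLogged = isLogged, isScaled = isScaled)
  metadata(out)$superpathway_vocab <- superpathwayVocab
  validObject(out)
  out
}

.completeAnnotations <- function(ann, ids) {
  if (!"metabolite_id" %in% colnames(ann)) {
    if (is.null(rownames(ann))) stop("annotations need a metabolite_id key")
    ann$metabolite_id <- rownames(ann)
  }
  if (anyDuplicated(ann$metabolite_id))
    stop("duplicate metabolite ids in annotations")
  idx <- match(ids, ann$metabolite_id)
  if (anyNA(idx))
    stop("metabolites without annotation record: ",
         paste(ids[is.na(idx)], collapse = ", "))
  ann <- ann[idx, , drop = FALSE]
  if (!"sub_pathway" %in% colnames(ann)) ann$sub_pathway <- ""
  if (!"hmdb_id" %in% colnames(ann)) ann$hmdb_id <- NA_character_
  ann$hmdb_id <- as.character(ann$hmdb_id)
  if (!"is_drug" %in% colnames(ann)) ann$is_drug <- FALSE
  ann$is_drug <- as.logical(ann$is_drug)
  rownames(ann) <- ann$metabolite_id
  ann[, c("metabolite_id", "super_pathway", "sub_pathway", "hmdb_id",
          "is_drug",
          setdiff(colnames(ann), c("metabolite_id", "super_pathway",
                                   "sub_pathway", "hmdb_id", "is_drug")))]
}

#' Accessors for MetaboliteExperiment
#'
#' `abundanceMatrix` returns an assay (metabolites x samples);
#' `annotations` the per-metabolite annotation table; `sampleGroups` and
#' `sampleCohorts` the per-sample labels; `metaboliteIds` / `sampleIds` the
#' dimension names; `isLogged` / `isScaled` the preprocessing flags.
#'
#' @param x a [MetaboliteExperiment-class].
#' @param which assay name, `"abundance"` (the working assay) or
#'   `"imputed"` (imputed, unlogged scale; present after [preprocess()]).
#' @return See descriptions.
#' @name accessors
#' @export
abundanceMatrix <- function(x, which = "abundance") assay(x, which)

#' @rdname accessors
#' @export
annotations <- function(x) as.data.frame(rowData(x))

#' @rdname accessors
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group),
                                     colnames(x))

#' @rdname accessors
#' @export
sampleCohorts <- function(x) setNames(as.character(colData(x)$cohort),
                                      colnames(x))

#' @rdname accessors
#' @export
metaboliteIds <- function(x) rownames(x)

#' @rdname accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname accessors
#' @export
isLogged <- function(x) x@isLogged

#' @rdname accessors
#' @export
isScaled <- function(x) x@isScaled

setMethod("show", "MetaboliteExperiment", function(object) {
  cat("MetaboliteExperiment:", nrow(object), "metabolites x",
      ncol(object), "samples\n")
  cat("  groups:",
      paste(sprintf("%s=%d", names(table(sampleGroups(object))),
                    table(sampleGroups(object))), collapse = " "), "\n")
  cat("  cohorts:", paste(unique(sampleCohorts(object)), collapse = ", "),
      "\n")
  cat("  logged:", object@isLogged, " scaled:", object@isScaled, "\n")
  invisible(NULL)
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport\n")
  for (m in names(object@perMethod))
    cat(sprintf("  %s (cross-cohort): %d\n", m, length(object@perMethod[[m]])))
  cat("  consensus panel:", length(object@consensus),
      ifelse(length(object@consensus),
             paste0("[", paste(object@consensus, collapse = ", "), "]"), ""),
      "\n")
  if (length(object@excludedDrugs))
    cat("  excluded drugs:", paste(object@excludedDrugs, collapse = ", "),
        "\n")
  if (length(object@concordance))
    cat("  direction concordance:",
        sum(object@concordance), "/", length(object@concordance), "\n")
  invisible(NULL)
})

setMethod("show", "CoabundanceNetwork", function(object) {
  cat("CoabundanceNetwork:", length(object@partition), "nodes,",
      nrow(object@edges), "edges,",
      length(unique(object@partition)), "communities\n")
  invisible(NULL)
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: k =", object@k, ",", nrow(object@M), "samples")
  if (!is.na(object@separation))
    cat(", ARI vs groups =", round(object@separation, 3))
  cat("\n")
  invisible(NULL)
})
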