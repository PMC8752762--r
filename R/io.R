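.readDelim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Read a cohort from delimited files
#'
#' Reads the three standard files of a cohort: the abundance matrix
#' (samples as rows, metabolites as columns, first column the sample id),
#' the metabolite annotation table (keyed by `metabolite_id`) and the
#' sample metadata table (keyed by `sample_id`). Comma vs tab dialect is
#' chosen from the file extension (`.csv` vs anything else).
#'
#' @param pathAbundance,pathAnnotations,pathMetadata file paths.
#' @return A validated [MetaboliteExperiment-class]. Column (metabolite)
#'   order of the abundance file is preserved.
#' @seealso [writeAbundance()] for the inverse; the round trip is lossless.
#' @export
readAbundance <- function(pathAbundance, pathAnnotations, pathMetadata) {
  ab <- .readDelim(pathAbundance)
  sample_ids <- as.character(ab[[1]])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", pathAbundance, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ab <- ab[, -1, drop = FALSE]
  if (anyDuplicated(colnames(ab)))
    stop("duplicate metabolite ids in ", pathAbundance)
  for (j in seq_along(ab)) {
    col <- ab[[j]]
    if (is.character(col)) {
      suppress <- suppressWarnings(as.numeric(ifelse(col %in% c("", "NA"),
                                                     NA, col)))
      bad <- which(!is.na(col) & !(col %in% c("", "NA")) & is.na(suppress))
      if (length(bad))
        stop("non-numeric abundance cell at row ", bad[1], ", column '",
             colnames(ab)[j], "'")
      ab[[j]] <- suppress
    }
  }
  m <- t(as.matrix(ab))
  colnames(m) <- sample_ids
  ann <- .readDelim(pathAnnotations)
  meta <- .readDelim(pathMetadata)
  extra <- setdiff(ann$metabolite_id, rownames(m))
  if (length(extra))
    message("annotation records without abundance column: ",
            paste(extra, collapse = ", "))
  MetaboliteExperiment(m, ann, meta)
}

#' Write a cohort to delimited files
#'
#' Writes the abundance matrix (samples x metabolites), annotations and
#' metadata of a [MetaboliteExperiment-class] as three delimited files, the
#' exact inverse of [readAbundance()].
#'
#' @param x a MetaboliteExperiment.
#' @param pathAbundance,pathAnnotations,pathMetadata output paths; dialect
#'   follows the extension as in [readAbundance()].
#' @return Invisibly, the three paths.
#' @export
writeAbundance <- function(x, pathAbundance, pathAnnotations, pathMetadata) {
  .writeDelim <- function(df, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  ab <- as.data.frame(t(abundanceMatrix(x)))
  ab <- cbind(sample_id = rownames(ab), ab)
  .writeDelim(ab, pathAbundance)
  .writeDelim(annotations(x), pathAnnotations)
  meta <- as.data.frame(colData(x))
  meta <- cbind(sample_id = rownames(meta), meta)
  .writeDelim(meta, pathMetadata)
  invisible(c(pathAbundance, pathAnnotations, pathMetadata))
}
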