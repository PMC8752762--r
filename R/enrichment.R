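#' Pathway-term over-representation
#'
#' One-sided hypergeometric (upper-tail) test per annotation term: is the
#' term over-represented in the selection relative to the detected-metabolite
#' universe? BH adjustment across terms. This answers the testable core of a
#' metabolite set enrichment analysis — whether particular super- or
#' sub-pathways dominate a selection — without any proprietary scoring.
#'
#' @param selection character vector of selected metabolite ids (non-empty,
#'   a subset of the universe).
#' @param universeAnnotations data.frame with `metabolite_id` and the term
#'   columns (the full detected universe).
#' @param termLevel `"super_pathway"` or `"sub_pathway"`.
#' @return data.frame with one row per term: `term`, `n_term_in_universe`,
#'   `n_term_in_selection`, `selection_size`, `universe_size`, `p`, `q`,
#'   ordered by `p`.
#' @export
enrichTerms <- function(selection, universeAnnotations,
                        termLevel = c("super_pathway", "sub_pathway")) {
  termLevel <- match.arg(termLevel)
  if (!length(selection)) stop("empty selection")
  uniIds <- universeAnnotations$metabolite_id
  out_ <- setdiff(selection, uniIds)
  if (length(out_))
    stop("selection ids outside universe: ", paste(out_, collapse = ", "))
  terms <- as.character(universeAnnotations[[termLevel]])
  N <- length(uniIds)
  n <- length(selection)
  selTerms <- terms[match(selection, uniIds)]
  res <- lapply(unique(terms), function(tm) {
    K <- sum(terms == tm)
    kk <- sum(selTerms == tm)
    p <- stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_term_in_universe = K, n_term_in_selection = kk,
               selection_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out[order(out$p), ]
}
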