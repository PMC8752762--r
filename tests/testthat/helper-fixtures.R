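suppressPackageStartupMessages(library(SummarizedExperiment))

# In-code fixtures shared across test files.

# tiny 4-sample x 3-metabolite cohort (metabolites rows internally)
makeToyTable <- function(abundance = NULL, isDrug = c(FALSE, FALSE, FALSE)) {
  if (is.null(abundance))
    abundance <- matrix(c(1, 2, 4, 8,
                          3, 3, 3, 3,
                          10, 20, 40, 5),
                        nrow = 3, byrow = TRUE)
  dimnames(abundance) <- list(paste0("M", seq_len(nrow(abundance))),
                              paste0("S", seq_len(ncol(abundance))))
  ann <- data.frame(
    metabolite_id = rownames(abundance),
    super_pathway = rep_len(c("Lipid", "Amino Acid", "Xenobiotics"),
                            nrow(abundance)),
    sub_pathway = rep_len(c("Sphingolipid Metabolism",
                            "Glutamate Metabolism",
                            "Drug - Antiviral"), nrow(abundance)),
    hmdb_id = NA_character_,
    is_drug = rep_len(isDrug, nrow(abundance)))
  meta <- data.frame(
    sample_id = colnames(abundance),
    cohort = "toy",
    group = rep_len(c("HC", "HC", "cART", "cART"), ncol(abundance)),
    exercise = rep_len(c(FALSE, TRUE), ncol(abundance)))
  MetaboliteExperiment(abundance, ann, meta)
}

# exhaustive Mann-Whitney oracle: enumerate all group assignments of the
# pooled sample and compute the exact two-sided p for the observed U
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- uStat(x, y)
  us <- apply(idx, 2, function(i) uStat(pooled[i], pooled[-i]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# step-up BH oracle applied literally: q_(i) = min_{j >= i} m * p_(j) / j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  q[o] <- qs
  q
}

# quick two-cohort synthetic pair at desk scale
smallSpec <- function(...) {
  syntheticSpec(nMetabolites = 150, blockSizes = c(40, 30, 30, 25, 15, 10),
                ...)
}
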