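#' Specification of a synthetic paired-cohort study
#'
#' Describes the generative model for synthetic metabolomics cohorts that
#' mirror a two-cohort case-control design: per cohort, `nHc + nArt` samples
#' over `nMetabolites` metabolites partitioned into Metabolon-style
#' super-pathways, with block-correlated metabolite groups (the future
#' network communities), a small planted biomarker set whose identities and
#' effect directions are shared across cohorts, a per-cohort batch shift,
#' and left-censored missingness.
#'
#' Latent values are drawn on the log2 scale with unit within-group standard
#' deviation, so planted `effectSizes` are directly on the Glass-delta scale
#' of the log-transformed data. Block correlation uses a common-factor
#' construction, `z = sqrt(rho) * f_block + sqrt(1 - rho) * eps`, which is
#' positive-definite for any `rhoWithin` in [0, 1).
#'
#' Defaults emulate a 24 + 24 per-cohort design over 841 metabolites with a
#' 46/22/17 percent lipid / amino acid / xenobiotics mix, six correlation
#' blocks sized like the observed co-abundance communities, and five planted
#' biomarkers (four down-regulated, planted in the fourth,
#' neurosteroid-like block; one up-regulated in the sixth, glutamate-like
#' block) with |effect| between 2.5 and 3 — the scale implied by panel
#' biomarkers significant at FDR < 0.001 in every cohort.
#'
#' @param nHc,nArt samples per group per cohort.
#' @param nCohorts number of cohorts (default 2).
#' @param nMetabolites metabolites per cohort.
#' @param superpathwayMix named proportions over super-pathways (must sum
#'   to 1).
#' @param blockSizes integer sizes of the correlation blocks;
#'   `sum(blockSizes) <= nMetabolites`.
#' @param rhoWithin common within-block correlation, in [0, 1).
#' @param effectSizes per-biomarker effects on the log2 scale in within-group
#'   SD units; the sign is the direction (cART minus HC). Identities and
#'   signs are identical across cohorts.
#' @param cohortShiftSd SD of the per-(cohort, metabolite) location shift —
#'   the batch structure that forces per-cohort analysis.
#' @param missingRate left-censoring fraction in [0, 1):
#'   `floor(missingRate * n)` lowest values per metabolite are censored.
#' @param baselineLog mean log2 baseline abundance.
#' @param drugBiomarker if `TRUE`, add one extra strongly up-regulated
#'   xenobiotic drug (an antiviral-like compound present only under
#'   treatment) to exercise drug exclusion.
#' @param seed integer seed; the spec plus seed fully determines the draw.
#' @return A list of class `SyntheticSpec`.
#' @seealso [generateCohorts()], [cameroonLikeSpec()]
#' @export
syntheticSpec <- function(nHc = 24, nArt = 24, nCohorts = 2,
                          nMetabolites = 841,
                          superpathwayMix = c(
                            "Lipid" = 0.46, "Amino Acid" = 0.22,
                            "Xenobiotics" = 0.17, "Nucleotide" = 0.05,
                            "Carbohydrate" = 0.04,
                            "Cofactors and Vitamins" = 0.03,
                            "Peptide" = 0.02, "Energy" = 0.01),
                          blockSizes = c(165, 145, 143, 123, 110, 91),
                          rhoWithin = 0.5,
                          effectSizes = c(-3.0, -2.8, -2.5, -2.5, 2.5),
                          cohortShiftSd = 1, missingRate = 0.1,
                          baselineLog = 10, drugBiomarker = FALSE,
                          seed = 1L) {
  spec <- list(nHc = nHc, nArt = nArt, nCohorts = nCohorts,
               nMetabolites = nMetabolites,
               superpathwayMix = superpathwayMix, blockSizes = blockSizes,
               rhoWithin = rhoWithin, effectSizes = effectSizes,
               cohortShiftSd = cohortShiftSd, missingRate = missingRate,
               baselineLog = baselineLog, drugBiomarker = drugBiomarker,
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  .validateSpec(spec)
  spec
}

.validateSpec <- function(spec) {
  if (spec$rhoWithin >= 1 || spec$rhoWithin < 0)
    stop("rhoWithin must be in [0, 1): block covariance infeasible")
  if (sum(spec$blockSizes) > spec$nMetabolites)
    stop("sum(blockSizes) exceeds nMetabolites")
  if (length(spec$effectSizes) > spec$nMetabolites)
    stop("more biomarkers than metabolites")
  if (spec$missingRate < 0 || spec$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (abs(sum(spec$superpathwayMix) - 1) > 1e-6)
    stop("superpathwayMix must sum to 1")
  invisible(TRUE)
}

#' Preset emulating the discovery cohort design
#'
#' 24 + 24 samples, 841 metabolites, 46/22/17 percent
#' lipid / amino acid / xenobiotics composition.
#'
#' @param ... overrides passed to [syntheticSpec()].
#' @return A `SyntheticSpec`.
#' @export
cameroonLikeSpec <- function(...) syntheticSpec(...)

.superpathwayCounts <- function(mix, m) {
  raw <- mix * m
  counts <- floor(raw)
  rem <- m - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Generate synthetic paired cohorts with ground truth
#'
#' Draws the cohorts described by a [syntheticSpec()]: per cohort,
#' block-correlated latent log2 values, planted group effects on the
#' biomarkers (cART samples shifted by `effect x within-group SD`), a
#' per-(cohort, metabolite) batch shift, exponentiation to the abundance
#' scale, and left-censoring of the lowest `missingRate` fraction of each
#' metabolite. Bit-identical output for identical spec and seed.
#'
#' @param spec a `SyntheticSpec`.
#' @param seed overrides `spec$seed` when given.
#' @return list with elements `cohorts` (named list of raw
#'   [MetaboliteExperiment-class], one per cohort) and `truth` (list:
#'   `biomarkers` data.frame of id + effect, `blocks` named integer with 0
#'   for unblocked metabolites, `cohortShifts` matrix, `spec`).
#' @export
generateCohorts <- function(spec, seed = spec$seed) {
  .validateSpec(spec)
  set.seed(as.integer(seed))
  m <- spec$nMetabolites
  n <- spec$nHc + spec$nArt
  ids <- sprintf("M%04d", seq_len(m))

  counts <- .superpathwayCounts(spec$superpathwayMix, m)
  sp <- rep(names(spec$superpathwayMix), counts)
  sub <- paste(sp, "metabolism", rep_len(c("A", "B"), m))
  isDrug <- rep(FALSE, m)

  blocks <- integer(m)
  pos <- 0
  for (b in seq_along(spec$blockSizes)) {
    blocks[pos + seq_len(spec$blockSizes[b])] <- b
    pos <- pos + spec$blockSizes[b]
  }
  names(blocks) <- ids

  effects <- spec$effectSizes
  nb <- length(spec$blockSizes)
  downBlock <- if (nb >= 4) 4L else max(nb, 1L)
  upBlock <- if (nb >= 6) 6L else max(nb, 1L)
  biomarkerIdx <- integer(0)
  downIdx <- which(blocks == downBlock)
  upIdx <- which(blocks == upBlock)
  freeIdx <- seq_len(m)
  for (e in effects) {
    pool <- if (e < 0) downIdx else upIdx
    pool <- setdiff(pool, biomarkerIdx)
    if (!length(pool)) pool <- setdiff(freeIdx, biomarkerIdx)
    biomarkerIdx <- c(biomarkerIdx, pool[1])
  }
  if (isTRUE(spec$drugBiomarker)) {
    xeno <- setdiff(which(sp == "Xenobiotics" & blocks == 0), biomarkerIdx)
    if (!length(xeno)) xeno <- setdiff(which(sp == "Xenobiotics"),
                                       biomarkerIdx)
    if (!length(xeno)) xeno <- setdiff(seq_len(m), biomarkerIdx)
    drugIdx <- xeno[1]
    biomarkerIdx <- c(biomarkerIdx, drugIdx)
    effects <- c(effects, 3.0)
    sp[drugIdx] <- "Xenobiotics"
    sub[drugIdx] <- "Drug - Antiviral"
    isDrug[drugIdx] <- TRUE
  }

  ann <- data.frame(metabolite_id = ids, super_pathway = sp,
                    sub_pathway = sub,
                    hmdb_id = sprintf("HMDB%07d", seq_len(m)),
                    is_drug = isDrug, stringsAsFactors = FALSE)

  mu <- stats::rnorm(m, spec$baselineLog, 1)
  group <- c(rep("HC", spec$nHc), rep("cART", spec$nArt))
  rho <- spec$rhoWithin

  cohorts <- vector("list", spec$nCohorts)
  names(cohorts) <- paste0("cohort", seq_len(spec$nCohorts))
  shifts <- matrix(0, m, spec$nCohorts,
                   dimnames = list(ids, names(cohorts)))
  for (cc in seq_len(spec$nCohorts)) {
    eps <- matrix(stats::rnorm(m * n), m, n)
    z <- eps
    if (nb > 0 && rho > 0) {
      f <- matrix(stats::rnorm(nb * n), nb, n)
      inBlock <- blocks > 0
      z[inBlock, ] <- sqrt(rho) * f[blocks[inBlock], , drop = FALSE] +
        sqrt(1 - rho) * eps[inBlock, , drop = FALSE]
    }
    z[biomarkerIdx, group == "cART"] <-
      z[biomarkerIdx, group == "cART"] + effects
    shift <- stats::rnorm(m, 0, spec$cohortShiftSd)
    shifts[, cc] <- shift
    logAb <- mu + z + shift
    ab <- 2^logAb
    sampleIds <- sprintf("C%dS%02d", cc, seq_len(n))
    dimnames(ab) <- list(ids, sampleIds)
    exercise <- stats::rbinom(n, 1, ifelse(group == "HC", 0.17, 0.58)) == 1
    meta <- data.frame(sample_id = sampleIds,
                       cohort = names(cohorts)[cc], group = group,
                       exercise = exercise, stringsAsFactors = FALSE)
    me <- MetaboliteExperiment(ab, ann, meta)
    if (spec$missingRate > 0) me <- censorProfile(me, spec$missingRate)
    cohorts[[cc]] <- me
  }
  truth <- list(
    biomarkers = data.frame(metabolite_id = ids[biomarkerIdx],
                            effect = effects, stringsAsFactors = FALSE),
    blocks = blocks, cohortShifts = shifts, spec = spec)
  list(cohorts = cohorts, truth = truth)
}

#' Left-censor the lowest values of each metabolite
#'
#' Emulates limit-of-detection missingness: for each metabolite, exactly
#' `floor(missingRate * n_samples)` lowest abundances are set to missing.
#'
#' @param x a raw [MetaboliteExperiment-class].
#' @param missingRate fraction in [0, 1).
#' @return The table with values censored to `NA`.
#' @export
censorProfile <- function(x, missingRate) {
  stopifnot(missingRate >= 0, missingRate < 1)
  if (missingRate == 0) return(x)
  a <- abundanceMatrix(x)
  kk <- floor(missingRate * ncol(a))
  if (kk > 0) {
    for (i in seq_len(nrow(a))) {
      ord <- order(a[i, ], na.last = NA)
      a[i, ord[seq_len(min(kk, length(ord)))]] <- NA
    }
    assay(x, "abundance") <- a
  }
  x
}
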