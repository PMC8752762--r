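#' Pipeline run configuration
#'
#' Bundles every threshold and setting of the full analysis with its default:
#' differential FDR 0.1, edge FDR 0.05, VIP > 1, Boruta alpha 0.01, 500-tree
#' balanced forests with 10-fold cross-validation, and consensus clustering
#' at k = 2 with 1000 repetitions at 80% sample subsampling. Every stochastic
#' stage derives its own seed from the base `seed` so a run is reproducible
#' end to end; the seeds actually used are recorded in the run summary.
#'
#' @param fdrDiff FDR threshold for the differential (Mann-Whitney) stage.
#' @param fdrEdges FDR threshold for network edges.
#' @param vipThreshold PLS-DA VIP selection cutoff.
#' @param borutaAlpha Boruta binomial-test level.
#' @param nTrees random-forest trees.
#' @param kFolds cross-validation folds.
#' @param nComp PLS-DA components.
#' @param k,reps,pItem,linkage consensus clustering settings.
#' @param leidenResolution Leiden resolution.
#' @param groupA,groupB the contrasted groups (control first).
#' @param extraDrugIds explicit drug exclusion list.
#' @param refCohort index or name of the cohort used for network discovery.
#' @param stages which stages to run, a subset of
#'   `c("diff", "select", "consensus", "network", "cluster", "enrich")`.
#' @param seed base integer seed.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(fdrDiff = 0.1, fdrEdges = 0.05, vipThreshold = 1,
                      borutaAlpha = 0.01, nTrees = 500, kFolds = 10,
                      nComp = 2, k = 2, reps = 1000, pItem = 0.8,
                      linkage = "average", leidenResolution = 1,
                      groupA = "HC", groupB = "cART",
                      extraDrugIds = character(), refCohort = 1,
                      stages = c("diff", "select", "consensus", "network",
                                 "cluster", "enrich"),
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys error; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

.stageSeed <- function(cfg, stage, offset = 0L) {
  offsets <- c(diff = 101L, select = 211L, network = 307L, cluster = 401L,
               enrich = 503L)
  (as.integer(cfg$seed) + offsets[[stage]] + as.integer(offset)) %% 2147483647L
}

#' Run the full trans-cohort analysis
#'
#' Orchestrates preprocess -> differential -> per-method selection ->
#' cross-cohort consensus (with drug exclusion and direction concordance) ->
#' co-abundance network and communities -> biomarker + first-neighbor
#' consensus clustering -> term enrichment, on two or more cohorts analyzed
#' separately (never pooled). Any stage failure aborts with the stage name.
#'
#' @param cohorts named list of [MetaboliteExperiment-class] (raw tables are
#'   preprocessed with defaults first), or a `SyntheticSpec` (cohorts are
#'   generated from it).
#' @param config a [runConfig()] list.
#' @param outDir optional directory; when given, per-cohort differential
#'   TSVs, selection TSVs, the panel TSV, the GraphML network, the consensus
#'   matrix CSV and the JSON run summary are written there.
#' @return the run summary: a nested list with per-stage counts, panel ids,
#'   concordance, community structure, per-cohort ARI, enrichment, thresholds
#'   and seeds.
#' @export
runPipeline <- function(cohorts, config = runConfig(), outDir = NULL) {
  if (inherits(cohorts, "SyntheticSpec"))
    cohorts <- generateCohorts(cohorts)$cohorts
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(config = unclass(config)[setdiff(names(config), "stages")],
                  stages = config$stages, cohorts = list())

  cohorts <- withStage("preprocess", lapply(cohorts, function(co)
    if (isLogged(co)) co else preprocess(co)))

  diffRes <- NULL
  if ("diff" %in% config$stages) {
    diffRes <- withStage("diff", lapply(cohorts, differentialAbundance,
                                        groupA = config$groupA,
                                        groupB = config$groupB))
    for (co in names(cohorts)) {
      d <- diffRes[[co]]
      summary$cohorts[[co]]$n_tested <- nrow(d)
      summary$cohorts[[co]]$n_significant <- sum(d$q < config$fdrDiff)
      if (!is.null(outDir))
        utils::write.table(d, file.path(outDir, paste0("diff_", co, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  selections <- NULL
  if ("select" %in% config$stages) {
    selections <- withStage("select", {
      out <- list()
      for (i in seq_along(cohorts)) {
        co <- names(cohorts)[i]
        mw <- diffRes[[co]]$metabolite_id[diffRes[[co]]$q < config$fdrDiff]
        pl <- plsdaSelect(cohorts[[co]], config$groupA, config$groupB,
                          nComp = config$nComp,
                          vipThreshold = config$vipThreshold)
        rf <- rfSelect(cohorts[[co]], config$groupA, config$groupB,
                       nTrees = config$nTrees, alpha = config$borutaAlpha,
                       seed = .stageSeed(config, "select", i))
        out[[co]] <- list(mw = mw, plsda = pl$selected, rf = rf$selected)
        summary$cohorts[[co]]$n_selected <-
          lapply(out[[co]], length)
      }
      out
    })
    if (!is.null(outDir))
      for (co in names(selections))
        for (m in names(selections[[co]]))
          utils::write.table(
            data.frame(metabolite_id = selections[[co]][[m]]),
            file.path(outDir, paste0("select_", co, "_", m, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- NULL
  if ("consensus" %in% config$stages) {
    report <- withStage("consensus", {
      rp <- intersectSelections(selections)
      rp <- excludeDrugs(rp, annotations(cohorts[[1]]),
                         extraDrugIds = config$extraDrugIds)
      if (length(rp@consensus))
        rp <- directionConcordance(rp, diffRes)
      rp
    })
    summary$panel <- report@consensus
    summary$excluded_drugs <- report@excludedDrugs
    summary$per_method_overlap <- lapply(report@perMethod, length)
    summary$concordance_fraction <-
      if (length(report@concordance)) mean(report@concordance) else NA
    if (!is.null(outDir))
      utils::write.table(data.frame(metabolite_id = report@consensus),
                         file.path(outDir, "panel.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  network <- NULL
  if ("network" %in% config$stages) {
    network <- withStage("network", buildCoabundanceNetwork(
      cohorts[[config$refCohort]], edgeFdr = config$fdrEdges,
      resolution = config$leidenResolution,
      seed = .stageSeed(config, "network")))
    summary$network <- list(
      n_nodes = length(network@partition), n_edges = nrow(network@edges),
      community_sizes = as.list(table(network@partition)),
      central_community = centralCommunity(network))
    if (!is.null(outDir))
      exportGraphML(network, file.path(outDir, "network.graphml"))
  }

  if ("cluster" %in% config$stages && length(summary$panel)) {
    withStage("cluster", {
      feats <- summary$panel
      if (!is.null(network)) {
        inGraph <- feats[feats %in% names(network@partition)]
        if (length(inGraph))
          feats <- union(feats, firstNeighbors(network, inGraph))
      }
      summary$cluster_features <- feats
      for (i in seq_along(cohorts)) {
        co <- names(cohorts)[i]
        feats_co <- intersect(feats, metaboliteIds(cohorts[[co]]))
        if (length(feats_co) < 2) next
        cr <- consensusCluster(cohorts[[co]], featureIds = feats_co,
                               k = config$k, reps = config$reps,
                               pItem = config$pItem,
                               linkage = config$linkage,
                               seed = .stageSeed(config, "cluster", i),
                               groupLabels = sampleGroups(cohorts[[co]]))
        summary$cohorts[[co]]$cluster_ari <- cr@separation
        if (!is.null(outDir))
          utils::write.csv(cr@M,
                           file.path(outDir,
                                     paste0("consensus_matrix_", co, ".csv")))
      }
    })
  }

  if ("enrich" %in% config$stages && length(summary$panel)) {
    enr <- withStage("enrich", enrichTerms(summary$panel,
                                           annotations(cohorts[[1]]),
                                           termLevel = "super_pathway"))
    summary$enrichment_top <- enr[1, c("term", "p", "q")]
    if (!is.null(outDir))
      utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary$seeds <- list(
    base = config$seed,
    select = vapply(seq_along(cohorts), function(i)
      .stageSeed(config, "select", i), numeric(1)),
    network = .stageSeed(config, "network"),
    cluster = vapply(seq_along(cohorts), function(i)
      .stageSeed(config, "cluster", i), numeric(1)))
  if (!is.null(outDir))
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  summary
}

#' Recompute headline counts on a deposited cohort matrix
#'
#' Given the three files of a deposited (already normalized) cohort, reads,
#' preprocesses and runs the differential stage, returning the quantities
#' usually quoted for such a matrix: the number of detected metabolites, the
#' number significant at the FDR threshold, and Glass-delta effect sizes for
#' requested metabolites.
#'
#' @param pathAbundance,pathAnnotations,pathMetadata cohort files, as in
#'   [readAbundance()].
#' @param fdr differential FDR threshold (default 0.1).
#' @param effectIds metabolite ids whose Glass delta to report.
#' @param groupA,groupB contrasted groups.
#' @return list with `nMetabolites`, `nSignificant`, `pThreshold05` (count at
#'   unadjusted p < 0.05), and `effects` (named Glass-delta vector).
#' @export
checkDepositedCohort <- function(pathAbundance, pathAnnotations,
                                 pathMetadata, fdr = 0.1,
                                 effectIds = character(),
                                 groupA = "HC", groupB = "cART") {
  me <- readAbundance(pathAbundance, pathAnnotations, pathMetadata)
  me <- preprocess(me)
  d <- differentialAbundance(me, groupA = groupA, groupB = groupB)
  eff <- setNames(d$D[match(effectIds, d$metabolite_id)], effectIds)
  list(nMetabolites = nrow(me), nSignificant = sum(d$q < fdr),
       pThreshold05 = sum(d$p < 0.05), effects = eff, differential = d)
}
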