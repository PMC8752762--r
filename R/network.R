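#' Significant positive Spearman edge list
#'
#' Tests every unordered metabolite pair for rank correlation across samples
#' (mid-rank tie handling), computes two-sided p-values from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`, adjusts by BH
#' across all tested pairs, and retains edges with `rho > 0` and `q` below
#' the edge FDR. Constant metabolites are excluded from testing with a
#' warning. Being rank-based, the edge list is invariant under any strictly
#' monotone per-metabolite transform.
#'
#' @param x a preprocessed [MetaboliteExperiment-class] with >= 4 samples.
#' @param edgeFdr BH threshold for retaining edges (default 0.05).
#' @return data.frame with `from`, `to`, `rho`, `q` (one row per retained
#'   unordered pair), plus attribute `"tested"` (number of pairs tested).
#' @export
spearmanEdgeList <- function(x, edgeFdr = 0.05) {
  X <- abundanceMatrix(x)
  if (ncol(X) < 4) stop("need >= 4 samples")
  const <- apply(X, 1, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("excluding constant metabolite(s): ",
            paste(rownames(X)[const], collapse = ", "))
    X <- X[!const, , drop = FALSE]
  }
  n <- ncol(X)
  R <- stats::cor(t(X), method = "spearman")
  iu <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[iu]
  rhoC <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  tval <- rhoC * sqrt((n - 2) / (1 - rhoC^2))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  q <- bhFdr(p)
  keep <- rho > 0 & q < edgeFdr
  out <- data.frame(from = rownames(X)[iu[keep, 1]],
                    to = rownames(X)[iu[keep, 2]],
                    rho = rho[keep], q = q[keep], stringsAsFactors = FALSE)
  attr(out, "tested") <- length(p)
  attr(out, "nodes") <- rownames(X)
  out
}

#' Build the co-abundance network
#'
#' Assembles the metabolite graph from [spearmanEdgeList()] (every
#' non-constant metabolite is a node, so isolated metabolites are singleton
#' nodes) and partitions it with the Leiden algorithm (modularity objective).
#' Community ids are renumbered by decreasing size (ties by smallest member
#' id).
#'
#' @param x a preprocessed [MetaboliteExperiment-class].
#' @param edgeFdr BH threshold on edges (default 0.05).
#' @param resolution Leiden resolution (default 1).
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return a [CoabundanceNetwork-class].
#' @export
buildCoabundanceNetwork <- function(x, edgeFdr = 0.05, resolution = 1,
                                    seed = 1) {
  edges <- spearmanEdgeList(x, edgeFdr = edgeFdr)
  nodes <- attr(edges, "nodes")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  partition <- detectCommunities(g, resolution = resolution, seed = seed)
  ann <- annotations(x)
  ann <- ann[match(nodes, ann$metabolite_id), , drop = FALSE]
  stats_ <- .communityStats(g, partition)
  new("CoabundanceNetwork", graph = g, edges = edges, partition = partition,
      communityStats = stats_, annotations = ann)
}

# per-community size and mean FULL-graph degree (not the induced subgraph)
.communityStats <- function(g, partition) {
  deg <- igraph::degree(g)
  do.call(rbind, lapply(sort(unique(partition)), function(cid) {
    mem <- names(partition)[partition == cid]
    data.frame(community = cid, size = length(mem),
               mean_degree = mean(deg[mem]))
  }))
}

#' Leiden community detection
#'
#' @param network a [CoabundanceNetwork-class] or igraph graph (non-empty).
#' @param resolution modularity resolution parameter.
#' @param seed integer seed; the partition is reproducible under it.
#' @return named integer vector of community ids (numbered by decreasing
#'   community size), one per node. Singletons are allowed.
#' @export
detectCommunities <- function(network, resolution = 1, seed = 1) {
  g <- if (is(network, "CoabundanceNetwork")) network@graph else network
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  mem <- igraph::membership(cl)
  # renumber by decreasing size, ties by smallest member index
  sizes <- table(mem)
  firstIdx <- vapply(names(sizes), function(k) min(which(mem == k)),
                     numeric(1))
  ord <- names(sizes)[order(-as.integer(sizes), firstIdx)]
  out <- match(as.character(mem), ord)
  names(out) <- igraph::V(g)$name
  out
}

#' Most central community
#'
#' The community with the highest mean full-graph degree (the average over
#' its members of their degree in the whole network, not the induced
#' subgraph). Ties go to the larger community, then the smaller id.
#'
#' @param network a [CoabundanceNetwork-class].
#' @return integer community id.
#' @export
centralCommunity <- function(network) {
  st <- network@communityStats
  ord <- order(-st$mean_degree, -st$size, st$community)
  st$community[ord[1]]
}

#' First neighbors of a seed set
#'
#' The seeds plus every node adjacent to a seed — the panel-expansion step
#' that pulls in the correlated context of nominated biomarkers. Seeds absent
#' from the graph are warned about and skipped; if none are present it is an
#' error.
#'
#' @param network a [CoabundanceNetwork-class].
#' @param seedIds character vector of metabolite ids.
#' @return character vector (seeds union neighbors); monotone in the seed
#'   set.
#' @export
firstNeighbors <- function(network, seedIds) {
  g <- network@graph
  present <- seedIds[seedIds %in% igraph::V(g)$name]
  absent <- setdiff(seedIds, present)
  if (length(absent))
    warning("seed id(s) not in graph, skipped: ",
            paste(absent, collapse = ", "))
  if (!length(present)) stop("no seed id present in the graph")
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                             function(v) igraph::V(g)$name[as.integer(v)])))
  sort(unique(c(present, nb)))
}

#' Super-pathway composition per community
#'
#' @param network a [CoabundanceNetwork-class].
#' @return data.frame with `community`, `super_pathway`, `count`, `percent`;
#'   percents sum to 100 within each community.
#' @export
communityComposition <- function(network) {
  ann <- network@annotations
  part <- network@partition
  out <- lapply(sort(unique(part)), function(cid) {
    mem <- names(part)[part == cid]
    sp <- ann$super_pathway[match(mem, ann$metabolite_id)]
    tab <- sort(table(sp), decreasing = TRUE)
    data.frame(community = cid, super_pathway = names(tab),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / length(mem),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Export a co-abundance network as GraphML
#'
#' Writes the graph with `rho` and `q` edge attributes and `community` and
#' `super_pathway` node attributes, readable by Cytoscape and igraph.
#'
#' @param network a [CoabundanceNetwork-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
exportGraphML <- function(network, path) {
  g <- network@graph
  igraph::V(g)$community <- unname(network@partition[igraph::V(g)$name])
  igraph::V(g)$super_pathway <- network@annotations$super_pathway[
    match(igraph::V(g)$name, network@annotations$metabolite_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
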