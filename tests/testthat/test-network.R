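# correlated-block table for network tests
blockTable <- function(nSamples = 60, rho = 0.8, blockSizes = c(10, 10),
                       seed = 1) {
  spec <- syntheticSpec(nHc = nSamples / 2, nArt = nSamples / 2,
                        nCohorts = 1, nMetabolites = sum(blockSizes),
                        blockSizes = blockSizes, rhoWithin = rho,
                        effectSizes = numeric(0), missingRate = 0,
                        cohortShiftSd = 0, seed = seed)
  gen <- generateCohorts(spec)
  list(me = preprocess(gen$cohorts[[1]]), blocks = gen$truth$blocks)
}

test_that("Spearman edges match hand-computed rank correlation", {
  # 6-sample toy with known ranks
  a <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 1, 4, 3, 6, 5,
                6, 5, 4, 3, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("M", 1:3), paste0("S", 1:6)))
  ann <- data.frame(metabolite_id = rownames(a), super_pathway = "Lipid",
                    sub_pathway = "x", hmdb_id = NA, is_drug = FALSE)
  meta <- data.frame(sample_id = colnames(a), cohort = "c",
                     group = rep(c("HC", "cART"), 3))
  me <- MetaboliteExperiment(a, ann, meta, isLogged = TRUE)
  edges <- spearmanEdgeList(me, edgeFdr = 1)  # keep all positive pairs
  # hand rank correlation M1-M2: d = (1,-1,1,-1,1,-1), rho = 1 - 6*6/(6*35)
  e12 <- edges[edges$from == "M1" & edges$to == "M2", ]
  expect_equal(e12$rho, 1 - 6 * 6 / (6 * 35))
  # M1-M3 perfectly anticorrelated: never retained even at FDR = 1
  expect_false(any(edges$from == "M1" & edges$to == "M3"))
  expect_equal(attr(edges, "tested"), 3)
})

test_that("identical profiles give a retained rho = 1 edge", {
  set.seed(2)
  base <- rnorm(20)
  a <- rbind(M1 = base, M2 = base, M3 = rnorm(20), M4 = rnorm(20))
  colnames(a) <- paste0("S", 1:20)
  ann <- data.frame(metabolite_id = rownames(a), super_pathway = "Lipid",
                    sub_pathway = "x", hmdb_id = NA, is_drug = FALSE)
  meta <- data.frame(sample_id = colnames(a), cohort = "c",
                     group = rep(c("HC", "cART"), 10))
  me <- MetaboliteExperiment(a, ann, meta, isLogged = TRUE)
  edges <- spearmanEdgeList(me, edgeFdr = 0.05)
  e <- edges[edges$from == "M1" & edges$to == "M2", ]
  expect_equal(e$rho, 1)
  expect_lt(e$q, 0.05)
  # invariance under a strictly monotone per-metabolite transform
  b <- a; b[1, ] <- exp(a[1, ]); b[3, ] <- a[3, ]^3
  me2 <- MetaboliteExperiment(b, ann, meta, isLogged = TRUE)
  e2 <- spearmanEdgeList(me2, edgeFdr = 0.05)
  expect_equal(e2[c("from", "to", "rho")], edges[c("from", "to", "rho")])
  # constant metabolite excluded with a warning
  a[4, ] <- 7
  me3 <- MetaboliteExperiment(a, ann, meta, isLogged = TRUE)
  expect_warning(e3 <- spearmanEdgeList(me3), "constant.*M4")
  expect_false("M4" %in% c(e3$from, e3$to))
})

test_that("Leiden separates disconnected cliques and planted blocks", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("n", 1:10)
  part <- detectCommunities(g, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[1:5])), 1)
  expect_equal(length(unique(part[6:10])), 1)
  # planted correlation blocks recovered on synthetic data
  bt <- blockTable(nSamples = 60, rho = 0.7, blockSizes = c(25, 25), seed = 3)
  net <- buildCoabundanceNetwork(bt$me, seed = 1)
  ari <- separationScore(net@partition[names(bt$blocks)], bt$blocks)
  expect_gte(ari, 0.9)
  # determinism under seed
  net2 <- buildCoabundanceNetwork(bt$me, seed = 1)
  expect_identical(net@partition, net2@partition)
  # modularity of the returned partition is non-negative
  expect_gte(igraph::modularity(net@graph,
                                net@partition[igraph::V(net@graph)$name]),
             0)
  expect_error(detectCommunities(igraph::make_empty_graph(0)), "empty")
})

test_that("central community maximizes mean full-graph degree", {
  # star K1,9 (mean degree 1.8) vs triangle (mean degree 2): triangle wins
  g <- igraph::make_star(10, mode = "undirected") +
    igraph::make_full_graph(3)
  igraph::V(g)$name <- paste0("n", 1:13)
  partition <- setNames(c(rep(1L, 10), rep(2L, 3)), igraph::V(g)$name)
  st <- cohortMet:::.communityStats(g, partition)
  expect_equal(st$mean_degree, c(1.8, 2))
  ann <- data.frame(metabolite_id = names(partition),
                    super_pathway = rep(c("Lipid", "Amino Acid"),
                                        c(10, 3)))
  net <- new("CoabundanceNetwork", graph = g, edges = data.frame(),
             partition = partition, communityStats = st, annotations = ann)
  expect_equal(centralCommunity(net), 2L)
  # composition sums to 100 per community
  comp <- communityComposition(net)
  expect_equal(as.numeric(tapply(comp$percent, comp$community, sum)),
               c(100, 100))
  expect_equal(comp$percent[comp$community == 2], 100)
  # single community is its own center
  net1 <- new("CoabundanceNetwork", graph = g, edges = data.frame(),
              partition = setNames(rep(1L, 13), names(partition)),
              communityStats = cohortMet:::.communityStats(
                g, setNames(rep(1L, 13), names(partition))),
              annotations = ann)
  expect_equal(centralCommunity(net1), 1L)
})

test_that("first neighbors expands seeds along edges only", {
  bt <- blockTable(nSamples = 80, rho = 0.8, blockSizes = c(15, 15), seed = 5)
  net <- buildCoabundanceNetwork(bt$me, edgeFdr = 1e-4, seed = 1)
  blk1 <- names(bt$blocks)[bt$blocks == 1]
  seeds <- blk1[1:2]
  nb <- firstNeighbors(net, seeds)
  expect_true(all(seeds %in% nb))
  # with zero cross-block correlation, neighbors stay inside the block
  expect_true(all(nb %in% blk1))
  # monotone in the seed set
  nb2 <- firstNeighbors(net, blk1[1:4])
  expect_true(all(nb %in% nb2))
  expect_warning(firstNeighbors(net, c(seeds, "absent")), "absent")
  expect_error(suppressWarnings(firstNeighbors(net, "absent")), "no seed")
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  bt <- blockTable(nSamples = 60, rho = 0.8, blockSizes = c(10, 10), seed = 7)
  net <- buildCoabundanceNetwork(bt$me, seed = 1)
  path <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), length(net@partition))
  expect_equal(igraph::ecount(g2), nrow(net@edges))
  expect_true(all(c("community", "super_pathway") %in%
                    igraph::vertex_attr_names(g2)))
  expect_true("rho" %in% igraph::edge_attr_names(g2))
})
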