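test_that("read/write round-trip is lossless", {
  me <- makeToyTable()
  a <- abundanceMatrix(me)
  a[2, 3] <- NA
  me <- MetaboliteExperiment(a, annotations(me),
                             cbind(sample_id = colnames(me),
                                   as.data.frame(colData(me))))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("ab.csv", "ann.csv", "meta.csv"))
  writeAbundance(me, paths[1], paths[2], paths[3])
  back <- readAbundance(paths[1], paths[2], paths[3])
  expect_equal(abundanceMatrix(back), abundanceMatrix(me))
  expect_equal(annotations(back), annotations(me))
  expect_equal(sampleGroups(back), sampleGroups(me))
  expect_equal(metaboliteIds(back), metaboliteIds(me))
  # tab dialect too
  paths2 <- file.path(dir, c("ab.tsv", "ann.tsv", "meta.tsv"))
  writeAbundance(me, paths2[1], paths2[2], paths2[3])
  expect_equal(abundanceMatrix(readAbundance(paths2[1], paths2[2],
                                             paths2[3])),
               abundanceMatrix(me))
})

test_that("reader reports offending ids and cells", {
  me <- makeToyTable()
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("ab.csv", "ann.csv", "meta.csv"))
  writeAbundance(me, paths[1], paths[2], paths[3])
  # drop one annotation record
  ann <- annotations(me)[-2, ]
  write.csv(ann, paths[2], row.names = FALSE, quote = FALSE)
  expect_error(readAbundance(paths[1], paths[2], paths[3]), "M2")
  # non-numeric cell
  writeAbundance(me, paths[1], paths[2], paths[3])
  tab <- read.csv(paths[1])
  tab$M1[2] <- "oops"
  write.csv(tab, paths[1], row.names = FALSE, quote = FALSE)
  expect_error(readAbundance(paths[1], paths[2], paths[3]),
               "row 2.*column 'M1'")
  # duplicate sample ids
  writeAbundance(me, paths[1], paths[2], paths[3])
  tab <- read.csv(paths[1])
  tab$sample_id[2] <- tab$sample_id[1]
  write.csv(tab, paths[1], row.names = FALSE, quote = FALSE)
  expect_error(readAbundance(paths[1], paths[2], paths[3]), "duplicate")
})

test_that("container validity enforces annotations and groups", {
  me <- makeToyTable()
  ann <- annotations(me)
  ann$is_drug[1] <- TRUE  # super_pathway Lipid -> violation
  expect_error(MetaboliteExperiment(abundanceMatrix(me), ann,
                                    cbind(sample_id = colnames(me),
                                          as.data.frame(colData(me)))),
               "Xenobiotics")
  meta <- cbind(sample_id = colnames(me), as.data.frame(colData(me)))
  meta$group[1] <- "patient"
  expect_error(MetaboliteExperiment(abundanceMatrix(me), annotations(me),
                                    meta), "group")
  a <- abundanceMatrix(me)
  a[1, 1] <- -1
  expect_error(MetaboliteExperiment(a, annotations(me),
                                    cbind(sample_id = colnames(me),
                                          as.data.frame(colData(me)))),
               ">= 0")
})

test_that("preprocess imputes, logs and scales as documented", {
  a <- matrix(c(1, NA, 4,
                5, 5, 5,
                1, 2, 4), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("M", 1:3), paste0("S", 1:3)))
  ann <- data.frame(metabolite_id = rownames(a), super_pathway = "Lipid",
                    sub_pathway = "x", hmdb_id = NA, is_drug = FALSE)
  meta <- data.frame(sample_id = colnames(a), cohort = "c",
                     group = c("HC", "HC", "cART"))
  me <- MetaboliteExperiment(a, ann, meta)
  expect_warning(pp <- preprocess(me), "zero-variance")
  # min-imputation before log
  expect_equal(unname(abundanceMatrix(pp, "imputed")[1, ]), c(1, 1, 4))
  expect_equal(unname(rowData(pp)$n_imputed), c(1L, 0L, 0L))
  # constant metabolite z-scored to zeros
  expect_equal(unname(abundanceMatrix(pp)[2, ]), c(0, 0, 0))
  # [1,2,4] -> log2 [0,1,2] -> z [-1,0,1]
  expect_equal(unname(abundanceMatrix(pp)[3, ]), c(-1, 0, 1))
  expect_true(isLogged(pp) && isScaled(pp))
  # missingness pattern of the working assay is what imputation filled
  expect_error(suppressWarnings(preprocess(pp)), "already preprocessed")
  # unscaled variant keeps plain log2
  pp2 <- suppressWarnings(preprocess(me, scale = FALSE))
  expect_equal(unname(abundanceMatrix(pp2)[3, ]), c(0, 1, 2))
  # entirely-missing metabolite
  a[2, ] <- NA
  me2 <- MetaboliteExperiment(a, ann, meta)
  expect_error(preprocess(me2), "entirely missing.*M2")
})

test_that("super-pathway proportions match counts and partition-sum", {
  # universe shaped like a large detected-metabolite set
  spec <- syntheticSpec(nMetabolites = 841, missingRate = 0, nCohorts = 1,
                        blockSizes = integer(0), seed = 4)
  me <- generateCohorts(spec)$cohorts[[1]]
  prop <- superpathwayProportions(me)
  expect_equal(sum(prop$count), 841)
  expect_equal(sum(prop$percent), 100, tolerance = 1e-12)
  expect_equal(prop$count[prop$super_pathway == "Lipid"],
               round(0.46 * 841))
  expect_equal(round(prop$percent[match(
    c("Lipid", "Amino Acid", "Xenobiotics"), prop$super_pathway)]),
    c(46, 22, 17))
  # single metabolite
  one <- superpathwayProportions(me, subset = metaboliteIds(me)[1])
  expect_equal(nrow(one), 1)
  expect_equal(one$percent, 100)
  # empty subset -> empty table
  expect_equal(nrow(superpathwayProportions(me, subset = character())), 0)
  # disjoint subsets partitioning the universe sum to universe counts
  ids <- metaboliteIds(me)
  half <- superpathwayProportions(me, ids[1:400])
  rest <- superpathwayProportions(me, ids[401:841])
  combined <- aggregate(count ~ super_pathway,
                        rbind(half[1:2], rest[1:2]), sum)
  expect_equal(combined$count[match(prop$super_pathway,
                                    combined$super_pathway)],
               prop$count)
})
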