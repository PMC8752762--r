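test_that("Mann-Whitney exact path matches enumeration and hand values", {
  res <- mannWhitney(1:3, 4:6)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/20 assignments as extreme, both tails
  # symmetry: swap maps U to n1*n2 - U, p unchanged
  swapped <- mannWhitney(4:6, 1:3)
  expect_equal(swapped$U, 9)
  expect_equal(swapped$p, res$p)
  # same multiset -> p = 1
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # all values tied -> p = 1 with warning
  expect_warning(tied <- mannWhitney(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(tied$p, 1)
  # enumeration oracle on random continuous data, n1 = n2 = 3
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(mannWhitney(x, y)$p, enumMannWhitneyP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree at n = 12 + 12", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12, mean = runif(1, 0, 1))
    pe <- mannWhitney(x, y, exact = TRUE)$p
    pa <- mannWhitney(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(numeric(0)), numeric(0))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    q <- bhFdr(p)
    expect_equal(q, bruteForceBH(p))
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("Glass delta and its categories follow the definition", {
  gd <- glassDelta(c(2, 2, 2, 2), c(0, 1, 1, 2))
  expect_equal(gd$D, 1 / sqrt(2 / 3))
  expect_equal(gd$category, "large")
  expect_equal(glassDelta(c(1, 2, 3), c(3, 2, 1))$D, 0)
  expect_error(glassDelta(c(1, 2), c(5, 5)), "undefined")
  expect_equal(effectCategory(c(0.1, 0.25, 0.62, 0.9, -1.07)),
               c("negligible", "small", "medium", "large", "large"))
  # invariant under common affine rescaling
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(glassDelta(3 * x + 7, 3 * y + 7)$D, glassDelta(x, y)$D)
})

test_that("covariate-adjusted regression behaves at its limits", {
  set.seed(9)
  n <- 40
  g <- rep(c("HC", "cART"), each = n / 2)
  # covariate orthogonal to group: p close to the plain two-sample t-test
  covar <- rep(c(-1, 1), n / 2)
  y <- rnorm(n) + (g == "cART") * 0.8
  adj <- adjustedGroupTest(y, g, data.frame(z = covar))
  plain <- t.test(y[g == "cART"], y[g == "HC"], var.equal = TRUE)$p.value
  expect_lt(abs(adj$p - plain), 0.02)
  # group effect entirely explained by the covariate
  covar2 <- (g == "cART") * 2 + rnorm(n, sd = 0.5)
  y2 <- covar2 + rnorm(n, sd = 0.1)
  adj2 <- adjustedGroupTest(y2, g, data.frame(z = covar2))
  expect_lt(abs(adj2$beta), 0.2)
  # rank deficiency names the collinear column
  expect_error(adjustedGroupTest(y, g, data.frame(dup = (g == "cART") * 1)),
               "collinear.*dup")
  # simulation: known partial effect recovered within 2 SE most of the time
  hits <- vapply(1:100, function(i) {
    z <- rnorm(n)
    yy <- 1.0 * (g == "cART") + 0.5 * z + rnorm(n)
    fit <- lm(yy ~ I(g == "cART") + z)
    est <- coef(summary(fit))[2, ]
    abs(est["Estimate"] - 1.0) <= 2 * est["Std. Error"]
  }, logical(1))
  expect_gte(mean(hits), 0.88)
})

test_that("clinical table statistics are recovered from counts/summaries", {
  ex <- chiSquareCounts(4, 24, 14, 24)
  expect_lt(abs(ex$p - 0.007), 0.001)
  al <- chiSquareCounts(15, 24, 17, 24)
  expect_lt(abs(al$p - 0.75), 0.01)
  # identical counts -> statistic 0, p = 1
  same <- chiSquareCounts(10, 24, 10, 24)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_warning(chiSquareCounts(0, 3, 1, 3), "below 1")
  # summary-based t-tests from printed mean (95% CI)
  age <- summaryTTest(48.00, c(45.59, 50.41), 24, 47.54, c(42.54, 52.50), 24)
  expect_lt(abs(age$p - 0.86), 0.005)
  bmi <- summaryTTest(27.88, c(26.47, 29.29), 24, 26.66, c(23.90, 29.41), 24)
  expect_lt(abs(bmi$p - 0.42), 0.005)
})

test_that("tableOne dispatches t-test and chi-square by variable type", {
  set.seed(3)
  md <- data.frame(group = rep(c("HC", "cART"), each = 24),
                   age = rnorm(48, 48, 5),
                   exercise = c(rep(c(TRUE, FALSE), c(4, 20)),
                                rep(c(TRUE, FALSE), c(14, 10))))
  t1 <- tableOne(md)
  expect_setequal(t1$test, c("t", "chisq"))
  expect_lt(abs(t1$p[t1$variable == "exercise"] - 0.0073), 1e-3)
})

test_that("differentialAbundance ties U, q, fold change and effect together", {
  gen <- generateCohorts(smallSpec(seed = 31))
  me <- preprocess(gen$cohorts[[1]])
  d <- differentialAbundance(me)
  expect_equal(nrow(d), 150)
  n1n2 <- 24 * 24
  expect_true(all(d$U >= 0 & d$U <= n1n2))
  expect_true(all(d$q >= d$p - 1e-15))
  expect_identical(d$direction, ifelse(d$log2fc >= 0, "up", "down"))
  # planted biomarkers dominate the ranking
  top5 <- d$metabolite_id[order(d$p)][1:5]
  expect_setequal(top5, gen$truth$biomarkers$metabolite_id)
  # effect signs match planted directions
  idx <- match(gen$truth$biomarkers$metabolite_id, d$metabolite_id)
  expect_equal(sign(d$D[idx]), sign(gen$truth$biomarkers$effect))
})
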