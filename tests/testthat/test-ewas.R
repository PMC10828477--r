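test_that("exact linear data is recovered exactly", {
  age <- c(60, 65, 70, 75, 80, 85, 90, 95)
  b <- rbind(cg001 = 0.3 + 0.002 * age)
  colnames(b) <- sprintf("s%02d", seq_along(age))
  ss <- data.frame(sample_id = colnames(b), age = age)
  res <- fitAgeEwas(b, ss, covariates = character())
  tb <- ewasTable(res)
  expect_equal(tb$effect, 0.002, tolerance = 1e-12)
  # zero residual variance: t undefined, excluded from significance
  expect_true(is.na(tb$p))
  expect_false(tb$significant)
})

test_that("coefficients and t statistics match the normal-equations oracle", {
  set.seed(11)
  n <- 6
  ss <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   age = c(52, 61, 70, 78, 85, 93),
                   sex = c("F", "M", "F", "M", "F", "M"))
  b <- namedMatrix(runif(5 * n), 5, n)
  res <- fitAgeEwas(b, ss, covariates = "sex")
  tb <- ewasTable(res)
  X <- cbind(1, ss$age, ss$sex == "M")
  XtXinv <- solve(t(X) %*% X)
  for (i in 1:5) {
    beta <- XtXinv %*% t(X) %*% b[i, ]
    r <- b[i, ] - X %*% beta
    s2 <- sum(r^2) / (n - 3)
    se <- sqrt(s2 * XtXinv[2, 2])
    expect_equal(tb$effect[i], beta[2], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(tb$t[i], beta[2] / se, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(tb$p[i], 2 * pt(-abs(beta[2] / se), n - 3),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("rank-deficient designs fail naming the aliased columns", {
  ss <- data.frame(sample_id = sprintf("s%d", 1:8), age = 1:8 * 10,
                   dup = 1:8 * 10 + 0)  # perfectly collinear with age
  b <- namedMatrix(runif(8 * 2), 2, 8)
  expect_error(fitAgeEwas(b, ss, covariates = "dup"), "aliased.*dup")
})

test_that("Bonferroni adjustment follows min(1, m p) with NA propagation", {
  expect_equal(adjustPvalues(c(0.001, 0.002, 0.003, 0.004, 0.005))[1], 0.005)
  expect_equal(adjustPvalues(rep(0.5, 10))[1], 1)
  expect_equal(adjustPvalues(0.37), 0.37)
  out <- adjustPvalues(c(0.01, NA, 0.02))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.04))  # m counts non-NA only
  expect_error(adjustPvalues(c(0.5, 1.2)), "outside")
  # cross-check against stats::p.adjust on complete input
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_equal(adjustPvalues(p), p.adjust(p, "bonferroni"))
})

test_that("null simulations keep the Bonferroni family-wise error in check", {
  hits <- sapply(1:20, function(s) {
    set.seed(3000 + s)
    n <- 200; m <- 2000
    b <- namedMatrix(runif(n * m), m, n)
    ss <- data.frame(sample_id = colnames(b),
                     age = runif(n, 40, 100))
    res <- fitAgeEwas(b, ss, covariates = character())
    mean(ewasTable(res)$significant)
  })
  expect_lte(mean(hits), 0.01)
})

test_that("partition performs conserving set algebra with direction tallies", {
  mkRes <- function(ids, sig, eff, tissue) {
    tb <- data.frame(cpg_id = ids, effect = eff, t = 1, p = 0.5, p_adj = 1,
                     significant = FALSE)
    tb$p[sig] <- 1e-8; tb$p_adj[sig] <- 1e-6; tb$significant[sig] <- TRUE
    new("EwasResult", table = tb, tissue = tissue, covariates = character(),
        threshold = 0.01)
  }
  ids <- sprintf("cg%d", 1:6)
  resA <- mkRes(ids, 1:3, c(1, -1, 1, 1, 1, 1), "A")
  resB <- mkRes(ids, 2:4, c(1, 1, -1, 1, 1, 1), "B")
  pt <- partitionCpgs(resA, resB)
  expect_equal(pt$A_only, "cg1")
  expect_equal(pt$shared, c("cg2", "cg3"))
  expect_equal(pt$B_only, "cg4")
  expect_equal(unname(pt$direction$A_only), c(1, 0))
  expect_equal(unname(pt$direction$shared_in_A), c(1, 1))
  expect_equal(unname(pt$direction$shared_in_B), c(1, 1))
  expect_equal(sum(pt$direction$shared_in_A), length(pt$shared))
  expect_equal(length(pt$A_only) + length(pt$shared),
               unname(pt$nSignificant["A"]))
  # the headline arithmetic: 201 shared of 613 significant is 32.8%
  idsBig <- sprintf("cg%05d", 1:5000)
  resA2 <- mkRes(idsBig, 1:613, rep(1, 5000), "A")
  resB2 <- mkRes(idsBig, 413:4625, rep(1, 5000), "B")
  pt2 <- partitionCpgs(resA2, resB2)
  expect_equal(length(pt2$shared), 201)
  expect_equal(unname(pt2$fractions["shared_pct_of_A"]), 32.8)
  resC <- mkRes(sprintf("xx%d", 1:4), 1:2, rep(1, 4), "C")
  expect_error(partitionCpgs(resA, resC), "panel mismatch")
})

test_that("partition matches simulation truth for well-powered CpGs", {
  st <- smallStudy(seed = 31, n = 400, noiseSd = 0.01,
                   counts = smallCounts(20L, 15L, 15L, 200L, 0L))
  resA <- fitAgeEwas(tissueA(st))
  resB <- fitAgeEwas(tissueB(st))
  pt <- partitionCpgs(resA, resB)
  tr <- simTruth(st)
  # at n=400, noise 0.01, the smallest simulated slope (5e-4/year over ~40
  # years of age spread) is detected with power ~1; classes should match
  sharedTruth <- rownames(tr)[tr$class == "shared_age"]
  expect_true(all(sharedTruth %in% pt$shared))
  expect_true(all(pt$B_only %in% rownames(tr)[tr$class == "tissueB_only"]))
  expect_false(any(rownames(tr)[tr$class == "null"] %in%
                     c(pt$A_only, pt$shared, pt$B_only)))
})

test_that("rank-sum p-value agrees with exhaustive enumeration on 5 vs 5", {
  x <- c(0.0012, 0.0019, 0.0023, 0.0031, 0.0044)
  y <- c(0.0015, 0.0027, 0.0036, 0.0049, 0.0058)
  # brute force: all C(10,5) assignments of the pooled values to group 1
  pool <- c(x, y)
  W <- sum(rank(pool)[1:5]) - 5 * 6 / 2
  combs <- combn(10, 5)
  stats <- apply(combs, 2, function(i) sum(rank(pool)[i]) - 15)
  pBrute <- mean(stats <= W | stats >= (25 - W))  # two-sided symmetric null
  ht <- wilcox.test(x, y)
  expect_equal(ht$p.value, pBrute, tolerance = 1e-12)
})

test_that("effect-size comparisons detect the simulated ratio and honour nulls", {
  st <- smallStudy(seed = 32, n = 300, noiseSd = 0.01,
                   counts = smallCounts(30L, 10L, 10L, 100L, 0L))
  resA <- fitAgeEwas(tissueA(st)); resB <- fitAgeEwas(tissueB(st))
  pt <- partitionCpgs(resA, resB)
  cmp <- compareEffectSizes(resA, resB, pt)
  sh <- cmp$contrasts$shared_abs
  expect_equal(sh$test, "signed-rank")
  expect_lt(sh$p_adj, 0.01)     # k=2 ratio over >=30 shared CpGs
  expect_lte(max(sapply(cmp$contrasts, `[[`, "p_adj")), 1)
  # identical effect vectors: no shift, p = 1
  identicalRes <- compareEffectSizes(resA, resA,
                                     partitionCpgs(resA, resA))
  expect_equal(identicalRes$contrasts$positive$p, 1)
  # tiny contrasts are skipped with warnings
  small <- smallStudy(seed = 33, n = 60,
                      counts = smallCounts(2L, 1L, 1L, 20L, 0L))
  rA <- fitAgeEwas(tissueA(small)); rB <- fitAgeEwas(tissueB(small))
  w <- capture_warnings(compareEffectSizes(rA, rB, partitionCpgs(rA, rB)))
  expect_true(any(grepl("skipped", w)))
})

test_that("paired signed-rank rejects reliably at k=2 across replicates", {
  rejections <- sapply(1:20, function(s) {
    st <- generateCohort(rateScenarioConfig(seed = 500 + s, k = 2, n = 150,
                                            noiseSd = 0.01, nShared = 201L))
    resA <- fitAgeEwas(tissueA(st), covariates = character())
    resB <- fitAgeEwas(tissueB(st), covariates = character())
    effA <- ewasTable(resA)$effect[1:201]
    effB <- ewasTable(resB)$effect[1:201]
    wilcox.test(abs(effA), abs(effB), paired = TRUE)$p.value < 0.01 / 3
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("power is nondecreasing in the true effect size", {
  n <- 120
  set.seed(77)
  age <- runif(n, 40, 100)
  detect <- sapply(c(2e-4, 6e-4, 18e-4), function(w) {
    hits <- sapply(1:30, function(r) {
      b <- namedMatrix(0.3 + w * age + rnorm(n, 0, 0.02), 1, n)
      ss <- data.frame(sample_id = colnames(b), age = age)
      ewasTable(fitAgeEwas(b, ss, covariates = character()))$significant
    })
    mean(hits)
  })
  expect_true(all(diff(detect) >= 0))
})

test_that("category summaries report composition, offsets and null correlations", {
  st <- smallStudy(seed = 34, n = 80, noiseSd = 0.01)
  shared <- sharedTruthSet(st)
  cs <- categorySummary(st, cpgSet = shared)
  expect_equal(sum(cs$composition$n), length(shared))
  expect_equal(sum(cs$composition$fraction), 1)
  # tissue A is built with lower island/shore baselines
  expect_gt(cs$setTallies[["frac_lower_median_in_A"]], 0.5)
  expect_gt(cs$setTallies[["frac_positive_in_both"]], 0.8)
  # constructed offset: tissue A uniformly 0.05 lower -> A always lower
  bA <- namedMatrix(0.30, 4, 6); bB <- namedMatrix(0.35, 4, 6)
  ann <- data.frame(cpg_id = rownames(bA), chrom = "chr1", category = "island",
                    cross_hybridizing = FALSE, design = "II")
  ss <- data.frame(sample_id = colnames(bA), age = seq(60, 85, 5), sex = "F",
                   tissue = "A", dataset_id = "d1", disease = "control")
  stOff <- PairedTissueStudy(BetaSet(bA, ss, ann),
                             BetaSet(bB, transform(ss, tissue = "B"), ann),
                             labels = c("A", "B"))
  csOff <- categorySummary(stOff, cpgSet = rownames(bA))
  expect_equal(csOff$setTallies[["frac_lower_median_in_A"]], 1)
})

test_that("null-class mean methylation shows only chance-level age correlation", {
  # negative control: across replicates, the per-category mean-beta-vs-age
  # tests on null data should be nominally significant at about the 5% rate
  pvals <- unlist(lapply(1:20, function(s) {
    st <- generateCohort(simulationConfig(
      nSubjects = 100, seed = 700 + s, noiseSd = 0.02,
      cpgCounts = c(shared_age = 0L, tissueA_only = 0L, tissueB_only = 0L,
                    null = 200L, sex_linked = 0L)))
    categorySummary(st)$meanBetaAgeCor$p
  }))
  expect_lte(mean(pvals < 0.05, na.rm = TRUE), 0.10)
})
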