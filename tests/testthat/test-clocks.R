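test_that("age transforms invert exactly and hit their anchor points", {
  expect_equal(transformAge(20, "log1p"), log(21))
  expect_equal(transformAge(20, "horvath", adultAge = 20), 0)
  expect_equal(transformAge(50, "identity"), 50)
  for (kind in c("identity", "log1p", "horvath"))
    for (a in c(1, 20, 80, 114))
      expect_equal(inverseTransformAge(transformAge(a, kind), kind), a,
                   tolerance = 1e-10)
  # horvath is continuous and increasing through the knot
  v <- transformAge(c(19.99, 20, 20.01), "horvath")
  expect_true(all(diff(v) > 0))
  expect_lt(v[3] - v[1], 0.01)
  expect_error(transformAge(-2), "domain")
})

test_that("a noiseless single-CpG clock recovers ages exactly at lambda 0", {
  age <- seq(20, 90, length.out = 30)
  b <- rbind(cg1 = 0.1 + 0.004 * transformAge(age, "log1p"))
  b <- rbind(b, cg2 = 0.5 + 0 * age)
  colnames(b) <- sprintf("s%02d", seq_along(age))
  ss <- data.frame(sample_id = colnames(b), age = age)
  clk <- trainClock(b, c("cg1", "cg2"), samples = ss, transform = "log1p",
                    config = enetConfig(alpha = 0.5, lambda = 0))
  pred <- predictAge(clk, b)
  expect_equal(pred$dnam_age, age, tolerance = 1e-6)
  expect_true(all(names(clockCoef(clk)) %in% c("cg1", "cg2")))
})

test_that("clocks only store CpGs from the requested set, with provenance", {
  st <- smallStudy(seed = 51, n = 80)
  shared <- sharedTruthSet(st)
  clk <- trainClock(tissueA(st), shared, name = "shared_clock",
                    config = enetConfig(alpha = 0.5, seed = 2))
  expect_true(all(names(clockCoef(clk)) %in% shared))
  pr <- clockProvenance(clk)
  expect_equal(pr$alpha, 0.5)
  expect_equal(pr$n, 80)
  expect_equal(pr$cpg_set_size, length(shared))
  expect_error(trainClock(tissueA(st), c("nope1", "nope2")), "empty feature")
})

test_that("lower alpha retains at least as many CpGs at the CV-chosen penalty", {
  wins <- sapply(1:20, function(s) {
    st <- generateCohort(rateScenarioConfig(seed = 900 + s, k = 1, n = 120,
                                            noiseSd = 0.02, nShared = 40L))
    shared <- sharedTruthSet(st)
    n02 <- length(clockCoef(trainClock(tissueA(st), shared,
                                       config = enetConfig(alpha = 0.2, seed = s))))
    n05 <- length(clockCoef(trainClock(tissueA(st), shared,
                                       config = enetConfig(alpha = 0.5, seed = s))))
    n02 >= n05
  })
  expect_gte(sum(wins), 18)
})

test_that("leave-one-dataset-out excludes the held-out dataset and covers all samples", {
  st <- smallStudy(seed = 52, n = 90, nDatasets = 3)
  bs <- tissueA(st)
  shared <- sharedTruthSet(st)
  cv <- leaveOneDatasetOutCV(bs, shared, config = enetConfig(alpha = 0.5, seed = 4))
  expect_equal(cv$sample_id, colnames(betaValues(bs)))
  expect_false(anyNA(cv$dnam_age))
  expect_equal(cv$fold, sampleData(bs)$dataset_id)  # each predicted by own fold
  # verify training exclusion via fold provenance
  models <- attr(cv, "models")
  for (f in names(models)) {
    nTrain <- clockProvenance(models[[f]])$n
    expect_equal(nTrain, sum(sampleData(bs)$dataset_id != f))
  }
  # two-dataset case: each model trains on the single other dataset
  st2 <- smallStudy(seed = 53, n = 40, nDatasets = 2)
  cv2 <- leaveOneDatasetOutCV(tissueA(st2), sharedTruthSet(st2),
                              config = enetConfig(alpha = 0.5, seed = 4))
  m2 <- attr(cv2, "models")
  ds <- sampleData(tissueA(st2))$dataset_id
  expect_equal(clockProvenance(m2$ds1)$n, sum(ds == "ds2"))
  expect_equal(clockProvenance(m2$ds2)$n, sum(ds == "ds1"))
  # single dataset fails
  one <- smallStudy(seed = 54, n = 20, nDatasets = 1)
  expect_error(leaveOneDatasetOutCV(tissueA(one), sharedTruthSet(one)),
               "at least 2 distinct datasets")
})

test_that("LOCO predictions do not depend on sample or dataset order", {
  st <- smallStudy(seed = 55, n = 60, nDatasets = 3)
  bs <- tissueA(st)
  shared <- sharedTruthSet(st)
  cfg <- enetConfig(alpha = 0.5, seed = 6)
  cv1 <- leaveOneDatasetOutCV(bs, shared, config = cfg)
  perm <- sample(ncol(bs))
  cv2 <- leaveOneDatasetOutCV(betaValues(bs)[, perm], shared,
                              samples = sampleData(bs), config = cfg)
  m <- match(cv1$sample_id, cv2$sample_id)
  expect_equal(cv1$dnam_age, cv2$dnam_age[m], tolerance = 1e-12)
})

test_that("k-fold partitions are near-equal, seeded, and cover every sample", {
  st <- smallStudy(seed = 56, n = 100, counts = smallCounts(10L, 0L, 0L, 20L, 0L))
  bs <- tissueA(st)
  shared <- sharedTruthSet(st)
  cv <- kFoldCV(bs, shared, config = enetConfig(alpha = 0.5, seed = 7), k = 10)
  expect_equal(unname(table(cv$fold)), rep(10L, 10), ignore_attr = TRUE)
  expect_false(anyNA(cv$dnam_age))
  st2 <- smallStudy(seed = 57, n = 101, counts = smallCounts(10L, 0L, 0L, 20L, 0L))
  cv2 <- kFoldCV(tissueA(st2), sharedTruthSet(st2),
                 config = enetConfig(alpha = 0.5, seed = 7), k = 10)
  expect_true(all(table(cv2$fold) %in% c(10L, 11L)))
  cv3 <- kFoldCV(bs, shared, config = enetConfig(alpha = 0.5, seed = 7), k = 10)
  expect_identical(cv$fold, cv3$fold)
  expect_identical(cv$dnam_age, cv3$dnam_age)
  expect_error(kFoldCV(bs, shared, k = 200), "invalid k")
})

test_that("out-of-fold accuracy approaches the generator noise floor", {
  # theoretical floor: per-CpG noise 0.01 on ~201 informative CpGs leaves
  # little residual age error; require out-of-fold MAD within 2x of the
  # in-sample MAD of an oracle OLS fit on the true model CpGs
  st <- generateCohort(rateScenarioConfig(seed = 58, k = 1, n = 400,
                                          noiseSd = 0.01, nShared = 201L))
  bs <- tissueA(st)
  shared <- sharedTruthSet(st)
  age <- sampleData(bs)$age
  cv <- kFoldCV(bs, shared, transform = "identity",
                config = enetConfig(alpha = 0.5, seed = 5), k = 5)
  madCV <- mean(abs(cv$dnam_age - age))
  oracleFit <- lm.fit(cbind(1, t(betaValues(bs)[shared, ])), age)
  madOracle <- mean(abs(oracleFit$residuals))
  expect_lte(madCV, 2 * madOracle)
  expect_gte(cor(cv$dnam_age, age), 0.9)
})

test_that("clock serialization round-trips bit for bit and rejects malformed tables", {
  st <- smallStudy(seed = 59, n = 60)
  clk <- trainClock(tissueA(st), sharedTruthSet(st), name = "rt",
                    config = enetConfig(alpha = 0.2, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  saveClock(clk, path)
  clk2 <- loadClock(path)
  p1 <- predictAge(clk, tissueA(st))
  p2 <- predictAge(clk2, tissueA(st))
  expect_identical(p1$dnam_age, p2$dnam_age)
  expect_identical(clockCoef(clk), clockCoef(clk2))
  expect_identical(clockIntercept(clk), clockIntercept(clk2))
  # hand-written 2-CpG clock: predictions match hand arithmetic
  hand <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# name\thand", "# intercept\t10", "# transform\tidentity",
               "cpg_id\tcoefficient", "cgA\t100", "cgB\t-50"), hand)
  hc <- loadClock(hand)
  b <- matrix(c(0.4, 0.2), 2, 1, dimnames = list(c("cgA", "cgB"), "s1"))
  expect_equal(predictAge(hc, b)$dnam_age, 10 + 100 * 0.4 - 50 * 0.2)
  # malformed: duplicate rows / missing intercept
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# intercept\t1", "cpg_id\tcoefficient", "cgA\t1", "cgA\t2"), dup)
  expect_error(loadClock(dup), "duplicate")
  noint <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# name\tx", "cpg_id\tcoefficient", "cgA\t1"), noint)
  expect_error(loadClock(noint), "intercept")
})
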