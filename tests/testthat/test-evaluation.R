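test_that("stratified folds partition the data and preserve class balance", {
  set.seed(17)
  y <- c(rep(1L, 720), rep(0L, 280))
  folds <- stratifiedKFold(y, k = 20L, seed = 3L)
  testSets <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(testSets)), 1:1000)
  expect_true(all(vapply(testSets, length, 0L) == 50L))
  # 720/280 split: every fold gets exactly 36 positives
  expect_true(all(vapply(testSets, function(i) sum(y[i] == 1), 0L) == 36L))
  # train and test are disjoint and complementary
  for (f in folds[1:3]) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_identical(sort(c(f$train, f$test)), 1:1000)
  }
  # general stratification bound on an uneven split
  y2 <- c(rep(1L, 101), rep(0L, 52))
  folds2 <- stratifiedKFold(y2, k = 7L, seed = 5L)
  rate <- mean(y2)
  for (f in folds2) {
    pos <- sum(y2[f$test] == 1)
    expect_lte(abs(pos - round(length(f$test) * rate)), 1)
  }
  expect_error(stratifiedKFold(c(rep(1L, 30), 0L), k = 5L), "class")
})

test_that("accuracy and F1 match brute-force confusion-matrix arithmetic", {
  # frozen worked example: 10 trials, 8 correct, TP=6 FP=1 FN=1
  pred <- c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0)
  truth <- c(1, 1, 1, 1, 1, 1, 0, 1, 0, 0)
  m <- computeMetrics(pred, truth)
  expect_equal(m[["accuracy"]], 0.8, tolerance = 1e-12)
  expect_equal(m[["f1"]], 0.857143, tolerance = 1e-6)
  expect_identical(computeMetrics(truth, truth),
                   c(accuracy = 1, f1 = 1))
  # zero-division convention: no predicted positives with true positives
  expect_identical(computeMetrics(rep(0, 5), c(1, 0, 0, 1, 0))[["f1"]], 0)
  # random property check against the brute-force oracle
  set.seed(23)
  for (rep in 1:10) {
    p <- rbinom(30, 1, 0.5); t <- rbinom(30, 1, 0.7)
    expect_equal(computeMetrics(p, t), bruteForceMetrics(p, t),
                 tolerance = 1e-12)
  }
  expect_error(computeMetrics(1, c(1, 0)), "equal length")
})

test_that("Wilcoxon signed-rank matches exact enumeration and symmetry", {
  # n = 3, all differences positive: the exact two-sided p enumerates all
  # 2^3 sign assignments; only the all-positive one has rank sum 6, and the
  # two-sided tail doubles it: p = 2/8 = 0.25
  a <- c(0.9, 0.8, 0.85); b <- c(0.7, 0.55, 0.62)
  r <- wilcoxonSignedRank(a, b)
  expect_equal(r$pValue, 0.25, tolerance = 1e-12)
  # negating all differences leaves p unchanged
  r2 <- wilcoxonSignedRank(b, a)
  expect_equal(r2$pValue, r$pValue, tolerance = 1e-12)
  expect_error(wilcoxonSignedRank(a, a), "degenerate")
  # agrees with the reference implementation on a larger sample
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxonSignedRank(x, y)$pValue,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("response-time quantiles interpolate order statistics", {
  expect_identical(responseTimeQuantiles(c(10, 20, 30, 40, 50)),
                   c(q1 = 20, median = 30, q3 = 40))
  expect_identical(responseTimeQuantiles(7), c(q1 = 7, median = 7, q3 = 7))
  set.seed(2)
  x <- rexp(31)
  expect_identical(responseTimeQuantiles(x),
                   responseTimeQuantiles(sample(x)))
})

test_that("feature truncation keeps the right clip prefix", {
  m <- matrix(rnorm(30 * 2), 30, 2)
  # frozen: floor(12 / 1.07) = 11 clips
  expect_identical(truncateFeatures(m, 12, clipDuration = 1.07), m[1:11, ])
  # a cutoff below one clip still keeps the first clip
  expect_identical(truncateFeatures(m, 1.0, clipDuration = 1.07),
                   m[1, , drop = FALSE])
  # cutoff beyond the sequence leaves it unchanged
  expect_identical(truncateFeatures(m, 1e6, clipDuration = 1.07), m)
  expect_error(truncateFeatures(m, 0, clipDuration = 1.07), "cutoff")
  # store-level truncation preserves clip duration and applies per sequence
  store <- featureStore(list(a = m, b = m[1:5, ]), clipDuration = 1.07)
  tr <- truncateFeatures(store, 12)
  expect_identical(clipDuration(tr), 1.07)
  expect_identical(nrow(getSequence(tr, "a")), 11L)
  expect_identical(nrow(getSequence(tr, "b")), 5L)
})

test_that("parameter-similarity metrics behave under shift and reversal", {
  a <- list(theta = c(0.3, -1, 2, 0.5), beta = c(1, 2, 3))
  same <- compareParameterEstimates(a, a)
  expect_equal(same$rmse, c(0, 0), tolerance = 1e-12)
  expect_equal(same$pearson, c(1, 1), tolerance = 1e-12)
  expect_equal(same$kendall, c(1, 1), tolerance = 1e-12)
  shifted <- list(theta = a$theta + 1, beta = a$beta + 1)
  sh <- compareParameterEstimates(a, shifted)
  expect_equal(sh$rmse, c(1, 1), tolerance = 1e-12)
  expect_equal(sh$pearson, c(1, 1), tolerance = 1e-12)
  rev <- list(theta = sort(a$theta, decreasing = TRUE)[rank(a$theta)],
              beta = rev(a$beta))
  rv <- compareParameterEstimates(a, rev)
  expect_equal(rv$kendall, c(-1, -1), tolerance = 1e-12)
  expect_error(compareParameterEstimates(list(theta = 1, beta = 1:2),
                                         list(theta = 1, beta = 1:2)),
               "fewer than 2")
})

test_that("agreement grouping matches a hand-tabulated toy case", {
  predsA <- c(1, 0, 1, 1, 0)
  predsB <- c(1, 1, 1, 0, 0)
  truths <- c(1, 0, 0, 1, 1)
  paramsA <- data.frame(theta = c(1, 2, 3, 4, 5),
                        beta = c(0, 0, 1, 1, 2),
                        phi = c(-1, 0, 1, 2, 0))
  g <- agreementGroups(predsA, predsB, truths, paramsA)
  expect_identical(g$nSame, 3L)        # trials 1, 3, 5
  expect_identical(g$nDiff, 2L)        # trials 2, 4
  expect_identical(g$aCorrectInDiff, 2L)  # A right on both 2 and 4
  st <- g$stats
  diffTheta <- st$mean[st$group == "different" & st$parameter == "theta"]
  expect_equal(diffTheta, mean(c(2, 4)), tolerance = 1e-12)
  expect_identical(g$nSame + g$nDiff, 5L)
  # identical predictions: the different group is empty
  gSame <- agreementGroups(predsA, predsA, truths, paramsA)
  expect_identical(gSame$nDiff, 0L)
  expect_identical(gSame$nSame, 5L)
  expect_error(agreementGroups(predsA, predsB[1:3], truths, paramsA),
               "misaligned")
})

test_that("per-student AR(1) estimation is calibrated", {
  # simulated AR(1) with coefficient 0.8: the 95% interval covers it in
  # most replicates
  set.seed(41)
  cover <- 0
  nRep <- 60
  for (r in seq_len(nRep)) {
    n <- 200
    x <- numeric(n)
    for (t in 2:n) x[t] <- 0.8 * x[t - 1] + rnorm(1)
    df <- data.frame(student = 0L, order = 1:n, phi = x)
    fit <- ar1PerStudent(df)
    if (fit$lower <= 0.8 && 0.8 <= fit$upper) cover <- cover + 1
  }
  expect_gte(cover / nRep, 0.9)
  # independent noise: the coefficient is rarely significant
  set.seed(43)
  sig <- 0
  for (r in seq_len(nRep)) {
    df <- data.frame(student = 0L, order = 1:150, phi = rnorm(150))
    if (ar1PerStudent(df)$pValue < 0.05) sig <- sig + 1
  }
  expect_lte(sig / nRep, 0.15)
  # degenerate constant series
  expect_error(ar1PerStudent(data.frame(student = 0L, order = 1:3,
                                        phi = rep(1, 3))), "constant")
  expect_error(ar1PerStudent(data.frame(student = 0L, order = 1:2,
                                        phi = c(1, 2))), "shorter")
})

test_that("cross-validation reports are coherent", {
  gen <- smallDataset(seed = 10L, nStudents = 6L, nItems = 12L)
  rep <- runCV(gen$data, gen$features, fastConfig(epochs = 2L), k = 3L)
  fm <- foldMetrics(rep)
  expect_identical(nrow(fm), 3L)
  expect_true(all(fm$testAccuracy >= 0 & fm$testAccuracy <= 1))
  preds <- cvPredictions(rep)
  expect_identical(nrow(preds), nrow(trials(gen$data)))
  expect_identical(preds$predicted, classifyResponse(preds$probability))
  s <- cvSummary(rep)
  expect_equal(s$mean[s$metric == "testAccuracy"], mean(fm$testAccuracy),
               tolerance = 1e-12)
  est <- averagedEntityEstimates(rep)
  expect_length(est$theta, 6L)
  expect_length(est$beta, 12L)
})
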