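test_that("the default design yields one trial per student-item pair", {
  gen <- generateDataset(generatorConfig(seed = 1L))
  tr <- trials(gen$data)
  expect_identical(nrow(tr), 1000L)
  expect_identical(nStudents(gen$data), 20L)
  expect_identical(nItems(gen$data), 50L)
  expect_identical(anyDuplicated(tr[, c("student", "item")]), 0L)
  expect_length(gen$truth$theta, 20L)
  expect_length(gen$truth$beta, 50L)
  expect_length(gen$truth$phi, 1000L)
  expect_equal(sqrt(sum(gen$truth$u^2)), 1, tolerance = 1e-12)
  # every trial resolves to a feature sequence of the recorded length
  lens <- vapply(tr$featureRef,
                 function(r) nrow(getSequence(gen$features, r)), 0L)
  expect_equal(unname(lens) * 1.07, tr$responseTime, tolerance = 1e-9)
})

test_that("generation follows the stated distributions", {
  # all-zero SDs: every probability is one half; the positive fraction
  # stays within 3 binomial SDs of 0.5
  gen0 <- generateDataset(generatorConfig(thetaSd = 0, betaSd = 0,
                                          phiSd = 0, seed = 3L))
  rate <- mean(trials(gen0$data)$response)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 1000))
  # empirical correct-rate tracks the mean generating probability
  gen <- generateDataset(generatorConfig(seed = 5L))
  tr <- trials(gen$data)
  p <- probCorrect(gen$truth$theta[tr$student + 1L],
                   gen$truth$beta[tr$item + 1L], gen$truth$phi)
  expect_lt(abs(mean(tr$response) - mean(p)),
            3 * sqrt(sum(p * (1 - p))) / 1000)
  # ground-truth phi is centred
  expect_lt(abs(mean(gen$truth$phi)), 3 * 0.75 / sqrt(1000))
})

test_that("sequence lengths follow the clipped discretized normal", {
  cfg <- generatorConfig(seed = 9L)
  lens <- generateLengths(cfg, n = 5000L)
  expect_true(all(lens >= 2L & lens <= 56L))
  # with clipping disabled, the sample mean matches the stated location
  raw <- generateLengths(generatorConfig(seed = 10L), n = 1e5L,
                         clip = FALSE)
  expect_lt(abs(mean(raw) - 23.10), 0.5)
  expect_identical(generateLengths(cfg, n = 100L),
                   generateLengths(cfg, n = 100L))
})

test_that("generation is bit-reproducible and responds to the seed", {
  g1 <- generateDataset(generatorConfig(seed = 7L))
  g2 <- generateDataset(generatorConfig(seed = 7L))
  expect_identical(trials(g1$data), trials(g2$data))
  expect_identical(g1$features@sequences, g2$features@sequences)
  expect_identical(g1$truth, g2$truth)
  g3 <- generateDataset(generatorConfig(seed = 8L))
  expect_false(identical(trials(g1$data)$response,
                         trials(g3$data)$response))
})

test_that("the time ramp places the state signal late in the sequence", {
  cfg <- generatorConfig(nStudents = 4L, nItems = 10L, phiSd = 2,
                         signalToNoise = 10, seed = 12L)
  gen <- generateDataset(cfg)
  tr <- trials(gen$data)
  u <- gen$truth$u
  # projection onto u at the first clip is pure noise (ramp 0); at the last
  # clip it tracks snr * phi / phiSd
  last <- vapply(seq_len(nrow(tr)), function(i) {
    m <- getSequence(gen$features, tr$featureRef[i])
    sum(m[nrow(m), ] * u)
  }, 0)
  first <- vapply(seq_len(nrow(tr)), function(i) {
    m <- getSequence(gen$features, tr$featureRef[i])
    sum(m[1, ] * u)
  }, 0)
  expect_gt(cor(last, gen$truth$phi), 0.9)
  expect_lt(abs(cor(first, gen$truth$phi)), 0.35)
  # with the ramp off the first clip carries the signal too
  genS <- generateDataset(generatorConfig(nStudents = 4L, nItems = 10L,
                                          phiSd = 2, signalToNoise = 10,
                                          timeRamp = FALSE, seed = 12L))
  trS <- trials(genS$data)
  firstS <- vapply(seq_len(nrow(trS)), function(i) {
    m <- getSequence(genS$features, trS$featureRef[i])
    sum(m[1, ] * genS$truth$u)
  }, 0)
  expect_gt(cor(firstS, genS$truth$phi), 0.9)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(phiSd = -1), "phiSd")
  expect_error(generatorConfig(nStudents = 0), "nStudents")
  expect_error(generatorConfig(lengthMin = 10L, lengthMax = 5L),
               "lengthMin")
  expect_error(generatorConfig(clipDuration = 0), "clipDuration")
})
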