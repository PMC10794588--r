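test_that("padBatch zero-pads to the batch maximum and keeps lengths", {
  s1 <- matrix(1, 2, 3)
  s2 <- matrix(2, 4, 3)
  b <- padBatch(list(s1, s2))
  expect_identical(b$validLengths, c(2L, 4L))
  expect_identical(b$Tmax, 4L)
  # padded rows of the shorter sequence are all zero
  rows <- 1 + 2 * (2:3)  # sequence 1 (b = 1), t = 2, 3 (0-based)
  expect_true(all(b$values[rows, ] == 0))
  # valid rows carry the original values
  expect_identical(b$values[1 + 2 * (0:1), ], s1)
  expect_identical(b$values[2 + 2 * (0:3), ], s2)
  # equal lengths: nothing changes
  be <- padBatch(list(s2, s2))
  expect_identical(be$Tmax, 4L)
  expect_identical(be$values[1 + 2 * (0:3), ], s2)
  expect_error(padBatch(list(s1, matrix(0, 2, 2))), "mixed")
  expect_error(padBatch(list()), "non-empty")
})

test_that("temporal read-out is causal and padding-invariant", {
  ns <- asNamespace("sadirt")
  cfg <- tcnConfig(channels = c(5L, 5L), dilations = c(1L, 8L), dropout = 0)
  set.seed(42)
  tcn <- ns$buildTcn(3L, cfg)
  set.seed(9)
  seqA <- matrix(rnorm(12 * 3), 12, 3)
  seqB <- matrix(rnorm(30 * 3), 30, 3)
  # same sequence padded to Tmax 12 vs Tmax 30: identical representation
  r1 <- temporalForward(tcn, padBatch(list(seqA, seqA[1:12, ])))
  r2 <- temporalForward(tcn, padBatch(list(seqA, seqB)))
  expect_equal(r1[1, ], r2[1, ], tolerance = 1e-12)
  # modifying a padded (invalid) row leaves the representation unchanged
  b <- padBatch(list(seqA, seqB))
  bMod <- b
  bMod$values[1 + 2 * 20, ] <- 99  # sequence 1, t = 20 (> valid length 12)
  expect_identical(temporalForward(tcn, b)[1, ],
                   temporalForward(tcn, bMod)[1, ])
  # all-zero weights give a zero representation
  zeroTcn <- tcn
  for (i in seq_along(zeroTcn$blocks))
    zeroTcn$blocks[[i]]$par <- lapply(zeroTcn$blocks[[i]]$par,
                                      function(p) p * 0)
  expect_true(all(temporalForward(zeroTcn, b) == 0))
})

test_that("state head is tanh-bounded and monotone in its pre-activation", {
  ns <- asNamespace("sadirt")
  set.seed(5)
  head <- ns$buildStateHead(4L)
  X <- matrix(rnorm(40), 10, 4)
  s <- stateHeadForward(head, X)
  expect_true(all(abs(s) < 1))
  # all-zero weights give exactly zero
  zeroHead <- list(layers = list(
    list(type = "linear", par = list(W = matrix(0, 4, 1), b = 0)),
    list(type = "tanh")))
  expect_identical(stateHeadForward(zeroHead, X), rep(0, 10))
  # monotone: scale a single representation along the weight direction
  w1 <- head$layers[[1]]$par$W
  lift <- seq(-2, 2, length.out = 9)
  out <- stateHeadForward(head, outer(lift, drop(w1)))
  expect_true(all(diff(out) > 0))
})

test_that("standardize-and-weight pins the batch mean at 0 and SD at |w|", {
  # frozen oracle: s = (1, 2, 3), w = 2; population SD = sqrt(2/3)
  r <- standardizeAndWeight(c(1, 2, 3), 2, mode = "training")
  expect_equal(r$phi, c(-2.4495, 0, 2.4495), tolerance = 1e-4)
  expect_equal(mean(r$phi), 0, tolerance = 1e-12)
  # w = 0 annihilates the state
  r0 <- standardizeAndWeight(c(1, 2, 3), 0, mode = "training")
  expect_identical(r0$phi, c(0, 0, 0))
  # property: every non-degenerate batch has mean 0, SD |w|
  set.seed(13)
  for (rep in 1:20) {
    s <- rnorm(sample(2:50, 1))
    w <- rnorm(1)
    ph <- standardizeAndWeight(s, w, mode = "training")$phi
    expect_equal(mean(ph), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean((ph - mean(ph))^2)), abs(w), tolerance = 1e-8)
  }
  # evaluation mode uses the running statistics
  rs <- list(mean = 1, var = 4)
  pe <- standardizeAndWeight(c(3, 1), 2, mode = "evaluation",
                             runningStats = rs)
  expect_equal(pe$phi, 2 * (c(3, 1) - 1) / sqrt(4 + 1e-5), tolerance = 1e-9)
  expect_error(standardizeAndWeight(rep(1, 5), 1, mode = "training"),
               "degenerate")
  expect_error(standardizeAndWeight(1, 1, mode = "training"), "at least 2")
})

test_that("regressState composes the stages and is permutation-equivariant", {
  gen <- smallDataset(seed = 4L)
  cfg <- fastConfig(epochs = 2L)
  model <- trainModel(gen$data, gen$features, cfg)
  refs <- trials(gen$data)$featureRef[1:10]
  phi <- regressState(gen$features, model, refs = refs)
  expect_length(phi, 10L)
  # permuting the batch permutes phi identically (evaluation mode)
  perm <- c(3, 1, 2, 10, 4:9)
  expect_equal(regressState(gen$features, model, refs = refs[perm]),
               phi[perm], tolerance = 1e-12)
  # duplicated sequences give identical estimates
  phiDup <- regressState(gen$features, model, refs = rep(refs[1], 3))
  expect_true(all(phiDup == phiDup[1]))
  # w frozen at zero kills the state exactly
  m0 <- model
  m0@params$state$par$w <- 0
  expect_identical(regressState(gen$features, m0, refs = refs), rep(0, 10))
})
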