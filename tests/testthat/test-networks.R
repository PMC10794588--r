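test_that("oneHot encodes indices and validates the range", {
  expect_identical(drop(oneHot(4, 5)), c(0, 0, 0, 0, 1))
  expect_identical(drop(oneHot(0, 3)), c(1, 0, 0))
  expect_error(oneHot(3, 3), "range")
  expect_error(oneHot(-1, 3), "range")
  X <- oneHot(c(2, 0, 2), 4)
  expect_identical(rowSums(X), c(1, 1, 1))
  expect_identical(which(X[1, ] == 1), 3L)
})

test_that("entity networks are deterministic and index-independent in
          evaluation mode", {
  ns <- asNamespace("sadirt")
  set.seed(3)
  net <- ns$buildEntityNet(6L, hidden = 10L, batchNorm = TRUE)
  a <- entityNetworkForward(net, 0:5, 6L)
  b <- entityNetworkForward(net, 0:5, 6L)
  expect_identical(a, b)
  # batch composition must not change an entity's estimate
  single <- vapply(0:5, function(j) entityNetworkForward(net, j, 6L), 0)
  expect_equal(unname(a), unname(single), tolerance = 1e-14)
  # single linear layer with known weights: output for index j is row j + 1
  lin <- list(layers = list(list(type = "linear",
                                 par = list(W = matrix(1:6 / 7, 6, 1),
                                            b = 0))))
  expect_equal(entityNetworkForward(lin, c(2, 5), 6L), c(3, 6) / 7,
               tolerance = 1e-14)
  # all-zero weights give zero for every index
  zero <- list(layers = list(list(type = "linear",
                                  par = list(W = matrix(0, 6, 1), b = 0))))
  expect_identical(entityNetworkForward(zero, 0:5, 6L), rep(0, 6))
})

test_that("baseIrtForward looks up scalar parameters", {
  tab <- list(theta = c(1, 2), beta = c(0.5, -0.5, 0))
  est <- baseIrtForward(tab, 1, 2)
  expect_identical(est$theta, 2)
  expect_identical(est$beta, 0)
  expect_error(baseIrtForward(tab, 2, 0), "range")
  # freshly initialized tables give probability one half
  zeros <- list(theta = rep(0, 2), beta = rep(0, 3))
  z <- baseIrtForward(zeros, 0, 0)
  expect_identical(probCorrect(z$theta, z$beta), 0.5)
})

test_that("base IRT gradient has the analytic sign and magnitude", {
  ns <- asNamespace("sadirt")
  # single trial with y = 1: d(-loglik)/dtheta = -(y - p); theta must rise
  # and beta fall after one optimizer step
  params <- list(table = list(par = list(theta = c(0, 0), beta = c(0, 0))))
  st <- ns$batchStep(params, "base_irt", c(0L, 0L), c(1L, 1L), c(1L, 1L),
                     NULL, NULL, 2L, 2L)
  expect_equal(st$grads$table$par$theta[1], 2 * -(1 - 0.5),
               tolerance = 1e-12)
  expect_equal(st$grads$table$par$beta[2], 2 * (1 - 0.5), tolerance = 1e-12)
  # finite-difference agreement on a random configuration
  set.seed(21)
  params <- list(table = list(par = list(theta = rnorm(3), beta = rnorm(4))))
  sIdx <- c(0L, 1L, 2L, 1L); iIdx <- c(0L, 1L, 2L, 3L); y <- c(1L, 0L, 1L, 1L)
  st <- ns$batchStep(params, "base_irt", sIdx, iIdx, y, NULL, NULL, 3L, 4L)
  h <- 1e-6
  for (j in 1:3) {
    pp <- params; pp$table$par$theta[j] <- pp$table$par$theta[j] + h
    lp <- ns$batchStep(pp, "base_irt", sIdx, iIdx, y, NULL, NULL, 3L, 4L)$loss
    pm <- params; pm$table$par$theta[j] <- pm$table$par$theta[j] - h
    lm <- ns$batchStep(pm, "base_irt", sIdx, iIdx, y, NULL, NULL, 3L, 4L)$loss
    expect_equal(st$grads$table$par$theta[j], (lp - lm) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("summaryStatsFeatures returns max/min/mean/population SD per
          dimension", {
  # constant sequence
  m <- matrix(3, 4, 2)
  expect_identical(summaryStatsFeatures(m), c(3, 3, 3, 3, 3, 3, 0, 0))
  # frozen: population SD of {1, 3} is 1
  expect_identical(summaryStatsFeatures(matrix(c(1, 3), 2, 1)),
                   c(3, 1, 2, 1))
  # degenerate single row
  expect_identical(summaryStatsFeatures(matrix(5, 1, 1)), c(5, 5, 5, 0))
  expect_error(summaryStatsFeatures(matrix(0, 0, 3)), "empty")
})

test_that("baseline MLP forward matches a hand-computed pass", {
  # all-zero weights: sigma(0) = 0.5
  zero <- list(layers = list(
    list(type = "linear", par = list(W = matrix(0, 4, 3), b = rep(0, 3))),
    list(type = "relu"),
    list(type = "linear", par = list(W = matrix(0, 3, 1), b = 0))))
  expect_identical(baselineMlpForward(zero, rep(1, 4)), 0.5)
  # hand-sized network, written-out weights
  W1 <- matrix(c(1, -1, 0.5, 2), 2, 2); b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1, 1), 2, 1); b2 <- 0.3
  net <- list(layers = list(
    list(type = "linear", par = list(W = W1, b = b1)), list(type = "relu"),
    list(type = "linear", par = list(W = W2, b = b2))))
  x <- c(0.4, -0.3)
  h <- pmax(drop(x %*% W1) + b1, 0)
  expect_equal(baselineMlpForward(net, x), sigmoid(sum(h) + 0.3),
               tolerance = 1e-14)
  # all-negative pre-activations: output depends only on the final bias
  xneg <- c(-5, 0)  # pre-activations (-5+0.1, -2.5-0.2) both negative
  expect_equal(baselineMlpForward(net, xneg), sigmoid(0.3),
               tolerance = 1e-14)
})
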