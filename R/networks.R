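# Index-to-parameter entity networks (Deep-IRT), the scalar-parameter
# Base IRT table, and the summary-statistics feature baseline.

#' One-hot encoding of an entity index
#'
#' @param index 0-based entity index (or vector of indices).
#' @param nEntities Number of entities; the encoding length.
#' @return A binary matrix with one row per index and a single 1 per row.
#' @examples
#' oneHot(4, 5)   # fifth of five students
#' @export
oneHot <- function(index, nEntities) {
  nEntities <- assertCount(nEntities, "nEntities")
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0L) || any(index >= nEntities))
    stop("index out of range [0, nEntities)", call. = FALSE)
  X <- matrix(0, length(index), nEntities)
  X[cbind(seq_along(index), index + 1L)] <- 1
  X
}

# Build a student/item network. The batch-norm variant is
# one-hot -> linear(h) -> BN -> tanh -> linear(h) -> BN -> tanh -> linear(1);
# without batch norm the BN layers are dropped. Draws its weights from the
# current RNG stream.
buildEntityNet <- function(nEntities, hidden = 50L, batchNorm = TRUE) {
  layers <- list(initLinear(nEntities, hidden))
  if (batchNorm) layers <- c(layers, list(initBN(hidden)))
  layers <- c(layers, list(list(type = "tanh")),
              list(initLinear(hidden, hidden)))
  if (batchNorm) layers <- c(layers, list(initBN(hidden)))
  layers <- c(layers, list(list(type = "tanh")),
              list(initLinear(hidden, 1L)))
  list(layers = layers)
}

#' Forward pass of a student/item network
#'
#' Maps 0-based entity indices to scalar parameter estimates (ability
#' \eqn{\theta} for the student network, difficulty \eqn{\beta} for the item
#' network) through the network's one-hot input. In evaluation mode
#' (\code{training = FALSE}) batch-norm layers use their running statistics,
#' so the estimate for an entity does not depend on the rest of the batch.
#'
#' @param net An entity network (as stored in a fitted model's
#'   \code{params$student} / \code{params$item}).
#' @param indices 0-based entity indices.
#' @param nEntities One-hot length (entity count the net was built for).
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return Numeric vector of parameter estimates, one per index.
#' @export
entityNetworkForward <- function(net, indices, nEntities, training = FALSE) {
  X <- oneHot(indices, nEntities)
  drop(mlpForward(net, X, training = training)$out)
}

#' Scalar-parameter Base IRT lookup
#'
#' The Base IRT model has no networks: each student ability and item
#' difficulty is a directly learnable scalar.
#'
#' @param table List with numeric vectors \code{theta} (per student) and
#'   \code{beta} (per item).
#' @param studentIndex,itemIndex 0-based indices.
#' @return List with elements \code{theta} and \code{beta}.
#' @export
baseIrtForward <- function(table, studentIndex, itemIndex) {
  studentIndex <- as.integer(studentIndex)
  itemIndex <- as.integer(itemIndex)
  if (any(studentIndex < 0L) || any(studentIndex >= length(table$theta)) ||
      any(itemIndex < 0L) || any(itemIndex >= length(table$beta)))
    stop("index out of range", call. = FALSE)
  list(theta = table$theta[studentIndex + 1L],
       beta = table$beta[itemIndex + 1L])
}

#' Per-dimension summary statistics of a feature sequence
#'
#' Collapses a T x D sequence into a fixed-length vector of per-dimension
#' maximum, minimum, mean and population SD, concatenated in that order:
#' \code{c(max_1..max_D, min_1..min_D, mean_1..mean_D, sd_1..sd_D)}.
#'
#' @param sequence Numeric T x D matrix with T >= 1.
#' @return Numeric vector of length 4 * D.
#' @export
summaryStatsFeatures <- function(sequence) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1L) stop("empty sequence", call. = FALSE)
  c(apply(sequence, 2L, max), apply(sequence, 2L, min),
    colMeans(sequence), apply(sequence, 2L, popSD))
}

# Build the two-hidden-layer feature baseline:
# input -> linear(h) -> relu -> linear(h) -> relu -> linear(1), sigmoid head.
buildBaselineMlp <- function(inputDim, hidden = 100L) {
  list(layers = list(initLinear(inputDim, hidden), list(type = "relu"),
                     initLinear(hidden, hidden), list(type = "relu"),
                     initLinear(hidden, 1L)))
}

#' Forward pass of the summary-statistics feature baseline
#'
#' A two-hidden-layer rectified-linear network over per-sequence summary
#' statistics, ending in a scalar logit passed through the sigmoid.
#'
#' @param net Baseline network (from a fitted \code{feature_baseline} model).
#' @param features Numeric matrix (rows = trials) or vector of summary
#'   statistics.
#' @return Vector of predicted probabilities of a correct response.
#' @export
baselineMlpForward <- function(net, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  sigmoid(drop(mlpForward(net, features, training = FALSE)$out))
}
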