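# The deep state regressor: variable-length feature sequences -> causal
# dilated temporal convolutions -> read-out at the last valid clip ->
# linear/batch-norm/tanh scalar head -> standardize-and-weight -> phi.

#' Default temporal-extractor configuration
#'
#' A compact causal TCN sized for desk-scale response datasets (hundreds to
#' a few thousand trials): residual blocks of two dilated convolutions each,
#' kernel 3, dilations doubling per block. The receptive field,
#' \eqn{1 + 2(k-1)\sum_b d_b}, must cover the longest expected sequence
#' (56 clips with the defaults: field 61).
#'
#' @param channels Output channels per residual block. The default is
#'   deliberately narrow: the state score is a single scalar per trial, and
#'   at desk scale (hundreds to a few thousand trials) a wider extractor
#'   mostly memorizes per-trial noise.
#' @param kernelSize Convolution kernel size (>= 2).
#' @param dilations Dilation per block; the default (1, 14) gives a local
#'   block plus one spanning the 56-clip horizon (receptive field 61).
#' @param dropout Dropout rate applied after each in-block activation
#'   during training. The high default is part of the same small-data
#'   regularization budget.
#' @return List describing the extractor; its \code{receptiveField} entry is
#'   derived from the other fields.
#' @export
tcnConfig <- function(channels = c(4L, 4L), kernelSize = 3L,
                      dilations = if (length(channels) == 2L) c(1L, 14L)
                                  else 4L^(seq_along(channels) - 1L),
                      dropout = 0.5) {
  kernelSize <- assertCount(kernelSize, "kernelSize", min = 2L)
  if (length(dilations) != length(channels))
    stop("'dilations' must have one entry per block", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("'dropout' must be in [0, 1)", call. = FALSE)
  list(channels = as.integer(channels), kernelSize = kernelSize,
       dilations = as.integer(dilations), dropout = dropout,
       receptiveField = 1L +
         as.integer((kernelSize - 1L) * 2L * sum(dilations)))
}

#' Zero-pad a collection of feature sequences into one batch
#'
#' Right-pads every T x D sequence with all-zero rows up to the batch
#' maximum length. The batch is stored as a single (B * Tmax) x D matrix
#' whose row index is \code{b + B * t} (0-based sequence b, time t), the
#' layout consumed by the temporal extractor.
#'
#' @param sequences Non-empty list of numeric T x D matrices with a common D.
#' @return List with \code{values} ((B*Tmax) x D matrix),
#'   \code{validLengths}, \code{B}, \code{Tmax} and \code{D}.
#' @export
padBatch <- function(sequences) {
  if (!is.list(sequences) || length(sequences) == 0L)
    stop("'sequences' must be a non-empty list", call. = FALSE)
  B <- length(sequences)
  lens <- vapply(sequences, nrow, 0L)
  if (any(lens < 1L)) stop("sequences must have at least one row",
                           call. = FALSE)
  dims <- vapply(sequences, ncol, 0L)
  if (length(unique(dims)) != 1L)
    stop("sequences have mixed feature dimensions", call. = FALSE)
  D <- dims[1L]
  Tmax <- max(lens)
  M <- matrix(0, B * Tmax, D)
  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(lens[b]) - 1L)
    M[rows, ] <- sequences[[b]]
  }
  list(values = M, validLengths = as.integer(lens), B = B,
       Tmax = as.integer(Tmax), D = D)
}

# Build the TCN parameter tree. Weights come from the current RNG stream.
buildTcn <- function(inputDim, config) {
  k <- config$kernelSize
  blocks <- vector("list", length(config$channels))
  cin <- inputDim
  for (bi in seq_along(config$channels)) {
    cout <- config$channels[bi]
    bound1 <- 1 / sqrt(k * cin)
    bound2 <- 1 / sqrt(k * cout)
    par <- list(
      W1 = matrix(stats::runif(k * cin * cout, -bound1, bound1),
                  k * cin, cout),
      b1 = stats::runif(cout, -bound1, bound1),
      W2 = matrix(stats::runif(k * cout * cout, -bound2, bound2),
                  k * cout, cout),
      b2 = stats::runif(cout, -bound2, bound2))
    if (cin != cout) {
      boundD <- 1 / sqrt(cin)
      par$Wd <- matrix(stats::runif(cin * cout, -boundD, boundD), cin, cout)
      par$bd <- stats::runif(cout, -boundD, boundD)
    }
    blocks[[bi]] <- list(par = par, dilation = config$dilations[bi])
    cin <- cout
  }
  list(blocks = blocks, config = config)
}

# Forward through the TCN stack on a padded batch matrix M ((B*T) x D).
# Causality guarantees that the output at a valid time index never depends
# on padded (later) rows. Each residual block runs as one fused compiled
# call; dropout draws come from R's RNG stream, so runs are seeded.
tcnStackForward <- function(tcn, M, B, T, training = FALSE) {
  caches <- vector("list", length(tcn$blocks))
  rate <- tcn$config$dropout
  for (bi in seq_along(tcn$blocks)) {
    blk <- tcn$blocks[[bi]]
    p <- blk$par
    cc <- .tcnBlockForward(M, B, T, p$W1, p$b1, p$W2, p$b2, p$Wd, p$bd,
                           blk$dilation, rate, training)
    cc$M <- M
    caches[[bi]] <- cc
    M <- cc$out
  }
  list(out = M, caches = caches)
}

tcnStackBackward <- function(tcn, caches, dOut, B, T) {
  grads <- vector("list", length(tcn$blocks))
  for (bi in rev(seq_along(tcn$blocks))) {
    blk <- tcn$blocks[[bi]]
    p <- blk$par
    cc <- caches[[bi]]
    bw <- .tcnBlockBackward(cc$M, B, T, p$W1, p$W2, p$Wd, blk$dilation, cc,
                            dOut)
    grads[[bi]] <- list(par = bw$grads)
    dOut <- bw$dM
  }
  list(grads = list(blocks = grads), dX = dOut)
}

#' Temporal-extractor forward pass with masked read-out
#'
#' Runs a padded batch through the causal dilated convolution stack and
#' reads, for every sequence, the representation at its last valid clip
#' (not the padded end). Because the convolutions are causal, that read-out
#' is provably independent of how much zero padding follows the valid rows.
#'
#' @param tcn Temporal extractor (from a fitted model's
#'   \code{params$state$tcn}).
#' @param batch A padded batch from [padBatch()].
#' @param training Apply dropout (TRUE) or run deterministically.
#' @return B x H matrix of per-sequence representations.
#' @export
temporalForward <- function(tcn, batch, training = FALSE) {
  fw <- tcnStackForward(tcn, batch$values, batch$B, batch$Tmax,
                        training = training)
  idx <- seq_len(batch$B) + batch$B * (batch$validLengths - 1L)
  fw$out[idx, , drop = FALSE]
}

# Build the scalar state head: linear(H -> 1) -> BN -> tanh.
buildStateHead <- function(inputDim) {
  list(layers = list(initLinear(inputDim, 1L), initBN(1L),
                     list(type = "tanh")))
}

#' Scalar state head forward pass
#'
#' Maps a per-sequence representation to a raw state score in (-1, 1)
#' through linear, batch-norm and hyperbolic-tangent layers.
#'
#' @param head State head (from a fitted model's \code{params$state$head}).
#' @param representation H-vector or B x H matrix.
#' @param training Batch-statistics (TRUE) or running-statistics mode.
#' @return Numeric vector of raw scores, one per row.
#' @export
stateHeadForward <- function(head, representation, training = FALSE) {
  if (!is.matrix(representation))
    representation <- matrix(representation, nrow = 1L)
  drop(mlpForward(head, representation, training = training)$out)
}

.sdEps <- 1e-8

#' Standardize raw state scores and scale by the variance weight
#'
#' The output stage that pins the distribution of the state parameter
#' \eqn{\phi}: in training mode the batch of raw scores is centred and
#' divided by its population SD, then multiplied by the learnable variance
#' weight \code{w}, so every training batch of \eqn{\phi} has mean 0 and SD
#' \eqn{|w|} exactly; running statistics are updated with momentum 0.1. In
#' evaluation mode the stored running statistics are used instead
#' (\eqn{\phi = w (s - \hat\mu)/\sqrt{\hat\sigma^2 + \epsilon}}).
#'
#' @param rawScores Numeric vector of raw scalar scores.
#' @param w Variance weight.
#' @param mode \code{"training"} or \code{"evaluation"}.
#' @param runningStats List with \code{mean} and \code{var}.
#' @return List with \code{phi} and the (possibly updated)
#'   \code{runningStats}.
#' @export
standardizeAndWeight <- function(rawScores, w, mode = c("training",
                                                        "evaluation"),
                                 runningStats = list(mean = 0, var = 1)) {
  mode <- match.arg(mode)
  if (mode == "training") {
    if (length(rawScores) < 2L)
      stop("training-mode standardization needs a batch of at least 2",
           call. = FALSE)
    mu <- mean(rawScores)
    sdv <- popSD(rawScores)
    if (sdv < .sdEps)
      stop("degenerate batch: raw state scores are (near-)constant",
           call. = FALSE)
    phi <- w * (rawScores - mu) / sdv
    runningStats$mean <- (1 - .bnMomentum) * runningStats$mean +
      .bnMomentum * mu
    runningStats$var <- (1 - .bnMomentum) * runningStats$var +
      .bnMomentum * sdv^2
  } else {
    phi <- w * (rawScores - runningStats$mean) /
      sqrt(runningStats$var + .bnEps)
  }
  list(phi = phi, runningStats = runningStats)
}

#' Regress per-trial states from feature sequences
#'
#' The full state-regressor composition: zero padding, causal temporal
#' convolutions with masked read-out, the scalar head, and
#' standardize-and-weight.
#'
#' @param sequences List of T x D feature matrices, or a
#'   \linkS4class{FeatureStore} together with \code{refs}.
#' @param model A fitted \linkS4class{SadModel} of variant \code{"sad_irt"}.
#' @param mode \code{"evaluation"} (running statistics; default) or
#'   \code{"training"} (batch statistics; does not update the model).
#' @param refs Feature references, when \code{sequences} is a store.
#' @return Numeric vector of per-trial state estimates \eqn{\phi}.
#' @export
regressState <- function(sequences, model, mode = "evaluation", refs = NULL) {
  if (is(sequences, "FeatureStore")) {
    if (is.null(refs)) stop("'refs' required with a FeatureStore",
                            call. = FALSE)
    sequences <- lapply(refs, function(r) getSequence(sequences, r))
  }
  state <- model@params$state
  if (is.null(state))
    stop("model variant has no state regressor", call. = FALSE)
  batch <- padBatch(sequences)
  rep <- temporalForward(state$tcn, batch, training = FALSE)
  s <- stateHeadForward(state$head, rep, training = (mode == "training"))
  standardizeAndWeight(s, state$par$w, mode = mode,
                       runningStats = state$runningStats)$phi
}
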