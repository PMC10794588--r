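# Joint gradient-descent training of the entity networks and the state
# regressor against the summed cross-entropy objective.

#' Training configuration
#'
#' @param variant Model variant: \code{"sad_irt"} (entity networks plus the
#'   deep state regressor), \code{"deep_irt"} (batch-norm entity networks),
#'   \code{"deep_irt_no_bn"}, \code{"base_irt"} (directly learnable scalar
#'   parameters), or \code{"feature_baseline"} (summary-statistics MLP over
#'   features only).
#' @param learningRate Adam learning rate.
#' @param batchSize Mini-batch size (>= 2; batch normalization and the
#'   standardize-and-weight stage need batch statistics).
#' @param epochs Number of passes over the shuffled training data; training
#'   always runs the configured number of epochs (no early stopping).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param entityHidden Hidden width of the student/item networks.
#' @param baselineHidden Hidden width of the feature baseline.
#' @param tcn Temporal-extractor configuration, see [tcnConfig()].
#' @param wInit Initial value of the variance weight w.
#' @param freezeW Keep w fixed at \code{wInit} during training. With
#'   \code{wInit = 0} this makes the state-aware model collapse exactly onto
#'   Deep-IRT.
#' @param statePriorSd SD of the zero-mean normal prior assumed for the
#'   state parameter phi. Because the standardize-and-weight stage pins the
#'   batch SD of phi at |w|, the prior's penalty gradient reduces exactly to
#'   weight decay on w; it keeps the state path gated when the features
#'   carry no usable signal. \code{Inf} disables the prior.
#' @return Resolved configuration list.
#' @export
trainConfig <- function(variant = c("sad_irt", "deep_irt", "deep_irt_no_bn",
                                    "base_irt", "feature_baseline"),
                        learningRate = 1e-3, batchSize = 64L, epochs = 200L,
                        seed = 0L, entityHidden = 50L, baselineHidden = 100L,
                        tcn = tcnConfig(), wInit = 1, freezeW = FALSE,
                        statePriorSd = 1) {
  if (is.list(tcn) && is.null(tcn$receptiveField))
    tcn <- do.call(tcnConfig, tcn)
  if (!(is.numeric(statePriorSd) && length(statePriorSd) == 1L &&
        !is.na(statePriorSd) && statePriorSd > 0))
    stop("'statePriorSd' must be a positive number (Inf to disable)",
         call. = FALSE)
  list(variant = match.arg(variant),
       learningRate = assertNumber(learningRate, "learningRate", 0,
                                   strict = TRUE),
       batchSize = assertCount(batchSize, "batchSize", min = 2L),
       epochs = assertCount(epochs, "epochs"),
       seed = assertCount(seed, "seed", min = 0L),
       entityHidden = assertCount(entityHidden, "entityHidden"),
       baselineHidden = assertCount(baselineHidden, "baselineHidden"),
       tcn = tcn,
       wInit = assertNumber(wInit, "wInit"),
       freezeW = assertFlag(freezeW, "freezeW"),
       statePriorSd = as.double(statePriorSd))
}

usesEntityNets <- function(variant)
  variant %in% c("sad_irt", "deep_irt", "deep_irt_no_bn")

usesFeatures <- function(variant)
  variant %in% c("sad_irt", "feature_baseline")

# Initialize the parameter tree for a variant. Every component draws its
# weights from its own seeded RNG stream, so shared seeds give identical
# entity networks across variants that share them.
initModel <- function(config, nStudents, nItems, featureDim = NULL) {
  params <- list()
  if (usesEntityNets(config$variant)) {
    bn <- config$variant != "deep_irt_no_bn"
    set.seed(subSeed(config$seed, 1))
    params$student <- buildEntityNet(nStudents, config$entityHidden, bn)
    set.seed(subSeed(config$seed, 2))
    params$item <- buildEntityNet(nItems, config$entityHidden, bn)
  }
  if (config$variant == "sad_irt") {
    set.seed(subSeed(config$seed, 3))
    tcn <- buildTcn(featureDim, config$tcn)
    H <- config$tcn$channels[length(config$tcn$channels)]
    head <- buildStateHead(H)
    params$state <- list(tcn = tcn, head = head,
                         par = list(w = config$wInit),
                         runningStats = list(mean = 0, var = 1))
  }
  if (config$variant == "base_irt")
    params$table <- list(par = list(theta = rep(0, nStudents),
                                    beta = rep(0, nItems)))
  if (config$variant == "feature_baseline") {
    set.seed(subSeed(config$seed, 4))
    params$baseline <- buildBaselineMlp(4L * featureDim,
                                        config$baselineHidden)
  }
  params
}

# Split a permutation into mini-batches; a trailing singleton is merged into
# the previous batch because batch statistics need n >= 2.
batchIndices <- function(perm, batchSize) {
  n <- length(perm)
  starts <- seq.int(1L, n, by = batchSize)
  batches <- lapply(starts, function(s) perm[s:min(s + batchSize - 1L, n)])
  nb <- length(batches)
  if (nb > 1L && length(batches[[nb]]) == 1L) {
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

# One forward/backward pass on a mini-batch. Returns loss, gradient tree
# (aligned with the parameter tree) and params with updated normalization
# buffers.
batchStep <- function(params, variant, sIdx, iIdx, y, seqs, feats,
                      nStudents, nItems, statePriorSd = Inf) {
  grads <- list()
  if (usesEntityNets(variant)) {
    fwS <- mlpForward(params$student, oneHot(sIdx, nStudents),
                      training = TRUE)
    fwI <- mlpForward(params$item, oneHot(iIdx, nItems), training = TRUE)
    params$student <- fwS$net
    params$item <- fwI$net
    theta <- drop(fwS$out)
    beta <- drop(fwI$out)
    if (variant == "sad_irt") {
      batch <- padBatch(seqs)
      tcnFw <- tcnStackForward(params$state$tcn, batch$values, batch$B,
                               batch$Tmax, training = TRUE)
      idx <- seq_len(batch$B) + batch$B * (batch$validLengths - 1L)
      rep <- tcnFw$out[idx, , drop = FALSE]
      headFw <- mlpForward(params$state$head, rep, training = TRUE)
      params$state$head <- headFw$net
      s <- drop(headFw$out)
      mu <- mean(s)
      sdv <- popSD(s)
      if (sdv < .sdEps)
        stop("degenerate batch: raw state scores are (near-)constant",
             call. = FALSE)
      z <- (s - mu) / sdv
      w <- params$state$par$w
      phi <- w * z
      rs <- params$state$runningStats
      rs$mean <- (1 - .bnMomentum) * rs$mean + .bnMomentum * mu
      rs$var <- (1 - .bnMomentum) * rs$var + .bnMomentum * sdv^2
      params$state$runningStats <- rs
    } else {
      phi <- 0
    }
    p <- sigmoid(theta - beta - phi)
    loss <- crossEntropyLoss(y, p)
    dlogit <- p - y
    bwS <- mlpBackward(params$student, fwS$caches, cbind(dlogit))
    bwI <- mlpBackward(params$item, fwI$caches, cbind(-dlogit))
    grads$student <- list(layers = bwS$grads)
    grads$item <- list(layers = bwI$grads)
    if (variant == "sad_irt") {
      dphi <- -dlogit
      dw <- sum(dphi * z)
      # Gaussian prior phi ~ N(0, statePriorSd^2): its penalty gradient
      # into the raw scores vanishes under batch standardization (the
      # centering/scale projections absorb it exactly), leaving only
      # weight decay on w: d/dw [sum(phi^2) / (2 sd^2)] = B w / sd^2.
      if (is.finite(statePriorSd))
        dw <- dw + length(z) * w / statePriorSd^2
      ds <- (w / sdv) * (dphi - mean(dphi) - z * mean(dphi * z))
      bwH <- mlpBackward(params$state$head, headFw$caches, cbind(ds))
      dY <- matrix(0, nrow(tcnFw$out), ncol(tcnFw$out))
      dY[idx, ] <- bwH$dX
      bwT <- tcnStackBackward(params$state$tcn, tcnFw$caches, dY,
                              batch$B, batch$Tmax)
      grads$state <- list(tcn = bwT$grads, head = list(layers = bwH$grads),
                          par = list(w = dw))
    }
  } else if (variant == "base_irt") {
    tab <- params$table$par
    theta <- tab$theta[sIdx + 1L]
    beta <- tab$beta[iIdx + 1L]
    p <- sigmoid(theta - beta)
    loss <- crossEntropyLoss(y, p)
    dlogit <- p - y
    gt <- rep(0, length(tab$theta))
    gb <- rep(0, length(tab$beta))
    rs <- rowsum(dlogit, sIdx)
    gt[as.integer(rownames(rs)) + 1L] <- rs
    ri <- rowsum(-dlogit, iIdx)
    gb[as.integer(rownames(ri)) + 1L] <- ri
    grads$table <- list(par = list(theta = gt, beta = gb))
  } else { # feature_baseline
    fw <- mlpForward(params$baseline, feats, training = TRUE)
    params$baseline <- fw$net
    p <- sigmoid(drop(fw$out))
    loss <- crossEntropyLoss(y, p)
    dlogit <- p - y
    bw <- mlpBackward(params$baseline, fw$caches, cbind(dlogit))
    grads$baseline <- list(layers = bw$grads)
  }
  list(loss = loss, grads = grads, params = params)
}

#' Train a model
#'
#' Joint mini-batch gradient descent of all model components against the
#' summed cross-entropy objective, with the Adam optimizer
#' (\eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999}, \eqn{\epsilon = 10^{-8}}).
#' Each epoch reshuffles the trials (seeded); the run is fully reproducible
#' given the configuration seed.
#'
#' @param data A \linkS4class{ResponseData}.
#' @param features A \linkS4class{FeatureStore}; required for the
#'   state-aware and feature-baseline variants.
#' @param config A [trainConfig()].
#' @return A fitted \linkS4class{SadModel}.
#' @export
trainModel <- function(data, features = NULL, config = trainConfig()) {
  stopifnot(is(data, "ResponseData"))
  tr <- data@trials
  n <- nrow(tr)
  if (config$batchSize > n)
    stop("batchSize exceeds the number of trials", call. = FALSE)
  variant <- config$variant
  seqs <- NULL
  featMat <- NULL
  if (usesFeatures(variant)) {
    if (is.null(features))
      stop(sprintf("variant '%s' requires a feature store", variant),
           call. = FALSE)
    missing <- setdiff(tr$featureRef, names(features@sequences))
    if (length(missing))
      stop(sprintf("missing feature sequences for %d trials (e.g. '%s')",
                   length(missing), missing[1L]), call. = FALSE)
    seqs <- features@sequences[tr$featureRef]
    if (variant == "feature_baseline")
      featMat <- t(vapply(seqs, summaryStatsFeatures,
                          numeric(4L * features@featureDim)))
  }
  params <- initModel(config, data@nStudents, data@nItems,
                      if (is.null(features)) NULL else features@featureDim)
  opt <- adamInit(params)
  batchLoss <- numeric(0)
  epochLoss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    set.seed(subSeed(config$seed, 10000 + epoch))
    batches <- batchIndices(sample.int(n), config$batchSize)
    eloss <- 0
    for (b in batches) {
      step <- batchStep(params, variant, tr$student[b], tr$item[b],
                        tr$response[b],
                        if (is.null(seqs)) NULL else seqs[b],
                        if (is.null(featMat)) NULL
                        else featMat[b, , drop = FALSE],
                        data@nStudents, data@nItems,
                        statePriorSd = config$statePriorSd)
      if (!is.finite(step$loss))
        stop(sprintf(
          "non-finite loss at epoch %d; training aborted (diverged?)",
          epoch), call. = FALSE)
      params <- step$params
      grads <- step$grads
      if (variant == "sad_irt" && config$freezeW)
        grads$state$par["w"] <- list(NULL)
      upd <- adamStep(params, grads, opt, lr = config$learningRate)
      params <- upd$par
      opt <- upd$state
      batchLoss <- c(batchLoss, step$loss)
      eloss <- eloss + step$loss
    }
    epochLoss[epoch] <- eloss / n
  }
  new("SadModel", variant = variant, params = params, config = config,
      nStudents = data@nStudents, nItems = data@nItems,
      lossHistory = epochLoss, batchLoss = batchLoss,
      seed = as.double(config$seed))
}

#' Evaluate a fitted model on a set of trials
#'
#' Runs the model in evaluation mode (running normalization statistics, no
#' dropout) and returns one prediction record per trial: the probability of
#' a correct response, the classified response, and the parameter estimates
#' that produced it.
#'
#' @param model A fitted \linkS4class{SadModel}.
#' @param data A \linkS4class{ResponseData} (or a trials data.frame with the
#'   same columns) whose entity indices lie within the model's ranges.
#' @param features Feature store; required for feature-using variants.
#' @return data.frame with columns \code{student}, \code{item},
#'   \code{response}, \code{responseTime}, \code{order}, \code{theta},
#'   \code{beta}, \code{phi}, \code{probability}, \code{predicted}.
#' @export
evaluateModel <- function(model, data, features = NULL) {
  tr <- if (is(data, "ResponseData")) data@trials else data
  variant <- model@variant
  if (any(tr$student < 0L) || any(tr$student >= model@nStudents) ||
      any(tr$item < 0L) || any(tr$item >= model@nItems))
    stop("entity index outside the model's training ranges", call. = FALSE)
  theta <- beta <- phi <- rep(NA_real_, nrow(tr))
  if (usesEntityNets(variant)) {
    theta <- entityNetworkForward(model@params$student, tr$student,
                                  model@nStudents)
    beta <- entityNetworkForward(model@params$item, tr$item, model@nItems)
    phi <- rep(0, nrow(tr))
    if (variant == "sad_irt") {
      if (is.null(features))
        stop("variant 'sad_irt' requires a feature store", call. = FALSE)
      phi <- regressState(features, model, mode = "evaluation",
                          refs = tr$featureRef)
    }
    p <- probCorrect(theta, beta, phi)
  } else if (variant == "base_irt") {
    est <- baseIrtForward(model@params$table$par, tr$student, tr$item)
    theta <- est$theta
    beta <- est$beta
    phi <- rep(0, nrow(tr))
    p <- probCorrect(theta, beta, phi)
  } else {
    if (is.null(features))
      stop("variant 'feature_baseline' requires a feature store",
           call. = FALSE)
    feats <- t(vapply(features@sequences[tr$featureRef],
                      summaryStatsFeatures,
                      numeric(4L * features@featureDim)))
    p <- baselineMlpForward(model@params$baseline, feats)
  }
  data.frame(student = tr$student, item = tr$item, response = tr$response,
             responseTime = tr$responseTime, order = tr$order,
             theta = theta, beta = beta, phi = phi, probability = p,
             predicted = classifyResponse(p), stringsAsFactors = FALSE)
}
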