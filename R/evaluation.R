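# Evaluation protocol: stratified k-fold CV, accuracy/F1, Wilcoxon fold
# comparison, early prediction by response-time quantiles, parameter
# similarity, prediction-agreement grouping, and per-student AR(1) analysis.

#' Stratified k-fold split
#'
#' Shuffles trials within each response class (seeded) and deals them out
#' so that every fold's class proportions match the global proportions to
#' within one trial.
#'
#' @param data A \linkS4class{ResponseData}, or a 0/1 response vector.
#' @param k Number of folds (>= 2).
#' @param seed Shuffling seed.
#' @return List of \code{k} folds, each a list with \code{fold},
#'   \code{train} and \code{test} (1-based trial indices).
#' @export
stratifiedKFold <- function(data, k = 20L, seed = 0L) {
  y <- if (is(data, "ResponseData")) data@trials$response else
    as.integer(data)
  k <- assertCount(k, "k", min = 2L)
  if (any(table(y) < k))
    stop("every class needs at least k members", call. = FALSE)
  set.seed(subSeed(seed, 42))
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    # deal the shuffled class members round-robin over folds
    assign[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(fold = f, train = which(assign != f), test = which(assign == f)))
}

#' Accuracy and F1 score of binary predictions
#'
#' F1 is the harmonic mean of precision and recall with the positive class
#' 1; if there are no predicted or no true positives it is defined as 0.
#'
#' @param predictions,truths Equal-length 0/1 vectors.
#' @return Named numeric vector \code{c(accuracy, f1)}.
#' @export
computeMetrics <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop("'predictions' and 'truths' must be non-empty and equal length",
         call. = FALSE)
  tp <- sum(predictions == 1 & truths == 1)
  fp <- sum(predictions == 1 & truths == 0)
  fn <- sum(predictions == 0 & truths == 1)
  accuracy <- mean(predictions == truths)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = accuracy, f1 = f1)
}

#' Paired Wilcoxon signed-rank test on per-fold scores
#'
#' Two-sided signed-rank test of the fold-wise differences between two
#' models' scores. Zero differences are discarded (classic treatment); the
#' exact null distribution is used for n <= 25 untied differences, the
#' normal approximation above that.
#'
#' @param scoresA,scoresB Equal-length numeric vectors (one entry per fold).
#' @return List with \code{statistic} (V, the positive-rank sum) and
#'   \code{pValue}.
#' @export
wilcoxonSignedRank <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("score vectors must have equal length", call. = FALSE)
  d <- scoresA - scoresB
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("degenerate input: all fold differences are zero", call. = FALSE)
  if (length(d) < 3L)
    stop("need at least 3 non-zero differences", call. = FALSE)
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  res <- stats::wilcox.test(d, exact = exact)
  list(statistic = unname(res$statistic), pValue = res$p.value)
}

#' Response-time quartiles
#'
#' Empirical first quartile, median and third quartile of the response
#' times, with linear interpolation between order statistics.
#'
#' @param data A \linkS4class{ResponseData} or a numeric vector of times.
#' @return Named vector \code{c(q1, median, q3)} in seconds.
#' @export
responseTimeQuantiles <- function(data) {
  times <- if (is(data, "ResponseData")) data@trials$responseTime else data
  if (length(times) < 1L) stop("no response times", call. = FALSE)
  q <- stats::quantile(times, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Truncate feature sequences at an early-prediction cutoff
#'
#' Keeps the first \code{max(1, floor(cutoff / clipDuration))} clips of each
#' sequence (never more than its valid length), emulating a prediction made
#' before the respondent has answered.
#'
#' @param x A T x D feature matrix or a \linkS4class{FeatureStore}.
#' @param cutoff Cutoff time in seconds (> 0).
#' @param clipDuration Seconds per clip; taken from the store when \code{x}
#'   is a \linkS4class{FeatureStore}.
#' @return Object of the same type as \code{x}, truncated.
#' @export
truncateFeatures <- function(x, cutoff, clipDuration = NULL) {
  assertNumber(cutoff, "cutoff", 0, strict = TRUE)
  if (is(x, "FeatureStore")) {
    keepN <- max(1L, as.integer(floor(cutoff / x@clipDuration)))
    x@sequences <- lapply(x@sequences, function(m)
      m[seq_len(min(keepN, nrow(m))), , drop = FALSE])
    return(x)
  }
  if (is.null(clipDuration))
    stop("'clipDuration' required for a bare matrix", call. = FALSE)
  keepN <- max(1L, as.integer(floor(cutoff / clipDuration)))
  x[seq_len(min(keepN, nrow(x))), , drop = FALSE]
}

subsetResponseData <- function(data, idx) {
  new("ResponseData", trials = data@trials[idx, , drop = FALSE],
      nStudents = data@nStudents, nItems = data@nItems,
      studentIds = data@studentIds, itemIds = data@itemIds)
}

#' Stratified k-fold cross-validation of a model variant
#'
#' Trains a fresh model per fold (all normalization statistics reset) and
#' records train/test accuracy and F1 plus the per-trial test predictions
#' with the parameter estimates behind them.
#'
#' @param data A \linkS4class{ResponseData}.
#' @param features Feature store (for feature-using variants).
#' @param config A [trainConfig()].
#' @param k Number of folds.
#' @param seed Seed for the fold split; per-fold training seeds are derived
#'   from it.
#' @return A \linkS4class{CVReport}.
#' @export
runCV <- function(data, features = NULL, config = trainConfig(), k = 20L,
                  seed = config$seed) {
  folds <- stratifiedKFold(data, k = k, seed = seed)
  foldRows <- vector("list", length(folds))
  predRows <- vector("list", length(folds))
  for (fs in folds) {
    cfg <- config
    cfg$seed <- subSeed(seed, 500 + fs$fold)
    trainData <- subsetResponseData(data, fs$train)
    model <- trainModel(trainData, features, cfg)
    evTrain <- evaluateModel(model, trainData, features)
    evTest <- evaluateModel(model, subsetResponseData(data, fs$test),
                            features)
    mTrain <- computeMetrics(evTrain$predicted, evTrain$response)
    mTest <- computeMetrics(evTest$predicted, evTest$response)
    foldRows[[fs$fold]] <- data.frame(
      fold = fs$fold, trainAccuracy = mTrain[["accuracy"]],
      trainF1 = mTrain[["f1"]], testAccuracy = mTest[["accuracy"]],
      testF1 = mTest[["f1"]])
    evTest$fold <- fs$fold
    predRows[[fs$fold]] <- evTest
  }
  new("CVReport", variant = config$variant, k = as.integer(k),
      folds = do.call(rbind, foldRows),
      predictions = do.call(rbind, predRows))
}

#' Average per-entity parameter estimates over test folds
#'
#' Entity networks estimate each student's ability and each item's
#' difficulty once per test-fold occurrence; similarity reports use the
#' per-entity averages of those estimates.
#'
#' @param predictions A \linkS4class{CVReport} or its predictions
#'   data.frame.
#' @return List with named vectors \code{theta} (by student index) and
#'   \code{beta} (by item index).
#' @export
averagedEntityEstimates <- function(predictions) {
  if (is(predictions, "CVReport")) predictions <- predictions@predictions
  theta <- tapply(predictions$theta, predictions$student, mean)
  beta <- tapply(predictions$beta, predictions$item, mean)
  list(theta = theta[order(as.integer(names(theta)))],
       beta = beta[order(as.integer(names(beta)))])
}

#' Similarity of two models' parameter estimates
#'
#' RMSE, Pearson correlation and Kendall tau-b between two models'
#' per-entity averaged ability and difficulty estimates.
#'
#' @param estimatesA,estimatesB Lists with vectors \code{theta} and
#'   \code{beta} (e.g. from [averagedEntityEstimates()]), covering the same
#'   entities in the same order.
#' @return data.frame with one row per parameter family.
#' @export
compareParameterEstimates <- function(estimatesA, estimatesB) {
  one <- function(a, b, name) {
    if (length(a) != length(b))
      stop("estimate vectors must cover the same entities", call. = FALSE)
    if (length(a) < 2L)
      stop("correlation undefined for fewer than 2 entities", call. = FALSE)
    data.frame(parameter = name,
               rmse = sqrt(mean((a - b)^2)),
               pearson = stats::cor(a, b),
               kendall = stats::cor(a, b, method = "kendall"))
  }
  rbind(one(unname(estimatesA$theta), unname(estimatesB$theta), "theta"),
        one(unname(estimatesA$beta), unname(estimatesB$beta), "beta"))
}

#' Group trials by prediction agreement between two models
#'
#' Splits trials into those where two models predict the same response and
#' those where they differ, and summarizes model A's parameter estimates
#' (mean and SD of theta, beta, phi) within each group — the grouping used
#' to inspect where the state parameter changes a prediction.
#'
#' @param predsA,predsB 0/1 predictions of the two models, aligned.
#' @param truths Observed 0/1 responses, aligned.
#' @param paramsA data.frame with columns \code{theta}, \code{beta},
#'   \code{phi} of model A's estimates, aligned.
#' @return List with group sizes \code{nSame} / \code{nDiff}, the number of
#'   trials in the different-prediction group that model A got right
#'   (\code{aCorrectInDiff}), and a \code{stats} data.frame of per-group
#'   parameter means and SDs.
#' @export
agreementGroups <- function(predsA, predsB, truths, paramsA) {
  n <- length(predsA)
  if (length(predsB) != n || length(truths) != n || nrow(paramsA) != n)
    stop("misaligned inputs", call. = FALSE)
  same <- predsA == predsB
  groupStats <- function(mask, label) {
    do.call(rbind, lapply(c("theta", "beta", "phi"), function(p)
      data.frame(group = label, parameter = p,
                 mean = mean(paramsA[[p]][mask]),
                 sd = stats::sd(paramsA[[p]][mask]))))
  }
  stats <- rbind(groupStats(rep(TRUE, n), "all"),
                 groupStats(same, "same"),
                 groupStats(!same, "different"))
  list(nSame = sum(same), nDiff = sum(!same),
       aCorrectInDiff = sum(predsA[!same] == truths[!same]),
       stats = stats)
}

#' Per-student AR(1) analysis of state estimates
#'
#' Regresses each student's state estimate \eqn{\phi_t} on its predecessor
#' \eqn{\phi_{t-1}} (trials in presentation order) by least squares and
#' reports the autoregressive coefficient with a standard-error-based 95%
#' confidence interval.
#'
#' @param predictions data.frame with columns \code{student}, \code{order}
#'   and \code{phi} (e.g. test predictions of a state-aware model).
#' @param minLength Minimum series length (default 3); shorter series error.
#' @return data.frame with one row per student: \code{student}, \code{n},
#'   \code{coefficient}, \code{se}, \code{lower}, \code{upper},
#'   \code{pValue}.
#' @export
ar1PerStudent <- function(predictions, minLength = 3L) {
  rows <- lapply(split(predictions, predictions$student), function(df) {
    df <- df[order(df$order), ]
    x <- df$phi
    n <- length(x)
    if (n < minLength)
      stop(sprintf("student %s: series shorter than %d", df$student[1L],
                   minLength), call. = FALSE)
    if (popSD(x) < .sdEps)
      stop(sprintf("student %s: constant state series", df$student[1L]),
           call. = FALSE)
    fit <- stats::lm(x[-1] ~ x[-n])
    sm <- summary(fit)$coefficients
    co <- sm[2L, 1L]
    se <- sm[2L, 2L]
    crit <- stats::qt(0.975, df = fit$df.residual)
    data.frame(student = df$student[1L], n = n, coefficient = co, se = se,
               lower = co - crit * se, upper = co + crit * se,
               pValue = sm[2L, 4L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Early-prediction performance curve
#'
#' Evaluates response prediction when only the features recorded before a
#' time cutoff are available. Cutoffs default to the single first clip, the
#' response-time quartiles, and the full recording. By default a separate
#' model is trained per cutoff on equally truncated training features;
#' \code{retrain = FALSE} instead trains once on full-length features and
#' only truncates at evaluation time.
#'
#' @param data A \linkS4class{ResponseData}.
#' @param features A \linkS4class{FeatureStore}.
#' @param config A [trainConfig()] for a feature-using variant.
#' @param cutoffs Numeric cutoffs in seconds, or \code{"auto"}.
#' @param k Cross-validation folds per cutoff.
#' @param seed Fold/split seed.
#' @param retrain Retrain per cutoff (default) or truncate at evaluation
#'   only.
#' @return data.frame with one row per cutoff: \code{cutoff},
#'   \code{meanTestAccuracy}, \code{meanTestF1}.
#' @export
earlyPredictionCurve <- function(data, features, config = trainConfig(),
                                 cutoffs = "auto", k = 20L,
                                 seed = config$seed, retrain = TRUE) {
  if (identical(cutoffs, "auto")) {
    q <- responseTimeQuantiles(data)
    cutoffs <- c(features@clipDuration, q[["q1"]], q[["median"]],
                 q[["q3"]], max(data@trials$responseTime))
  }
  fullModelReport <- NULL
  rows <- lapply(cutoffs, function(cut) {
    store <- truncateFeatures(features, cut)
    if (retrain) {
      rep <- runCV(data, store, config, k = k, seed = seed)
    } else {
      # one model per fold trained on full-length features, evaluated on
      # truncated ones
      if (is.null(fullModelReport)) {
        folds <- stratifiedKFold(data, k = k, seed = seed)
        fullModelReport <<- lapply(folds, function(fs) {
          cfg <- config
          cfg$seed <- subSeed(seed, 500 + fs$fold)
          list(fold = fs, model = trainModel(
            subsetResponseData(data, fs$train), features, cfg))
        })
      }
      foldRows <- lapply(fullModelReport, function(fm) {
        ev <- evaluateModel(fm$model, subsetResponseData(data,
                                                         fm$fold$test),
                            store)
        m <- computeMetrics(ev$predicted, ev$response)
        data.frame(testAccuracy = m[["accuracy"]], testF1 = m[["f1"]])
      })
      rep <- do.call(rbind, foldRows)
    }
    fm <- if (is(rep, "CVReport")) rep@folds else rep
    data.frame(cutoff = cut, meanTestAccuracy = mean(fm$testAccuracy),
               meanTestF1 = mean(fm$testF1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-student-out robustness loop
#'
#' Removes one student at a time and reruns the stratified cross-validation
#' on the remaining data — a thin driver used to check that the conclusions
#' do not hinge on any single participant.
#'
#' @param data A \linkS4class{ResponseData}.
#' @param features Feature store.
#' @param config A [trainConfig()].
#' @param k Folds per rerun.
#' @param students 0-based student indices to leave out (default: all).
#' @return data.frame with one row per left-out student: mean test accuracy
#'   and F1 of the rerun.
#' @export
leaveOneStudentOut <- function(data, features = NULL,
                               config = trainConfig(), k = 20L,
                               students = NULL) {
  if (is.null(students)) students <- seq_len(data@nStudents) - 1L
  rows <- lapply(students, function(s) {
    keep <- which(data@trials$student != s)
    rep <- runCV(subsetResponseData(data, keep), features, config, k = k,
                 seed = config$seed)
    data.frame(leftOut = s, meanTestAccuracy = mean(rep@folds$testAccuracy),
               meanTestF1 = mean(rep@folds$testF1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
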