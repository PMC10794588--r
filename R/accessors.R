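# Accessors and show methods.

#' @rdname ResponseData-class
#' @param object A \linkS4class{ResponseData}.
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))

#' @rdname ResponseData-class
#' @export
setMethod("trials", "ResponseData", function(object) object@trials)

#' @rdname ResponseData-class
#' @export
setGeneric("nStudents", function(object) standardGeneric("nStudents"))

#' @rdname ResponseData-class
#' @export
setMethod("nStudents", "ResponseData", function(object) object@nStudents)

#' @rdname ResponseData-class
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname ResponseData-class
#' @export
setMethod("nItems", "ResponseData", function(object) object@nItems)

#' @rdname FeatureStore-class
#' @param object A \linkS4class{FeatureStore}.
#' @export
setGeneric("clipDuration", function(object) standardGeneric("clipDuration"))

#' @rdname FeatureStore-class
#' @export
setMethod("clipDuration", "FeatureStore", function(object) object@clipDuration)

#' @rdname FeatureStore-class
#' @export
setGeneric("featureDim", function(object) standardGeneric("featureDim"))

#' @rdname FeatureStore-class
#' @export
setMethod("featureDim", "FeatureStore", function(object) object@featureDim)

#' Fetch one feature sequence by reference
#'
#' @param object A \linkS4class{FeatureStore}.
#' @param ref Feature reference key.
#' @return The T x D feature matrix.
#' @export
setGeneric("getSequence", function(object, ref) standardGeneric("getSequence"))

#' @rdname getSequence
#' @export
setMethod("getSequence", "FeatureStore", function(object, ref) {
  m <- object@sequences[[ref]]
  if (is.null(m)) stop(sprintf("unknown feature reference '%s'", ref),
                       call. = FALSE)
  m
})

#' @rdname SadModel-class
#' @param object A \linkS4class{SadModel}.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname SadModel-class
#' @export
setMethod("lossHistory", "SadModel", function(object) object@lossHistory)

#' @rdname CVReport-class
#' @param object A \linkS4class{CVReport}.
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))

#' @rdname CVReport-class
#' @export
setMethod("foldMetrics", "CVReport", function(object) object@folds)

#' @rdname CVReport-class
#' @export
setGeneric("cvPredictions", function(object) standardGeneric("cvPredictions"))

#' @rdname CVReport-class
#' @export
setMethod("cvPredictions", "CVReport", function(object) object@predictions)

#' Mean and SD of per-fold metrics
#'
#' @param object A \linkS4class{CVReport}.
#' @return data.frame with one row per metric (train/test accuracy and F1)
#'   and columns \code{mean} and \code{sd} over folds.
#' @export
setGeneric("cvSummary", function(object) standardGeneric("cvSummary"))

#' @rdname cvSummary
#' @export
setMethod("cvSummary", "CVReport", function(object) {
  cols <- c("trainAccuracy", "trainF1", "testAccuracy", "testF1")
  data.frame(metric = cols,
             mean = vapply(cols, function(c) mean(object@folds[[c]]), 0),
             sd = vapply(cols, function(c) stats::sd(object@folds[[c]]), 0),
             row.names = NULL)
})

setMethod("show", "ResponseData", function(object) {
  tr <- object@trials
  cat(sprintf("ResponseData: %d trials, %d students x %d items\n",
              nrow(tr), object@nStudents, object@nItems))
  cat(sprintf("  correct-response rate: %.3f\n", mean(tr$response)))
  cat(sprintf("  response time [s]: %.2f-%.2f (mean %.2f)\n",
              min(tr$responseTime), max(tr$responseTime),
              mean(tr$responseTime)))
  invisible(object)
})

setMethod("show", "FeatureStore", function(object) {
  lens <- vapply(object@sequences, nrow, 0L)
  cat(sprintf("FeatureStore: %d sequences, D = %d, clip %.3f s\n",
              length(lens), object@featureDim, object@clipDuration))
  cat(sprintf("  lengths: %d-%d (mean %.2f)\n", min(lens), max(lens),
              mean(lens)))
  invisible(object)
})

setMethod("show", "SadModel", function(object) {
  cat(sprintf("SadModel (variant '%s'), %d students x %d items\n",
              object@variant, object@nStudents, object@nItems))
  if (length(object@lossHistory))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                length(object@lossHistory),
                object@lossHistory[length(object@lossHistory)]))
  if (!is.null(object@params$state))
    cat(sprintf("  variance weight w = %.4f\n", object@params$state$par$w))
  invisible(object)
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: variant '%s', %d-fold stratified CV\n",
              object@variant, object@k))
  s <- cvSummary(object)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-14s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(object)
})
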