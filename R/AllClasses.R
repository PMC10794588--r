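# S4 classes for the central data containers.

#' ResponseData: a table of scored item responses
#'
#' One row per trial: which student answered which item, whether the answer
#' was correct, how long it took, and (optionally) a reference into a
#' \linkS4class{FeatureStore} holding the behavioural feature sequence
#' recorded during the trial. Arbitrary string identifiers are mapped to
#' dense 0-based indices at construction; the mapping is kept in the
#' \code{studentIds} / \code{itemIds} slots.
#'
#' @slot trials data.frame with columns \code{student}, \code{item} (0-based
#'   integer indices), \code{response} (0/1), \code{responseTime} (seconds),
#'   \code{featureRef} (character) and \code{order} (presentation order).
#' @slot nStudents Number of distinct students (one-hot length of the
#'   student network input).
#' @slot nItems Number of distinct items.
#' @slot studentIds Character vector mapping index \code{i} to the original
#'   identifier of student \code{i - 1}.
#' @slot itemIds Same for items.
#' @export
setClass("ResponseData",
         representation(trials = "data.frame",
                        nStudents = "integer",
                        nItems = "integer",
                        studentIds = "character",
                        itemIds = "character"))

setValidity("ResponseData", function(object) {
  tr <- object@trials
  need <- c("student", "item", "response", "responseTime", "featureRef",
            "order")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr) == 0L) return("trials must contain at least one row")
  if (!all(tr$response %in% c(0L, 1L))) return("response must be 0 or 1")
  if (any(!is.finite(tr$responseTime)) || any(tr$responseTime <= 0))
    return("responseTime must be positive")
  if (any(tr$student < 0L) || any(tr$student >= object@nStudents))
    return("student index out of bounds")
  if (any(tr$item < 0L) || any(tr$item >= object@nItems))
    return("item index out of bounds")
  if (anyDuplicated(tr[, c("student", "item")]))
    return("duplicate (student, item) pairs")
  if (nrow(tr) > object@nStudents * object@nItems)
    return("more trials than student-item pairs")
  TRUE
})

#' FeatureStore: per-trial behavioural feature sequences
#'
#' A keyed collection of T x D feature matrices: one row per clip (a short
#' temporal window of the recording, e.g. a facial-video clip embedding),
#' one column per feature dimension. All matrices share the feature
#' dimension and the clip duration.
#'
#' @slot sequences Named list of numeric T x D matrices, keyed by the
#'   \code{featureRef} values of a \linkS4class{ResponseData}.
#' @slot clipDuration Seconds of recording covered by one clip (one row).
#' @slot featureDim Shared number of feature columns D.
#' @export
setClass("FeatureStore",
         representation(sequences = "list",
                        clipDuration = "numeric",
                        featureDim = "integer"))

setValidity("FeatureStore", function(object) {
  if (length(object@sequences) == 0L) return("no sequences")
  if (is.null(names(object@sequences)) || any(names(object@sequences) == ""))
    return("sequences must be named by feature reference")
  if (anyDuplicated(names(object@sequences)))
    return("duplicate feature references")
  if (!is.finite(object@clipDuration) || object@clipDuration <= 0)
    return("clipDuration must be positive")
  for (m in object@sequences) {
    if (!is.matrix(m) || !is.numeric(m)) return("sequences must be matrices")
    if (nrow(m) < 1L) return("each sequence needs at least one clip")
    if (ncol(m) != object@featureDim)
      return("inconsistent feature dimension")
    if (any(!is.finite(m))) return("non-finite feature values")
  }
  TRUE
})

#' SadModel: a fitted model bundle
#'
#' Holds a trained model of one of the five variants together with its
#' resolved training configuration, the per-epoch loss trajectory, and the
#' seed that makes the fit bit-reproducible.
#'
#' @slot variant One of \code{"sad_irt"}, \code{"deep_irt"},
#'   \code{"deep_irt_no_bn"}, \code{"base_irt"}, \code{"feature_baseline"}.
#' @slot params Nested list of trained weights and normalization buffers.
#' @slot config Resolved training configuration (see [trainConfig()]).
#' @slot nStudents,nItems Entity counts the one-hot encodings were sized to.
#' @slot lossHistory Mean per-trial cross-entropy after each epoch.
#' @slot batchLoss Summed cross-entropy of every mini-batch, in order.
#' @slot seed Seed used for initialization and batching.
#' @export
setClass("SadModel",
         representation(variant = "character",
                        params = "list",
                        config = "list",
                        nStudents = "integer",
                        nItems = "integer",
                        lossHistory = "numeric",
                        batchLoss = "numeric",
                        seed = "numeric"))

setValidity("SadModel", function(object) {
  ok <- c("sad_irt", "deep_irt", "deep_irt_no_bn", "base_irt",
          "feature_baseline")
  if (!(length(object@variant) == 1L && object@variant %in% ok))
    return(paste("variant must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' CVReport: stratified cross-validation results
#'
#' @slot variant Model variant evaluated.
#' @slot k Number of folds.
#' @slot folds data.frame of per-fold train/test accuracy and F1.
#' @slot predictions data.frame of per-trial test-set prediction records
#'   (fold, indices, truth, probability, class, and the theta/beta/phi
#'   estimates that produced the probability).
#' @export
setClass("CVReport",
         representation(variant = "character",
                        k = "integer",
                        folds = "data.frame",
                        predictions = "data.frame"))

setValidity("CVReport", function(object) {
  need <- c("fold", "trainAccuracy", "trainF1", "testAccuracy", "testF1")
  if (!all(need %in% names(object@folds)))
    return(paste("folds must have columns:", paste(need, collapse = ", ")))
  m <- as.matrix(object@folds[, setdiff(need, "fold")])
  if (any(m < 0 | m > 1)) return("metrics must lie in [0, 1]")
  TRUE
})

#' Construct a ResponseData object
#'
#' @param students,items Vectors of student / item identifiers (any atomic
#'   type; converted to character and densely indexed in order of first
#'   appearance).
#' @param responses 0/1 vector of scored responses.
#' @param responseTimes Positive response times in seconds.
#' @param featureRefs Optional character keys into a feature store; defaults
#'   to \code{"s<student>_i<item>"}.
#' @param order Optional presentation order (per the whole table); defaults
#'   to input order.
#' @param nStudents,nItems Optional entity counts, when the table does not
#'   mention every entity.
#' @return A \linkS4class{ResponseData} object.
#' @export
responseData <- function(students, items, responses, responseTimes,
                         featureRefs = NULL, order = NULL,
                         nStudents = NULL, nItems = NULL) {
  students <- as.character(students)
  items <- as.character(items)
  studentIds <- unique(students)
  itemIds <- unique(items)
  sIdx <- match(students, studentIds) - 1L
  iIdx <- match(items, itemIds) - 1L
  if (is.null(featureRefs))
    featureRefs <- sprintf("s%d_i%d", sIdx, iIdx)
  if (is.null(order)) order <- seq_along(students)
  trials <- data.frame(student = sIdx, item = iIdx,
                       response = as.integer(responses),
                       responseTime = as.double(responseTimes),
                       featureRef = as.character(featureRefs),
                       order = as.integer(order),
                       stringsAsFactors = FALSE)
  new("ResponseData", trials = trials,
      nStudents = if (is.null(nStudents)) length(studentIds)
                  else assertCount(nStudents, "nStudents"),
      nItems = if (is.null(nItems)) length(itemIds)
               else assertCount(nItems, "nItems"),
      studentIds = studentIds, itemIds = itemIds)
}

#' Construct a FeatureStore
#'
#' @param sequences Named list of numeric T x D matrices.
#' @param clipDuration Seconds per clip (row).
#' @return A \linkS4class{FeatureStore}.
#' @export
featureStore <- function(sequences, clipDuration) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  sequences <- lapply(sequences, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  new("FeatureStore", sequences = sequences,
      clipDuration = assertNumber(clipDuration, "clipDuration", 0,
                                  strict = TRUE),
      featureDim = ncol(sequences[[1L]]))
}
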