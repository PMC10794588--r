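# Readers and writers: response logs (CSV), feature stores (directory of
# per-trial CSV matrices plus a JSON metadata file), and run configurations
# (YAML or JSON with defaults filled in).

.responseColumns <- c("student_id", "item_id", "response", "response_time_s",
                      "feature_ref", "order_index")

#' Write a response table to CSV
#'
#' Columns: \code{student_id, item_id, response, response_time_s,
#' feature_ref, order_index}; comma-separated, UTF-8, header row, "."
#' decimal. Identifiers written are the original string ids.
#'
#' @param data A \linkS4class{ResponseData}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeResponses <- function(data, path) {
  tr <- data@trials
  df <- data.frame(student_id = data@studentIds[tr$student + 1L],
                   item_id = data@itemIds[tr$item + 1L],
                   response = tr$response,
                   response_time_s = formatC(tr$responseTime, digits = 17,
                                             format = "g"),
                   feature_ref = tr$featureRef,
                   order_index = tr$order,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Read a response table from CSV
#'
#' Validates the schema (header, binary responses, positive times, unique
#' student-item pairs) and maps the string identifiers to dense 0-based
#' indices in order of first appearance; the mapping is preserved in the
#' returned object.
#'
#' @param path CSV path written by [writeResponses()] (or produced by any
#'   tool emitting the same schema).
#' @return A \linkS4class{ResponseData}.
#' @export
readResponses <- function(path) {
  df <- data.table::fread(path, colClasses = list(
    character = c("student_id", "item_id", "feature_ref")),
    data.table = FALSE)
  missing <- setdiff(.responseColumns, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!(df$response %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("value error: row %d, column 'response': %s is not 0/1",
                 bad[1L], df$response[bad[1L]]), call. = FALSE)
  bad <- which(!is.finite(df$response_time_s) | df$response_time_s <= 0)
  if (length(bad))
    stop(sprintf(
      "value error: row %d, column 'response_time_s': must be > 0",
      bad[1L]), call. = FALSE)
  if (anyDuplicated(df[, c("student_id", "item_id")]))
    stop("uniqueness error: duplicate (student_id, item_id) pair",
         call. = FALSE)
  responseData(students = df$student_id, items = df$item_id,
               responses = df$response, responseTimes = df$response_time_s,
               featureRefs = df$feature_ref, order = df$order_index)
}

#' Write a feature store to a directory of CSV matrices
#'
#' One plain numeric CSV per sequence (\code{<feature_ref>.csv}, no header)
#' plus \code{meta.json} carrying the clip duration, the feature dimension
#' and the reference list. Values are written with 17 significant digits so
#' that doubles round-trip bit-exactly.
#'
#' @param store A \linkS4class{FeatureStore}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFeatureStore <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(clip_duration = store@clipDuration,
         feature_dim = store@featureDim,
         refs = names(store@sequences)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (ref in names(store@sequences)) {
    m <- store@sequences[[ref]]
    txt <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m))
    data.table::fwrite(as.data.frame(txt), file.path(dir,
                                                     paste0(ref, ".csv")),
                       quote = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a feature store from a CSV directory
#'
#' @param dir Directory written by [writeFeatureStore()].
#' @param refs Optional response table (\linkS4class{ResponseData}) whose
#'   feature references must all resolve; a dangling reference is an error.
#' @return A \linkS4class{FeatureStore}.
#' @export
readFeatureStore <- function(dir, refs = NULL) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath))
    stop("schema error: missing meta.json", call. = FALSE)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$clip_duration))
    stop("schema error: meta.json lacks clip_duration", call. = FALSE)
  seqs <- lapply(meta$refs, function(ref) {
    f <- file.path(dir, paste0(ref, ".csv"))
    if (!file.exists(f))
      stop(sprintf("referential error: missing sequence file '%s'", f),
           call. = FALSE)
    as.matrix(data.table::fread(f, header = FALSE, data.table = FALSE))
  })
  names(seqs) <- meta$refs
  if (!is.null(refs)) {
    dangling <- setdiff(refs@trials$featureRef, meta$refs)
    if (length(dangling))
      stop(sprintf("referential error: %d dangling feature_ref (e.g. '%s')",
                   length(dangling), dangling[1L]), call. = FALSE)
  }
  store <- featureStore(seqs, clipDuration = meta$clip_duration)
  if (!is.null(meta$feature_dim) && store@featureDim != meta$feature_dim)
    stop("schema error: feature_dim does not match the matrices",
         call. = FALSE)
  store
}

.configDefaults <- function() {
  list(
    generator = generatorConfig(),
    training = trainConfig(),
    cv = list(k = 20L)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration with sections \code{generator},
#' \code{training} and \code{cv}, fills every omitted field with its
#' default (learning rate 1e-3, batch size 64, 200 epochs, 20 folds), and
#' rejects unknown keys and type-invalid values. An empty or absent file
#' yields the full default configuration.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Fully resolved configuration list with sections
#'   \code{generator}, \code{training} and \code{cv}.
#' @export
loadConfig <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  defaults <- .configDefaults()
  unknownSections <- setdiff(names(raw), names(defaults))
  if (length(unknownSections))
    stop("validation error at: ", unknownSections[1L], call. = FALSE)
  resolved <- defaults
  for (section in names(raw)) {
    sec <- raw[[section]]
    if (!is.list(sec))
      stop("validation error at: ", section, " (must be a mapping)",
           call. = FALSE)
    unknown <- setdiff(names(sec), names(defaults[[section]]))
    if (length(unknown))
      stop("validation error at: ", section, ".", unknown[1L],
           call. = FALSE)
    for (key in names(sec)) resolved[[section]][[key]] <- sec[[key]]
  }
  # re-validate through the constructors so type errors carry field paths
  resolved$generator <- tryCatch(
    do.call(generatorConfig, resolved$generator[names(formals(
      generatorConfig))[names(formals(generatorConfig)) %in%
        names(resolved$generator)]]),
    error = function(e) stop("validation error in generator: ",
                             conditionMessage(e), call. = FALSE))
  trFields <- resolved$training[setdiff(names(resolved$training),
                                        c("variant", "tcn"))]
  resolved$training <- tryCatch(
    do.call(trainConfig, c(list(variant = resolved$training$variant,
                                tcn = resolved$training$tcn), trFields)),
    error = function(e) stop("validation error in training: ",
                             conditionMessage(e), call. = FALSE))
  resolved$cv$k <- tryCatch(assertCount(resolved$cv$k, "cv.k", min = 2L),
                            error = function(e)
                              stop("validation error in cv: ",
                                   conditionMessage(e), call. = FALSE))
  resolved
}
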