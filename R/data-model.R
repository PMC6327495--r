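#' Construct a SparseSeriesSet
#'
#' @param records either a named list over feature ids of named lists over
#'   object ids of numeric vectors, or a single such feature column wrapped
#'   appropriately. Missing (object, feature) entries are filled with the
#'   empty record.
#' @param labels named character (or coercible) vector mapping every object
#'   id to its class label.
#' @param featureIds,objectIds optional explicit orderings; default to the
#'   order encountered in \code{records} / \code{labels}.
#' @return a validated \linkS4class{SparseSeriesSet}
#' @examples
#' x <- SparseSeriesSet(
#'   records = list(lab = list(p1 = c(1, 2, 3), p2 = numeric(0))),
#'   labels  = c(p1 = "case", p2 = "control"))
#' nObjects(x)
#' @export
SparseSeriesSet <- function(records, labels, featureIds = names(records),
                            objectIds = names(labels)) {
  labels <- stats::setNames(as.character(labels), names(labels))
  featureIds <- as.character(featureIds)
  objectIds <- as.character(objectIds)
  full <- lapply(featureIds, function(f) {
    col <- records[[f]]
    out <- stats::setNames(vector("list", length(objectIds)), objectIds)
    for (o in objectIds) {
      v <- col[[o]]
      out[[o]] <- if (is.null(v)) numeric(0) else as.numeric(v)
    }
    out
  })
  names(full) <- featureIds
  new("SparseSeriesSet", records = full, labels = labels[objectIds],
      featureIds = featureIds, objectIds = objectIds)
}

#' @rdname sshapelet-generics
#' @export
setMethod("featureIds", "SparseSeriesSet", function(x) x@featureIds)
#' @rdname sshapelet-generics
#' @export
setMethod("featureIds", "SymbolicSeriesSet", function(x) x@featureIds)
#' @rdname sshapelet-generics
#' @export
setMethod("objectIds", "SparseSeriesSet", function(x) x@objectIds)
#' @rdname sshapelet-generics
#' @export
setMethod("objectIds", "SymbolicSeriesSet", function(x) x@objectIds)
#' @rdname sshapelet-generics
#' @export
setMethod("classLabels", "SparseSeriesSet", function(object) object@labels)
#' @rdname sshapelet-generics
#' @export
setMethod("classLabels", "SymbolicSeriesSet", function(object) object@labels)
#' @rdname sshapelet-generics
#' @export
setMethod("nObjects", "SparseSeriesSet", function(x) length(x@objectIds))
#' @rdname sshapelet-generics
#' @export
setMethod("nObjects", "SymbolicSeriesSet", function(x) length(x@objectIds))
#' @rdname sshapelet-generics
#' @export
setMethod("nFeatures", "SparseSeriesSet", function(x) length(x@featureIds))
#' @rdname sshapelet-generics
#' @export
setMethod("nFeatures", "SymbolicSeriesSet", function(x) length(x@featureIds))

.checkFeature <- function(x, feature) {
  if (length(feature) != 1L || !feature %in% x@featureIds)
    stop("unknown feature id: ", feature)
  feature
}

#' @rdname sshapelet-generics
#' @export
setMethod("records", "SparseSeriesSet", function(x, feature)
  x@records[[.checkFeature(x, feature)]])
#' @rdname sshapelet-generics
#' @export
setMethod("records", "SymbolicSeriesSet", function(x, feature)
  x@records[[.checkFeature(x, feature)]])

#' @rdname sshapelet-generics
#' @export
setMethod("sparsityFraction", "SparseSeriesSet", function(x, feature) {
  col <- records(x, feature)
  mean(vapply(col, length, integer(1)) == 0L)
})

#' @rdname sshapelet-generics
#' @export
setMethod("sparsityFraction", "SymbolicSeriesSet", function(x, feature) {
  mean(is.na(records(x, feature)))
})

#' Subset a SparseSeriesSet by objects
#'
#' \code{x[i]} keeps the objects selected by \code{i} (indices, object ids,
#' or a logical mask), preserving feature structure and labels. Used by the
#' cross-validation harness to form folds.
#'
#' @param x a \linkS4class{SparseSeriesSet}
#' @param i object indices, ids or logical mask
#' @param j,...,drop ignored
#' @export
setMethod("[", "SparseSeriesSet", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else x@objectIds[i]
  if (anyNA(ids) || !all(ids %in% x@objectIds)) stop("unknown object ids in subset")
  recs <- lapply(x@records, function(col) col[ids])
  new("SparseSeriesSet", records = recs, labels = x@labels[ids],
      featureIds = x@featureIds, objectIds = ids)
})

#' Read a long-format measurements table into a SparseSeriesSet
#'
#' The measurements file has one row per measurement with columns
#' \code{object_id, feature_id, time, value}; the labels file has columns
#' \code{object_id, label}. Per (object, feature), values sorted ascending by
#' time form the record; sampling times are used only for this ordering
#' (irregular intervals are otherwise ignored). Simultaneous measurements
#' (identical timestamps) keep their file order -- a documented convention.
#' Objects present in the labels file but absent from the measurements file
#' get all-empty records; objects measured but unlabelled are an error.
#'
#' @param measurementsPath path to the measurements CSV (UTF-8, header row)
#' @param labelsPath path to the labels CSV
#' @return a \linkS4class{SparseSeriesSet}
#' @seealso \code{\link{writeLongCSV}} for the inverse
#' @export
readLongCSV <- function(measurementsPath, labelsPath) {
  lab <- read.csv(labelsPath, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("object_id", "label") %in% names(lab)))
    stop("labels file must have columns object_id, label: ", labelsPath)
  if (anyDuplicated(lab$object_id))
    stop("duplicated object_id in labels file: ", labelsPath)
  mea <- read.csv(measurementsPath, stringsAsFactors = FALSE,
                  colClasses = c(object_id = "character", feature_id = "character"))
  if (!all(c("object_id", "feature_id", "time", "value") %in% names(mea)))
    stop("measurements file must have columns object_id, feature_id, time, value: ",
         measurementsPath)
  if (nrow(mea) > 0) {
    badTime <- which(is.na(suppressWarnings(as.numeric(mea$time))))
    badVal <- which(is.na(suppressWarnings(as.numeric(mea$value))))
    if (length(badTime))
      stop(sprintf("non-numeric time at data line %d of %s", badTime[1], measurementsPath))
    if (length(badVal))
      stop(sprintf("non-numeric value at data line %d of %s", badVal[1], measurementsPath))
    unlabeled <- setdiff(unique(mea$object_id), lab$object_id)
    if (length(unlabeled))
      stop("objects present in measurements but missing from labels: ",
           paste(head(unlabeled, 5), collapse = ", "))
  }
  objectIds <- lab$object_id
  featIds <- unique(mea$feature_id)
  if (length(featIds) == 0L) featIds <- "feature1"  # degenerate: all-empty dataset
  recs <- stats::setNames(lapply(featIds, function(f) {
    stats::setNames(rep(list(numeric(0)), length(objectIds)), objectIds)
  }), featIds)
  if (nrow(mea) > 0) {
    mea$time <- as.numeric(mea$time)
    mea$value <- as.numeric(mea$value)
    key <- split(seq_len(nrow(mea)), list(mea$feature_id, mea$object_id), drop = TRUE)
    for (k in names(key)) {
      idx <- key[[k]]
      idx <- idx[order(mea$time[idx])]  # stable: ties keep file order
      recs[[mea$feature_id[idx[1]]]][[mea$object_id[idx[1]]]] <- mea$value[idx]
    }
  }
  SparseSeriesSet(records = recs, labels = stats::setNames(lab$label, lab$object_id),
                  featureIds = featIds, objectIds = objectIds)
}

#' Write a SparseSeriesSet as long-format measurement + label CSVs
#'
#' Companion writer to \code{\link{readLongCSV}}; the round trip is the
#' identity on values, ordering and labels. Timestamps are emitted as the
#' within-record measurement index plus an optional deterministic sub-integer
#' jitter, and rows can be shuffled so that reading genuinely exercises the
#' sort-by-time path.
#'
#' @param x a \linkS4class{SparseSeriesSet}
#' @param measurementsPath,labelsPath output CSV paths
#' @param shuffle shuffle measurement row order (default TRUE)
#' @param jitter add order-preserving jitter in (-0.3, 0.3) to the integer
#'   timestamps (default TRUE)
#' @param seed seed for shuffling/jitter
#' @return invisibly, the two paths
#' @export
writeLongCSV <- function(x, measurementsPath, labelsPath,
                         shuffle = TRUE, jitter = TRUE, seed = 1L) {
  rows <- list()
  for (f in x@featureIds) {
    col <- x@records[[f]]
    for (o in x@objectIds) {
      v <- col[[o]]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = o, feature_id = f, time = seq_along(v), value = v,
        stringsAsFactors = FALSE)
    }
  }
  mea <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = character(0), feature_id = character(0),
               time = numeric(0), value = numeric(0))
  if (nrow(mea) > 0 && (shuffle || jitter)) {
    rng <- .localRNG(seed)
    on.exit(rng(), add = TRUE)
    if (jitter)
      mea$time <- mea$time + stats::runif(nrow(mea), -0.3, 0.3)
    if (shuffle)
      mea <- mea[sample.int(nrow(mea)), , drop = FALSE]
  }
  write.csv(mea, measurementsPath, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(object_id = x@objectIds, label = unname(x@labels[x@objectIds]),
                       stringsAsFactors = FALSE),
            labelsPath, row.names = FALSE, quote = FALSE)
  invisible(c(measurementsPath, labelsPath))
}

#' Write a transformed feature matrix to CSV
#'
#' @param matrix a feature matrix as returned by
#'   \code{\link{transformFeatures}}: a data.frame with an \code{object_id}
#'   column, one numeric column per retained feature, and a \code{label}
#'   column. Refused if it has no feature columns or any non-finite cell.
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeFeatureMatrix <- function(matrix, path) {
  featCols <- setdiff(names(matrix), c("object_id", "label"))
  if (length(featCols) == 0L)
    stop("feature matrix has no feature columns; refusing to write header-only file")
  vals <- as.matrix(matrix[, featCols, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("feature matrix contains non-finite cells")
  ok <- tryCatch({
    write.csv(matrix, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write feature matrix to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a transformed feature matrix from CSV
#'
#' @param path CSV written by \code{\link{writeFeatureMatrix}}
#' @return the feature matrix data.frame
#' @export
readFeatureMatrix <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(object_id = "character", label = "character"))
  out
}

# Save the RNG state and seed a local stream; the returned function restores
# the caller's state.
.localRNG <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
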