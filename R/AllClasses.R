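#' SparseSeriesSet: labelled objects over sparse multi-variate series features
#'
#' The core container: \code{n} labelled objects described by \code{m}
#' multi-variate features, where each (object, feature) record is an ordered,
#' variable-length real-valued series. A record of length zero is the empty
#' record (the "empty set" marker) -- there is no separate NA state, and a
#' record absent from an input file is identical in meaning to a zero-length
#' record.
#'
#' @slot records named list over feature ids; each element is a named list
#'   over object ids of numeric vectors (length 0 = empty record). Order is
#'   meaningful and preserved exactly as read; sampling times are used only
#'   to establish it.
#' @slot labels named character vector over object ids; one class label per
#'   object, at least for supervised stages two distinct labels overall.
#'   Labels are opaque strings; more than two classes are supported by the
#'   transformation stages (evaluation assumes binary).
#' @slot featureIds character vector of the m feature identifiers.
#' @slot objectIds character vector of the n object identifiers.
#'
#' @seealso \code{\link{readLongCSV}}, \code{\link{simulateSparseSeries}},
#'   \code{\link{discretize}}
#' @export
setClass("SparseSeriesSet",
  representation(
    records   = "list",
    labels    = "character",
    featureIds = "character",
    objectIds = "character"
  )
)

setValidity("SparseSeriesSet", function(object) {
  msg <- character()
  if (length(object@featureIds) < 1L) msg <- c(msg, "at least one feature required")
  if (length(object@objectIds) < 1L) msg <- c(msg, "at least one object required")
  if (anyDuplicated(object@featureIds)) msg <- c(msg, "duplicated feature ids")
  if (anyDuplicated(object@objectIds)) msg <- c(msg, "duplicated object ids")
  if (!identical(names(object@records), object@featureIds))
    msg <- c(msg, "records must be named by featureIds, in order")
  if (!identical(sort(names(object@labels)), sort(object@objectIds)))
    msg <- c(msg, "every object must have exactly one label")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not be NA")
  for (f in names(object@records)) {
    col <- object@records[[f]]
    if (!identical(names(col), object@objectIds)) {
      msg <- c(msg, sprintf("records for feature '%s' must be named by objectIds, in order", f))
      break
    }
    if (!all(vapply(col, is.numeric, logical(1)))) {
      msg <- c(msg, sprintf("records for feature '%s' must be numeric vectors", f))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SymbolicSeriesSet: the SAX-discretized counterpart of a SparseSeriesSet
#'
#' Same shape as \linkS4class{SparseSeriesSet}, but each record is a symbol
#' string over a SAX alphabet of size \code{alphabetSize}, or \code{NA} for
#' the empty record. Produced by \code{\link{discretize}}.
#'
#' @slot records named list over feature ids; each element a named character
#'   vector over object ids (\code{NA} = empty record).
#' @slot labels,featureIds,objectIds as in \linkS4class{SparseSeriesSet}.
#' @slot alphabetSize integer SAX alphabet size used for every record.
#' @slot paaRatio numeric PAA compression ratio in (0, 1] used for every
#'   record (1 = PAA disabled).
#' @export
setClass("SymbolicSeriesSet",
  representation(
    records    = "list",
    labels     = "character",
    featureIds = "character",
    objectIds  = "character",
    alphabetSize = "integer",
    paaRatio   = "numeric"
  )
)

setValidity("SymbolicSeriesSet", function(object) {
  msg <- character()
  if (!identical(names(object@records), object@featureIds))
    msg <- c(msg, "records must be named by featureIds, in order")
  if (!identical(sort(names(object@labels)), sort(object@objectIds)))
    msg <- c(msg, "every object must have exactly one label")
  if (length(object@alphabetSize) != 1L || object@alphabetSize < 2L)
    msg <- c(msg, "alphabetSize must be a single integer >= 2")
  if (length(object@paaRatio) != 1L || object@paaRatio <= 0 || object@paaRatio > 1)
    msg <- c(msg, "paaRatio must be in (0, 1]")
  syms <- letters[seq_len(min(object@alphabetSize, 26L))]
  for (f in names(object@records)) {
    col <- object@records[[f]]
    if (!is.character(col) || !identical(names(col), object@objectIds)) {
      msg <- c(msg, sprintf("records for feature '%s' must be a character vector named by objectIds", f))
      break
    }
    chars <- unique(unlist(strsplit(col[!is.na(col)], "", fixed = TRUE)))
    if (!all(chars %in% syms)) {
      msg <- c(msg, sprintf("feature '%s' contains symbols outside the alphabet", f))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SShapelet: a selected sequence shapelet for one feature
#'
#' The class-distinctive subsequence selected for a feature, together with
#' the alphabet it is written in, its optimal split distance, the information
#' gain that split achieved on the training column, and the learned encoding
#' substituted for empty records at transform time.
#'
#' @slot featureId feature the shapelet was selected for.
#' @slot sequence the symbol string s*.
#' @slot alphabetSize the alphabet size of maximum utility, alpha*.
#' @slot deltaOsp optimal split distance threshold (records with distance
#'   strictly below it fall on the left/near side).
#' @slot gain information gain (bits) of the optimal split on training data.
#' @slot strategy one of "plain", "mc", "lr".
#' @slot emptySide for lr, the winning placement of empty records ("left",
#'   "right"); "none" when the training column had no empty records or for
#'   plain/mc.
#' @slot emptyEncoding the finite numeric distance substituted for empty
#'   records when transforming (plain: |s*|; mc: modal training distance;
#'   lr: the winning side's distance).
#' @export
setClass("SShapelet",
  representation(
    featureId   = "character",
    sequence    = "character",
    alphabetSize = "integer",
    deltaOsp    = "numeric",
    gain        = "numeric",
    strategy    = "character",
    emptySide   = "character",
    emptyEncoding = "numeric"
  )
)

setValidity("SShapelet", function(object) {
  msg <- character()
  if (nchar(object@sequence) < 1L) msg <- c(msg, "sequence must be non-empty")
  if (!object@strategy %in% c("plain", "mc", "lr"))
    msg <- c(msg, "strategy must be plain, mc or lr")
  if (!object@emptySide %in% c("left", "right", "none"))
    msg <- c(msg, "emptySide must be left, right or none")
  if (!is.finite(object@emptyEncoding)) msg <- c(msg, "emptyEncoding must be finite")
  if (object@gain < -1e-12) msg <- c(msg, "gain must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ShapeletModel: the learned transformation tau*
#'
#' The self-contained mapping from multi-variate objects to real-valued
#' feature vectors: one \linkS4class{SShapelet} per retained feature (none
#' for the sequence-length baseline \code{sl}), the discretization
#' configuration, the sparsity tolerance used to retain features, and the
#' seed that drove candidate sampling. Transforming new data needs nothing
#' beyond this object.
#'
#' @slot strategy one of "plain", "mc", "lr", "sl".
#' @slot shapelets list of \linkS4class{SShapelet}, one per retained feature
#'   (empty for "sl").
#' @slot featureIds retained feature ids (those passing the sparsity filter
#'   on the training set, in training order).
#' @slot tauSp sparsity tolerance in (0, 1].
#' @slot paaRatio PAA compression ratio in (0, 1].
#' @slot alphabetSizes candidate alphabet sizes searched.
#' @slot candidatesPerFeature candidate pool size per (feature, alphabet).
#' @slot distMethod window dissimilarity used ("levenshtein" or "hamming").
#' @slot seed integer seed that drove candidate sampling.
#' @slot version schema version of the serialized form.
#' @seealso \code{\link{fitShapeletModel}}, \code{\link{transformFeatures}},
#'   \code{\link{writeShapeletModel}}
#' @export
setClass("ShapeletModel",
  representation(
    strategy   = "character",
    shapelets  = "list",
    featureIds = "character",
    tauSp      = "numeric",
    paaRatio   = "numeric",
    alphabetSizes = "integer",
    candidatesPerFeature = "integer",
    distMethod = "character",
    seed       = "integer",
    version    = "integer"
  )
)

setValidity("ShapeletModel", function(object) {
  msg <- character()
  if (!object@strategy %in% c("plain", "mc", "lr", "sl"))
    msg <- c(msg, "strategy must be plain, mc, lr or sl")
  if (length(object@featureIds) < 1L) msg <- c(msg, "no retained features")
  if (object@strategy == "sl") {
    if (length(object@shapelets) != 0L) msg <- c(msg, "sl models carry no shapelets")
  } else {
    if (length(object@shapelets) != length(object@featureIds))
      msg <- c(msg, "one shapelet per retained feature required")
    else if (!all(vapply(object@shapelets, function(z) is(z, "SShapelet"), logical(1))))
      msg <- c(msg, "shapelets must be SShapelet objects")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SparseSeriesSet", function(object) {
  emp <- mean(vapply(object@featureIds, function(f)
    sparsityFraction(object, f), numeric(1)))
  cat(sprintf("SparseSeriesSet: %d objects x %d features (%d classes, %.1f%% empty records)\n",
              length(object@objectIds), length(object@featureIds),
              length(unique(object@labels)), 100 * emp))
  cat("  features: ", paste(head(object@featureIds, 5), collapse = ", "),
      if (length(object@featureIds) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SymbolicSeriesSet", function(object) {
  cat(sprintf("SymbolicSeriesSet: %d objects x %d features, alphabet size %d, PAA ratio %g\n",
              length(object@objectIds), length(object@featureIds),
              object@alphabetSize, object@paaRatio))
})

setMethod("show", "SShapelet", function(object) {
  cat(sprintf("SShapelet '%s' (feature %s, alpha=%d): delta_osp=%g, gain=%.3f bits, %s",
              object@sequence, object@featureId, object@alphabetSize,
              object@deltaOsp, object@gain, object@strategy))
  cat(sprintf(", empty -> %g%s\n", object@emptyEncoding,
              if (object@emptySide == "none") "" else paste0(" (", object@emptySide, ")")))
})

setMethod("show", "ShapeletModel", function(object) {
  cat(sprintf("ShapeletModel (strategy %s): %d retained features, tau_sp=%g, seed=%d\n",
              object@strategy, length(object@featureIds), object@tauSp, object@seed))
  if (object@strategy != "sl") {
    gains <- vapply(object@shapelets, slot, numeric(1), "gain")
    cat(sprintf("  shapelet gains: min %.3f / median %.3f / max %.3f bits\n",
                min(gains), stats::median(gains), max(gains)))
  }
})
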