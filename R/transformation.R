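#' Sparsity filter for features
#'
#' Retains the features whose fraction of empty records is at most
#' \code{tauSp} (inclusive boundary) and which have at least one non-empty
#' record -- so a fully empty feature is dropped even at \code{tauSp = 1}.
#'
#' @param dataset a \linkS4class{SparseSeriesSet}
#' @param tauSp sparsity tolerance in (0, 1]
#' @return character vector of retained feature ids (possibly empty)
#' @export
filterFeatures <- function(dataset, tauSp) {
  if (tauSp <= 0 || tauSp > 1) stop("tauSp must be in (0, 1]")
  keep <- vapply(featureIds(dataset), function(f) {
    sp <- sparsityFraction(dataset, f)
    sp <= tauSp && sp < 1
  }, logical(1))
  featureIds(dataset)[keep]
}

#' Fit the feature transformation tau* (Phases A + B)
#'
#' Learns a self-contained \linkS4class{ShapeletModel} on a training set:
#' sparsity filtering, SAX discretization per candidate alphabet, and
#' s-shapelet discovery per retained feature under the chosen empty-record
#' strategy. The sequence-length baseline \code{sl} learns no shapelets --
#' its model only records the retained features. Deterministic under a
#' fixed seed; refitting with the same seed yields an identical model.
#'
#' @param dataset training \linkS4class{SparseSeriesSet} with >= 2 classes
#' @param strategy "plain", "mc", "lr" or "sl"
#' @param tauSp sparsity tolerance in (0, 1]
#' @param alphabetSizes candidate SAX alphabet sizes (default 2, 3, 5)
#' @param paaRatio PAA compression ratio (default 1, disabled)
#' @param candidatesPerFeature candidate pool size per (feature, alphabet)
#' @param seed integer seed driving candidate sampling
#' @param method window dissimilarity, see \code{\link{subsequenceDistance}}
#' @return a \linkS4class{ShapeletModel}
#' @export
fitShapeletModel <- function(dataset, strategy = c("plain", "mc", "lr", "sl"),
                             tauSp = 1.0, alphabetSizes = c(2L, 3L, 5L),
                             paaRatio = 1, candidatesPerFeature = 50L,
                             seed = 1L, method = c("levenshtein", "hamming")) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  if (length(unique(classLabels(dataset))) < 2L)
    stop("training set must contain at least two classes")
  retained <- filterFeatures(dataset, tauSp)
  if (length(retained) == 0L) stop("no features survive the sparsity filter")
  shp <- if (strategy == "sl") list() else
    unname(discoverShapelets(dataset, strategy, tauSp, alphabetSizes,
                             paaRatio, candidatesPerFeature, seed, method))
  new("ShapeletModel", strategy = strategy, shapelets = shp,
      featureIds = retained, tauSp = as.numeric(tauSp),
      paaRatio = as.numeric(paaRatio),
      alphabetSizes = sort(as.integer(alphabetSizes)),
      candidatesPerFeature = as.integer(candidatesPerFeature),
      distMethod = method, seed = as.integer(seed), version = 1L)
}

#' Transform a dataset into a real-valued feature matrix (Phase C)
#'
#' Applies the learned mapping to any dataset covering the model's retained
#' features (records may be empty). For shapelet strategies each non-empty
#' record is discretized with the alphabet chosen for its feature at
#' training time and encoded as its subsequence distance to the feature's
#' s-shapelet; empty records receive the learned encoding (plain: shapelet
#' length; mc: modal training distance; lr: the stored winning-side
#' distance). The \code{sl} baseline encodes each record as its raw number
#' of measurements, with empty records as 0. Only training-derived state is
#' used: permuting the rows of a test set permutes the output identically.
#'
#' @param model a \linkS4class{ShapeletModel}
#' @param dataset a \linkS4class{SparseSeriesSet} covering the retained
#'   features
#' @return data.frame with columns \code{object_id}, one numeric column per
#'   retained feature, and \code{label}; no missing cells
#' @export
transformFeatures <- function(model, dataset) {
  missingFeat <- setdiff(model@featureIds, featureIds(dataset))
  if (length(missingFeat))
    stop("dataset lacks features required by the model: ",
         paste(head(missingFeat, 5), collapse = ", "))
  n <- nObjects(dataset)
  out <- data.frame(object_id = objectIds(dataset), stringsAsFactors = FALSE)
  if (model@strategy == "sl") {
    for (f in model@featureIds)
      out[[f]] <- vapply(records(dataset, f), length, integer(1)) + 0
  } else {
    # discretize once per alphabet actually used by the winning shapelets
    usedAlphas <- sort(unique(vapply(model@shapelets, slot, integer(1), "alphabetSize")))
    symb <- stats::setNames(
      lapply(usedAlphas, function(a) discretize(dataset, a, model@paaRatio)),
      usedAlphas)
    for (z in model@shapelets) {
      column <- records(symb[[as.character(z@alphabetSize)]], z@featureId)
      d <- as.numeric(subsequenceDistance(z@sequence, column, model@distMethod))
      d[is.na(d)] <- z@emptyEncoding
      out[[z@featureId]] <- d
    }
  }
  out$label <- unname(classLabels(dataset))
  stopifnot(!anyNA(out))
  out
}

#' Serialize / restore a ShapeletModel as JSON
#'
#' The JSON document is versioned and self-contained (strategy, seed,
#' discretization config, sparsity tolerance, and per retained feature the
#' shapelet string, alphabet, optimal split distance, gain, empty-record
#' placement and encoding), so the round trip reproduces transform output
#' exactly. Identical fits serialize to byte-identical documents.
#'
#' @param model a \linkS4class{ShapeletModel}
#' @param path file path
#' @return \code{writeShapeletModel} invisibly returns \code{path};
#'   \code{readShapeletModel} returns the restored
#'   \linkS4class{ShapeletModel}
#' @export
writeShapeletModel <- function(model, path) {
  doc <- list(
    version = model@version,
    strategy = model@strategy,
    seed = model@seed,
    paa_ratio = model@paaRatio,
    tau_sp = model@tauSp,
    alphabet_sizes = model@alphabetSizes,
    candidates_per_feature = model@candidatesPerFeature,
    dist_method = model@distMethod,
    retained_features = model@featureIds,
    features = lapply(model@shapelets, function(z) list(
      id = z@featureId, shapelet = z@sequence, alpha = z@alphabetSize,
      delta_osp = z@deltaOsp, gain = z@gain, empty_side = z@emptySide,
      empty_encoding = z@emptyEncoding))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeShapeletModel
#' @export
readShapeletModel <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model JSON at ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(doc$version) || doc$version != 1L)
    stop("unsupported model schema version: ", deparse(doc$version))
  shp <- lapply(doc$features, function(fz) {
    new("SShapelet", featureId = fz$id, sequence = fz$shapelet,
        alphabetSize = as.integer(fz$alpha), deltaOsp = as.numeric(fz$delta_osp),
        gain = as.numeric(fz$gain), strategy = doc$strategy,
        emptySide = fz$empty_side, emptyEncoding = as.numeric(fz$empty_encoding))
  })
  new("ShapeletModel", strategy = doc$strategy, shapelets = shp,
      featureIds = vapply(doc$retained_features, as.character, character(1)),
      tauSp = as.numeric(doc$tau_sp), paaRatio = as.numeric(doc$paa_ratio),
      alphabetSizes = vapply(doc$alphabet_sizes, as.integer, integer(1)),
      candidatesPerFeature = as.integer(doc$candidates_per_feature),
      distMethod = doc$dist_method, seed = as.integer(doc$seed),
      version = as.integer(doc$version))
}
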