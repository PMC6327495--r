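#' Simulate a sparse multi-variate time-series dataset
#'
#' Generates the kind of data the framework assumes: labelled objects over
#' features whose records are variable-length Gaussian-noise series, with
#' two kinds of class signal planted by feature role:
#' \describe{
#'   \item{motif}{a fixed real-valued shape (scaled by \code{motifAmplitude})
#'     is added at a uniformly random offset to the records of
#'     positive-class objects only -- a class-exclusive temporal motif.}
#'   \item{sparsity}{records are empty with class-conditional probability
#'     \code{qPos} for positives and \code{qNeg} for negatives -- missingness
#'     that is informative in itself (missing not at random).}
#'   \item{noise}{no signal: pure noise series, class-independent
#'     missingness at rate \code{qNoise}.}
#' }
#' Motif features use the class-independent rate \code{qNoise} for
#' missingness; sparsity features carry no motif. Deterministic under
#' \code{seed}.
#'
#' @param n number of objects
#' @param m number of features (roles recycled to length m)
#' @param pPos probability of the positive class ("pos" vs "neg")
#' @param roles character vector over features, values in
#'   \code{c("motif", "sparsity", "noise")}
#' @param motif real-valued motif shape (unit scale)
#' @param motifAmplitude scale applied to the motif before adding it
#' @param dRange integer range of series lengths, \code{c(dMin, dMax)};
#'   \code{dMin} must be at least the motif length
#' @param qPos,qNeg class-conditional missingness rates of
#'   sparsity-informative features
#' @param qNoise missingness rate of motif/noise features; defaults to the
#'   mean of \code{qPos} and \code{qNeg}
#' @param noiseSd standard deviation of the Gaussian background noise
#' @param seed integer seed
#' @return a \linkS4class{SparseSeriesSet} with feature ids \code{f1..fm}
#'   (role appended, e.g. \code{"f1.motif"}) and object ids \code{o1..on}
#' @export
simulateSparseSeries <- function(n = 200L, m = 5L, pPos = 0.5,
                                 roles = c("motif", "motif", "sparsity",
                                           "noise", "noise"),
                                 motif = c(1, -1, 1, -1, 1, -1, 1),
                                 motifAmplitude = 3, dRange = c(10L, 20L),
                                 qPos = 0.2, qNeg = 0.2, qNoise = NULL,
                                 noiseSd = 0.5, seed = 1L) {
  if (pPos <= 0 || pPos >= 1) stop("pPos must be in (0, 1)")
  if (qPos < 0 || qPos > 1 || qNeg < 0 || qNeg > 1)
    stop("missingness rates must be in [0, 1]")
  if (dRange[1] < 1L) stop("minimum series length must be >= 1")
  if (dRange[1] < length(motif))
    stop("motif (length ", length(motif), ") longer than the minimum series length")
  roles <- rep_len(roles, m)
  if (!all(roles %in% c("motif", "sparsity", "noise")))
    stop("roles must be 'motif', 'sparsity' or 'noise'")
  if (is.null(qNoise)) qNoise <- (qPos + qNeg) / 2
  restore <- .localRNG(seed)
  on.exit(restore(), add = TRUE)
  objectIds <- paste0("o", seq_len(n))
  featureIds <- paste0("f", seq_len(m), ".", roles)
  labels <- stats::setNames(
    ifelse(stats::runif(n) < pPos, "pos", "neg"), objectIds)
  recs <- stats::setNames(vector("list", m), featureIds)
  for (j in seq_len(m)) {
    qsByClass <- if (roles[j] == "sparsity") c(pos = qPos, neg = qNeg)
                 else c(pos = qNoise, neg = qNoise)
    col <- stats::setNames(vector("list", n), objectIds)
    for (i in seq_len(n)) {
      if (stats::runif(1) < qsByClass[[labels[i]]]) {
        col[[i]] <- numeric(0)
        next
      }
      d <- sample(seq.int(dRange[1], dRange[2]), 1L)
      v <- stats::rnorm(d, 0, noiseSd)
      if (roles[j] == "motif" && labels[i] == "pos") {
        off <- sample.int(d - length(motif) + 1L, 1L)
        idx <- off:(off + length(motif) - 1L)
        v[idx] <- v[idx] + motifAmplitude * motif
      }
      col[[i]] <- v
    }
    recs[[j]] <- col
  }
  new("SparseSeriesSet", records = recs, labels = labels,
      featureIds = featureIds, objectIds = objectIds)
}

#' Fixed worked-example toy datasets
#'
#' Two tiny fixed datasets used for worked illustrations and tests:
#' \describe{
#'   \item{"one-third"}{12 objects, 4 "pos" : 8 "neg" (label entropy
#'     0.918 bits), one fully observed feature whose positive records embed
#'     a low-high-high-low shape.}
#'   \item{"three-tenths"}{10 objects, 3 "pos" : 7 "neg" (label entropy
#'     0.881 bits), one feature with three empty records, missing mostly in
#'     the positive class.}
#' }
#' Both are deterministic constants: calling again yields identical data.
#'
#' @param variant which toy to build
#' @return a \linkS4class{SparseSeriesSet}
#' @export
workedToy <- function(variant = c("one-third", "three-tenths")) {
  variant <- match.arg(variant)
  if (variant == "one-third") {
    pats <- list(
      p1 = c(-1.0, 1.2, 1.1, -0.9, 0.1, -0.2),
      p2 = c(-1.1, 0.9, 1.3, -1.0, -0.1),
      p3 = c(0.2, -1.2, 1.0, 1.2, -1.1, 0.3, -0.4),
      p4 = c(-0.9, 1.1, 0.9, -1.2, 0.5, 0.2),
      n1 = c(0.1, 0.3, -0.2, 0.2, -0.1, 0.4),
      n2 = c(1.5, 1.2, 0.8, 0.5, 0.1),
      n3 = c(-0.3, -0.1, 0.0, 0.2, 0.1, -0.2),
      n4 = c(0.4, 0.6, 0.2, -0.5, -0.3, 0.1, 0.2),
      n5 = c(-1.4, -1.0, -0.6, -0.1, 0.3),
      n6 = c(0.2, 0.1, 0.4, 0.3, 0.2, 0.5),
      n7 = c(0.9, -0.4, 0.2, -0.6, 0.8),
      n8 = c(-0.2, 0.5, -0.7, 0.4, -0.1, 0.3))
    labels <- stats::setNames(rep(c("pos", "neg"), c(4, 8)), names(pats))
    return(SparseSeriesSet(records = list(lab1 = pats), labels = labels))
  }
  pats <- list(
    p1 = numeric(0),
    p2 = numeric(0),
    p3 = c(-1.0, 1.1, 1.0, -1.1, 0.2),
    n1 = c(0.2, -0.1, 0.3, 0.1, -0.2, 0.0),
    n2 = c(1.1, 0.8, 0.4, 0.1, -0.3),
    n3 = c(-0.5, -0.2, 0.1, 0.4, 0.6),
    n4 = c(0.3, 0.2, 0.5, 0.1, 0.4, 0.2),
    n5 = numeric(0),
    n6 = c(-0.8, 0.6, -0.4, 0.5, -0.2),
    n7 = c(0.0, 0.2, -0.3, 0.1, 0.2))
  labels <- stats::setNames(rep(c("pos", "neg"), c(3, 7)), names(pats))
  SparseSeriesSet(records = list(lab1 = pats), labels = labels)
}
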