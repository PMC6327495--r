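#' Shannon entropy of a label multiset
#'
#' \code{-sum p_i log2 p_i} over the class proportions; classes with zero
#' probability contribute nothing. A 1:2 binary mix has entropy 0.918 bits,
#' a 3:7 mix 0.881 bits.
#'
#' @param labels non-empty vector of class labels
#' @return entropy in bits, a real >= 0
#' @export
labelEntropy <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty label multiset is undefined")
  p <- tabulate(factor(labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

.countsEntropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

.rowEntropy <- function(m) {
  n <- rowSums(m)
  p <- m / ifelse(n == 0, 1, n)
  lp <- ifelse(p > 0, log2(pmax(p, .Machine$double.xmin)), 0)
  -rowSums(p * lp)
}

#' Information gain of a partitioning
#'
#' Parent entropy minus the size-weighted mean entropy of the parts. The
#' parts must disjointly partition the parent multiset.
#'
#' @param parent label multiset
#' @param parts list of label multisets forming a disjoint partition of
#'   \code{parent}
#' @return information gain in bits, in [0, labelEntropy(parent)]
#' @examples
#' parent <- rep(c("pos", "neg"), c(4, 8))
#' partitionGain(parent, list(rep(c("pos", "neg"), c(4, 2)), rep("neg", 6)))
#' @export
partitionGain <- function(parent, parts) {
  pooled <- sort(as.character(unlist(parts)))
  if (!identical(pooled, sort(as.character(parent))))
    stop("parts do not disjointly partition the parent multiset")
  n <- length(parent)
  child <- sum(vapply(parts, function(p)
    if (length(p) == 0L) 0 else length(p) / n * labelEntropy(p), numeric(1)))
  labelEntropy(parent) - child
}

#' Subsequence distance to symbolic records
#'
#' The dissimilarity between a candidate subsequence \code{s} and each
#' target record: for a target at least as long as \code{s}, the minimum
#' edit distance between \code{s} and any contiguous window of the target of
#' length \code{nchar(s)} (making the measure invariant to the target's
#' length); for a shorter non-empty target, the edit distance of \code{s} to
#' the whole record. The distance never exceeds \code{nchar(s)} and is 0 iff
#' the target contains \code{s} exactly (for equal-or-longer targets). Empty
#' records (\code{NA}) yield \code{NA}: their treatment is strategy-specific
#' and handled by \code{\link{optimalSplit}} / \code{\link{transformFeatures}}.
#'
#' @param s non-empty candidate symbol string
#' @param targets character vector of symbolic records (\code{NA} = empty)
#' @param method window dissimilarity: Levenshtein edit distance (default)
#'   or Hamming
#' @return integer vector of distances
#' @examples
#' subsequenceDistance("ab", c("cabd", "bbbb"))  # 0, 1
#' @export
subsequenceDistance <- function(s, targets, method = c("levenshtein", "hamming")) {
  method <- match.arg(method)
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) < 1L)
    stop("candidate subsequence must be a single non-empty string")
  subseq_distance_cpp(s, as.character(targets), method == "hamming")
}

#' Sample candidate subsequences for one feature
#'
#' Draws snippets of the observed symbolic records of a feature: for each
#' draw, a length uniform in 1..l_max (l_max = longest record of the
#' feature), then a uniformly chosen eligible record (length >= the drawn
#' length), then a uniform start offset. When \code{count} meets or exceeds
#' the number of distinct (record, start, length) positions, all positions
#' are enumerated instead. Deterministic for a fixed seed.
#'
#' @param symbolic a \linkS4class{SymbolicSeriesSet}
#' @param feature feature id with at least one non-empty record
#' @param count candidate pool size (default 50)
#' @param seed integer seed
#' @return data.frame with columns \code{sequence}, \code{object_id},
#'   \code{start}, \code{length}
#' @export
sampleCandidates <- function(symbolic, feature, count = 50L, seed = 1L) {
  col <- records(symbolic, feature)
  col <- col[!is.na(col)]
  if (length(col) == 0L)
    stop("feature '", feature, "' has no non-empty records to sample from")
  lens <- nchar(col)
  lmax <- max(lens)
  total <- sum(lens * (lens + 1) / 2)
  if (count >= total) {
    rows <- lapply(seq_along(col), function(r) {
      len <- lens[r]
      grid <- do.call(rbind, lapply(seq_len(len), function(l)
        cbind(l = l, off = seq_len(len - l + 1L))))
      data.frame(sequence = substring(col[r], grid[, "off"], grid[, "off"] + grid[, "l"] - 1L),
                 object_id = names(col)[r], start = grid[, "off"], length = grid[, "l"],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  restore <- .localRNG(seed)
  on.exit(restore(), add = TRUE)
  l <- sample.int(lmax, count, replace = TRUE)
  recIdx <- integer(count)
  off <- integer(count)
  for (lv in sort(unique(l))) {
    draws <- which(l == lv)
    elig <- which(lens >= lv)
    recIdx[draws] <- elig[sample.int(length(elig), length(draws), replace = TRUE)]
    maxOff <- lens[recIdx[draws]] - lv + 1L
    off[draws] <- 1L + as.integer(floor(stats::runif(length(draws)) * maxOff))
  }
  data.frame(sequence = substring(col[recIdx], off, off + l - 1L),
             object_id = names(col)[recIdx], start = off, length = l,
             stringsAsFactors = FALSE)
}

# Scan every candidate threshold (all distinct observed distances plus
# max + 1) for the split {d < delta | d >= delta} maximizing information
# gain; ties go to the smallest delta.
.thresholdScan <- function(d, labels, classLevels) {
  ds <- sort(unique(d))
  thresholds <- c(ds, ds[length(ds)] + 1)
  tab <- table(factor(d, levels = ds), factor(labels, levels = classLevels))
  cum <- apply(tab, 2, cumsum)
  if (!is.matrix(cum))
    cum <- matrix(cum, nrow = 1, dimnames = list(NULL, classLevels))
  left <- rbind(rep(0, ncol(cum)), cum)      # row k: class counts with d < thresholds[k]
  totals <- left[nrow(left), ]
  right <- rep(totals, each = nrow(left)) - left
  n <- sum(totals)
  nL <- rowSums(left)
  parentH <- .countsEntropy(totals)
  gains <- parentH - (nL * .rowEntropy(left) + (n - nL) * .rowEntropy(right)) / n
  k <- which.max(gains)                      # first max: smallest delta wins ties
  list(delta = thresholds[k], gain = max(0, gains[k]), parentEntropy = parentH)
}

#' Optimal distance-threshold split for a candidate subsequence
#'
#' Computes the subsequence distance from \code{s} to every record of a
#' symbolic feature column and finds the distance threshold delta maximizing
#' the information gain of the induced two-way split (left: distance
#' strictly below delta; right: the rest). Candidate thresholds are all
#' distinct observed distances plus the maximum plus one. Empty records are
#' handled per strategy:
#' \describe{
#'   \item{plain}{an empty record is at distance \code{nchar(s)} and
#'     competes like any other record.}
#'   \item{mc}{empty records are excluded from the threshold search
#'     entirely (the parent multiset is the non-empty records).}
#'   \item{lr}{both placements of all empty records are evaluated -- left at
#'     distance 0, right at the maximum training distance (the largest
#'     distance over the whole column, empties entering at their default
#'     \code{nchar(s)}) -- and the better placement is kept; ties go left.}
#' }
#'
#' @param s non-empty candidate symbol string
#' @param column character vector of symbolic records (\code{NA} = empty)
#' @param labels class labels aligned with \code{column}
#' @param strategy "plain", "mc" or "lr"
#' @param method window dissimilarity, see \code{\link{subsequenceDistance}}
#' @return list with \code{delta} (optimal split distance), \code{gain}
#'   (bits), \code{emptySide} ("left", "right" or "none"),
#'   \code{emptyDistance} (the Dist(s, empty) value the strategy implies;
#'   \code{NA} for mc), and \code{parentEntropy}
#' @export
optimalSplit <- function(s, column, labels, strategy = c("plain", "mc", "lr"),
                         method = c("levenshtein", "hamming")) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  if (length(column) == 0L) stop("empty feature column")
  if (length(column) != length(labels)) stop("column and labels lengths differ")
  empty <- is.na(column)
  nE <- sum(empty)
  classLevels <- sort(unique(as.character(labels)))
  dObs <- subsequenceDistance(s, column[!empty], method)
  if (strategy == "mc") {
    if (nE == length(column))
      stop("all records are empty: no splittable mass under strategy mc")
    sc <- .thresholdScan(dObs, labels[!empty], classLevels)
    return(c(sc, list(emptySide = "none", emptyDistance = NA_real_)))
  }
  if (strategy == "plain") {
    d <- c(dObs, rep(nchar(s), nE))
    lab <- c(labels[!empty], labels[empty])
    sc <- .thresholdScan(d, lab, classLevels)
    return(c(sc, list(emptySide = "none", emptyDistance = as.numeric(nchar(s)))))
  }
  # lr
  if (nE == length(column))
    stop("all records are empty: no splittable mass under strategy lr")
  if (nE == 0L) {
    sc <- .thresholdScan(dObs, labels, classLevels)
    return(c(sc, list(emptySide = "none",
                      emptyDistance = as.numeric(max(dObs, nchar(s))))))
  }
  maxDist <- max(dObs, nchar(s))
  lab <- c(labels[!empty], labels[empty])
  scL <- .thresholdScan(c(dObs, rep(0, nE)), lab, classLevels)
  scR <- .thresholdScan(c(dObs, rep(maxDist, nE)), lab, classLevels)
  if (scR$gain > scL$gain)
    c(scR, list(emptySide = "right", emptyDistance = as.numeric(maxDist)))
  else
    c(scL, list(emptySide = "left", emptyDistance = 0))
}

# Modal subsequence distance over non-empty records (ties -> smallest value).
.modalDistance <- function(s, column, method = "levenshtein") {
  d <- subsequenceDistance(s, column[!is.na(column)], method)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])  # names sorted ascending; first max
}

#' Select the optimum s-shapelet for one feature across alphabet sizes
#'
#' For each alphabet size, every candidate is scored by the information gain
#' of its optimal split on the feature's symbolic column and the best is
#' kept (ties: shorter sequence, then lexicographically smaller). The
#' alphabet size of maximum utility then decides the winner (ties: smaller
#' alphabet). The winner's empty-record encoding is learned at the same
#' time: its own length under plain, the modal training distance under mc,
#' and the winning placement's distance under lr (the maximum training
#' distance when the training column had no empty records).
#'
#' @param symbolicByAlpha named list of \linkS4class{SymbolicSeriesSet},
#'   one per alphabet size (names = alphabet sizes)
#' @param feature feature id
#' @param candidatesByAlpha named list of candidate data.frames as returned
#'   by \code{\link{sampleCandidates}}, aligned with \code{symbolicByAlpha}
#' @param strategy "plain", "mc" or "lr"
#' @param method window dissimilarity, see \code{\link{subsequenceDistance}}
#' @return an \linkS4class{SShapelet}
#' @export
selectShapelet <- function(symbolicByAlpha, feature, candidatesByAlpha,
                           strategy = c("plain", "mc", "lr"),
                           method = c("levenshtein", "hamming")) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  alphas <- sort(as.integer(names(symbolicByAlpha)))
  best <- NULL
  for (a in alphas) {
    symb <- symbolicByAlpha[[as.character(a)]]
    column <- records(symb, feature)
    labels <- classLabels(symb)
    seqs <- unique(candidatesByAlpha[[as.character(a)]]$sequence)
    if (length(seqs) == 0L) next
    # deterministic candidate order: shorter first, then lexicographic, so
    # that the first maximum respects the documented tie-break
    seqs <- seqs[order(nchar(seqs), seqs)]
    evals <- lapply(seqs, optimalSplit, column = column, labels = labels,
                    strategy = strategy, method = method)
    gains <- vapply(evals, `[[`, numeric(1), "gain")
    k <- which.max(gains)
    if (is.null(best) || gains[k] > best$gain + 1e-12) {
      e <- evals[[k]]
      best <- list(alpha = a, sequence = seqs[k], delta = e$delta,
                   gain = gains[k], emptySide = e$emptySide,
                   emptyDistance = e$emptyDistance, column = column)
    }
  }
  if (is.null(best)) stop("no candidates available for feature '", feature, "'")
  enc <- switch(strategy,
    plain = as.numeric(nchar(best$sequence)),
    mc = .modalDistance(best$sequence, best$column, method),
    lr = best$emptyDistance)
  new("SShapelet", featureId = feature, sequence = best$sequence,
      alphabetSize = as.integer(best$alpha), deltaOsp = as.numeric(best$delta),
      gain = as.numeric(best$gain), strategy = strategy,
      emptySide = best$emptySide, emptyEncoding = enc)
}

# Stable per-(feature, alphabet) sub-seed below 2^31.
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65521 * 32749 + i * 9973) %% 2147483647) + 1L
}

#' Discover one s-shapelet per retained feature (Phase B)
#'
#' Runs the sparsity filter, discretizes the dataset once per alphabet size,
#' samples a candidate pool per (feature, alphabet) and selects the optimum
#' s-shapelet per feature. Deterministic under a fixed seed.
#'
#' @param dataset a \linkS4class{SparseSeriesSet} with >= 2 classes
#' @param strategy "plain", "mc" or "lr"
#' @param tauSp sparsity tolerance in (0, 1]: a feature is retained when its
#'   fraction of empty records is at most \code{tauSp} and it has at least
#'   one non-empty record
#' @param alphabetSizes candidate SAX alphabet sizes (default 2, 3, 5)
#' @param paaRatio PAA compression ratio (default 1, disabled)
#' @param candidatesPerFeature candidate pool size per (feature, alphabet)
#' @param seed integer seed driving all candidate sampling
#' @param method window dissimilarity, see \code{\link{subsequenceDistance}}
#' @return named list of \linkS4class{SShapelet}, one per retained feature
#' @export
discoverShapelets <- function(dataset, strategy = c("plain", "mc", "lr"),
                              tauSp = 1.0, alphabetSizes = c(2L, 3L, 5L),
                              paaRatio = 1, candidatesPerFeature = 50L,
                              seed = 1L, method = c("levenshtein", "hamming")) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  retained <- filterFeatures(dataset, tauSp)
  if (length(retained) == 0L) stop("no features survive the sparsity filter")
  alphabetSizes <- sort(as.integer(alphabetSizes))
  symbolicByAlpha <- stats::setNames(
    lapply(alphabetSizes, function(a) discretize(dataset, a, paaRatio)),
    alphabetSizes)
  out <- stats::setNames(vector("list", length(retained)), retained)
  for (fi in seq_along(retained)) {
    f <- retained[fi]
    cands <- stats::setNames(lapply(seq_along(alphabetSizes), function(ai) {
      sampleCandidates(symbolicByAlpha[[ai]], f, candidatesPerFeature,
                       seed = .deriveSeed(seed, fi * 101L + ai))
    }), alphabetSizes)
    out[[f]] <- selectShapelet(symbolicByAlpha, f, cands, strategy, method)
  }
  out
}
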