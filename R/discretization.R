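#' SAX alphabet with Gaussian-equiprobable breakpoints
#'
#' Builds the alphabet used by \code{\link{sax}}: the first \code{size}
#' lowercase letters, and \code{size - 1} ascending breakpoints chosen so
#' that each of the \code{size} regions has probability 1/size under the
#' standard normal (so for size 2 the single breakpoint is 0, i.e. simply
#' below or above the mean).
#'
#' @param size alphabet size, an integer in 2..26
#' @return list with elements \code{size}, \code{symbols}, \code{breakpoints}
#' @examples
#' saxAlphabet(3)$breakpoints  # c(-0.4307..., 0.4307...)
#' @export
saxAlphabet <- function(size) {
  size <- as.integer(size)
  if (is.na(size) || size < 2L || size > 26L)
    stop("alphabet size must be an integer in 2..26")
  list(size = size,
       symbols = letters[seq_len(size)],
       breakpoints = qnorm(seq_len(size - 1L) / size))
}

#' z-normalize a series
#'
#' Subtracts the mean and divides by the population (1/n) standard
#' deviation. A zero-variance series (including a single point) returns all
#' zeros rather than failing: constant lab series are legitimate records and
#' must survive to shapelet discovery.
#'
#' @param series non-empty numeric vector
#' @return numeric vector of the same length with mean 0 and population sd 1
#'   (or all zeros when the input has zero variance)
#' @export
znormalize <- function(series) {
  if (length(series) == 0L) stop("cannot z-normalize an empty series")
  mu <- mean(series)
  sdp <- sqrt(mean((series - mu)^2))
  if (sdp == 0) return(rep(0, length(series)))
  (series - mu) / sdp
}

#' Piecewise aggregate approximation (PAA)
#'
#' Compresses a length-d series to w = ceiling(ratio * d) partition means.
#' With \code{ratio = 1} the series is returned unchanged (PAA disabled, the
#' default throughout: symbolic sequences then keep their variable lengths).
#' When w divides d the partitions are contiguous blocks of d/w points;
#' otherwise each point at index j joins partition ceiling(j * w / d)
#' (equal-width real-valued partitioning).
#'
#' @param series non-empty numeric vector
#' @param ratio compression ratio in (0, 1]
#' @return numeric vector of length ceiling(ratio * length(series))
#' @examples
#' paa(c(1, 2, 3, 4), 0.5)  # c(1.5, 3.5)
#' @export
paa <- function(series, ratio = 1) {
  d <- length(series)
  if (d == 0L) stop("cannot summarize an empty series")
  if (ratio <= 0 || ratio > 1) stop("PAA ratio must be in (0, 1]")
  if (ratio == 1) return(series)
  w <- ceiling(ratio * d)
  part <- ceiling(seq_len(d) * w / d)
  as.numeric(tapply(series, part, mean))
}

#' SAX symbolic mapping
#'
#' Maps each value of a (z-normalized, PAA-reduced) series to a symbol: a
#' value v maps to symbol k when breakpoint k-1 <= v < breakpoint k, with the
#' first symbol for values below the first breakpoint. Values exactly equal
#' to a breakpoint map to the upper region.
#'
#' @param series numeric vector (typically znormalize + paa output)
#' @param alphabet a \code{\link{saxAlphabet}} or an alphabet size
#' @return a single symbol string of the same length as the input
#' @examples
#' sax(c(-1, 0, 1), 3)  # "abc"
#' @export
sax <- function(series, alphabet) {
  if (is.numeric(alphabet) && length(alphabet) == 1L) alphabet <- saxAlphabet(alphabet)
  idx <- findInterval(series, alphabet$breakpoints) + 1L
  paste(alphabet$symbols[idx], collapse = "")
}

#' Discretize every record of a SparseSeriesSet (Phase A)
#'
#' Applies znormalize, then PAA, then SAX to every non-empty record; empty
#' records stay empty (the \code{NA} marker). Each record is discretized
#' independently of all others (no cross-record leakage), and labels are
#' carried through unchanged.
#'
#' @param x a \linkS4class{SparseSeriesSet}
#' @param alphabetSize SAX alphabet size (integer >= 2)
#' @param paaRatio PAA compression ratio in (0, 1]; 1 disables PAA
#' @param ... unused
#' @return a \linkS4class{SymbolicSeriesSet}
#' @export
setMethod("discretize", "SparseSeriesSet", function(x, alphabetSize = 3L,
                                                    paaRatio = 1, ...) {
  ab <- saxAlphabet(alphabetSize)
  recs <- lapply(x@records, function(col) {
    out <- vapply(col, function(v) {
      if (length(v) == 0L) NA_character_
      else sax(paa(znormalize(v), paaRatio), ab)
    }, character(1))
    stats::setNames(out, names(col))
  })
  new("SymbolicSeriesSet", records = recs, labels = x@labels,
      featureIds = x@featureIds, objectIds = x@objectIds,
      alphabetSize = ab$size, paaRatio = as.numeric(paaRatio))
})
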