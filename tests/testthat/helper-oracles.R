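# Independent oracles used to cross-check the implementation.
# They deliberately use a different route: utils::adist for edit distance,
# explicit window enumeration, explicit loops over thresholds/placements,
# and a locally inlined entropy formula.

oracleSubseqDistance <- function(s, target) {
  ns <- nchar(s)
  nt <- nchar(target)
  if (nt < ns) return(as.integer(utils::adist(s, target)))
  wins <- substring(target, seq_len(nt - ns + 1L), seq_len(nt - ns + 1L) + ns - 1L)
  min(utils::adist(s, wins))
}

oracleEntropy <- function(labels) {
  if (length(labels) == 0L) return(0)
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Exhaustive threshold scan on a distance vector.
oracleScan <- function(d, labels) {
  ths <- c(sort(unique(d)), max(d) + 1)
  n <- length(labels)
  parentH <- oracleEntropy(labels)
  best <- NULL
  for (th in ths) {
    left <- labels[d < th]
    right <- labels[d >= th]
    g <- parentH - (length(left) * oracleEntropy(left) +
                    length(right) * oracleEntropy(right)) / n
    if (is.null(best) || g > best$gain + 1e-12) best <- list(delta = th, gain = g)
  }
  best
}

# Exhaustive optimal split over all thresholds and (for lr) both placements.
oracleOptimalSplit <- function(s, column, labels, strategy) {
  empty <- is.na(column)
  dObs <- vapply(column[!empty], oracleSubseqDistance, numeric(1), s = s)
  nE <- sum(empty)
  if (strategy == "mc") {
    return(c(oracleScan(dObs, labels[!empty]),
             list(emptySide = "none")))
  }
  if (strategy == "plain") {
    return(c(oracleScan(c(dObs, rep(nchar(s), nE)),
                        c(labels[!empty], labels[empty])),
             list(emptySide = "none")))
  }
  if (nE == 0L) return(c(oracleScan(dObs, labels), list(emptySide = "none")))
  M <- max(dObs, nchar(s))
  lab <- c(labels[!empty], labels[empty])
  left <- oracleScan(c(dObs, rep(0, nE)), lab)
  right <- oracleScan(c(dObs, rep(M, nE)), lab)
  if (right$gain > left$gain + 1e-12) c(right, list(emptySide = "right"))
  else c(left, list(emptySide = "left"))
}

randomSymbolString <- function(len, alpha) {
  paste(sample(letters[seq_len(alpha)], len, replace = TRUE), collapse = "")
}

# Random labelled symbolic column with a controllable fraction of empties.
randomColumn <- function(nRecords, alpha, emptyFrac = 0.25, maxLen = 8L) {
  col <- vapply(seq_len(nRecords), function(i) {
    if (stats::runif(1) < emptyFrac) NA_character_
    else randomSymbolString(sample.int(maxLen, 1L), alpha)
  }, character(1))
  if (all(is.na(col))) col[1] <- randomSymbolString(3L, alpha)
  labels <- sample(c("pos", "neg"), nRecords, replace = TRUE)
  if (length(unique(labels)) == 1L) labels[1] <- setdiff(c("pos", "neg"), labels[1])
  list(column = col, labels = labels)
}

# Small fully in-code dataset used by several suites.
tinyDataset <- function() {
  SparseSeriesSet(
    records = list(
      labA = list(o1 = c(1, 2, 3, 4), o2 = c(5, 5, 5), o3 = numeric(0),
                  o4 = c(2, 1), o5 = c(0.5, 1.5, -1)),
      labB = list(o1 = numeric(0), o2 = c(1, 0, 1), o3 = c(4, 2),
                  o4 = c(3, 3, 2, 1), o5 = numeric(0))),
    labels = c(o1 = "case", o2 = "control", o3 = "case", o4 = "control",
               o5 = "control"))
}
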