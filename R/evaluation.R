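#' Random-forest classifier factory
#'
#' The default classifier behind the evaluation harness: a random forest
#' with 100 trees and sqrt(m) features per split, matching the evaluation
#' protocol's configuration (the impurity split criterion is the engine's
#' Gini index). The harness is model agnostic: any function with the same
#' factory signature can be plugged in.
#'
#' @param numTrees number of trees (default 100)
#' @return a function \code{(x, y, seed)} returning a scoring function
#'   \code{(newx) -> numeric} of positive-class probabilities; the positive
#'   class is the second factor level of \code{y}
#' @export
randomForestClassifier <- function(numTrees = 100L) {
  function(x, y, seed) {
    fit <- ranger::ranger(x = x, y = y, num.trees = numTrees,
                          mtry = max(1L, floor(sqrt(ncol(x)))),
                          probability = TRUE, seed = seed, num.threads = 1L)
    pos <- levels(y)[2]
    function(newx) predict(fit, data = newx, num.threads = 1L)$predictions[, pos]
  }
}

# AUC of scores for the positive class, midrank tie handling.
.scoreAUC <- function(truth, scores, positive) {
  resp <- factor(ifelse(truth == positive, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(response = resp, predictor = scores, levels = c("neg", "pos"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Stratified fold assignment: within each class, shuffled round-robin.
.stratifiedFolds <- function(labels, folds, seed) {
  counts <- table(labels)
  if (min(counts) < folds)
    stop("a class has fewer members (", min(counts), ") than folds (", folds, ")")
  restore <- .localRNG(seed)
  on.exit(restore(), add = TRUE)
  assign <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    assign[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated AUC of one strategy
#'
#' For each fold: fit the transformation on the training split only,
#' transform both splits, train the classifier on the transformed training
#' split and score AUC on the held-out split. No test-fold record ever
#' influences shapelet selection, modal distances or empty-record encodings.
#'
#' @param dataset a binary-labelled \linkS4class{SparseSeriesSet}
#' @param strategy "plain", "mc", "lr" or "sl"
#' @param folds number of stratified folds (default 10)
#' @param tauSp,alphabetSizes,paaRatio,candidatesPerFeature,method passed to
#'   \code{\link{fitShapeletModel}}
#' @param seed seed for candidate sampling (and the classifier)
#' @param foldSeed separate seed for fold assignment (defaults to
#'   \code{seed + 1}) so sampling and fold variability can be varied
#'   independently
#' @param positive positive class label; defaults to the last label in sort
#'   order ("pos" when labels are "pos"/"neg")
#' @param classifier classifier factory, see
#'   \code{\link{randomForestClassifier}}
#' @return list with \code{meanAUC}, \code{foldAUC} (length \code{folds}),
#'   \code{folds}, \code{strategy}, \code{tauSp}
#' @export
crossValidate <- function(dataset, strategy, folds = 10L, tauSp = 1.0,
                          alphabetSizes = c(2L, 3L, 5L), paaRatio = 1,
                          candidatesPerFeature = 50L, seed = 1L,
                          foldSeed = NULL, positive = NULL,
                          classifier = randomForestClassifier(),
                          method = "levenshtein") {
  labels <- classLabels(dataset)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("cross-validated AUC requires binary labels")
  if (is.null(positive)) positive <- lev[2]
  if (is.null(foldSeed)) foldSeed <- as.integer(seed) + 1L
  assign <- .stratifiedFolds(labels, folds, foldSeed)
  foldAUC <- numeric(folds)
  for (k in seq_len(folds)) {
    trainSet <- dataset[assign != k]
    testSet <- dataset[assign == k]
    model <- fitShapeletModel(trainSet, strategy, tauSp = tauSp,
                              alphabetSizes = alphabetSizes,
                              paaRatio = paaRatio,
                              candidatesPerFeature = candidatesPerFeature,
                              seed = seed, method = method)
    trainFM <- transformFeatures(model, trainSet)
    testFM <- transformFeatures(model, testSet)
    featCols <- setdiff(names(trainFM), c("object_id", "label"))
    y <- factor(trainFM$label, levels = c(setdiff(lev, positive), positive))
    score <- classifier(trainFM[, featCols, drop = FALSE], y, seed)
    s <- score(testFM[, featCols, drop = FALSE])
    foldAUC[k] <- .scoreAUC(testFM$label, s, positive)
  }
  list(meanAUC = mean(foldAUC), foldAUC = foldAUC, folds = folds,
       strategy = strategy, tauSp = tauSp)
}

#' Sweep the sparsity tolerance over strategies
#'
#' Cross-validates every (strategy, tauSp) combination on one dataset and
#' returns the per-fold AUCs in long format; \code{summary = TRUE} collapses
#' to mean AUC per cell.
#'
#' @param dataset a binary-labelled \linkS4class{SparseSeriesSet}
#' @param strategies character vector of strategies to compare
#' @param tauGrid sparsity tolerances to sweep (default the canonical grid
#'   0.2, 0.3, 0.5, 0.7, 0.9, 0.95, 1.0)
#' @param ... passed to \code{\link{crossValidate}}
#' @param summary return one row per (strategy, tauSp) with mean AUC
#'   instead of per-fold rows
#' @param path optional CSV path to write the table to
#' @return data.frame with columns \code{strategy}, \code{tau_sp},
#'   \code{fold}, \code{auc} (or \code{strategy}, \code{tau_sp},
#'   \code{mean_auc} when \code{summary})
#' @export
sparsitySweep <- function(dataset, strategies = c("sl", "plain", "mc", "lr"),
                          tauGrid = c(0.2, 0.3, 0.5, 0.7, 0.9, 0.95, 1.0),
                          ..., summary = FALSE, path = NULL) {
  if (any(tauGrid <= 0 | tauGrid > 1)) stop("tauGrid values must be in (0, 1]")
  rows <- list()
  for (st in strategies) {
    for (tau in tauGrid) {
      cv <- crossValidate(dataset, st, tauSp = tau, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = st, tau_sp = tau, fold = seq_along(cv$foldAUC),
        auc = cv$foldAUC, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (summary)
    out <- stats::aggregate(list(mean_auc = out$auc),
                            by = list(strategy = out$strategy, tau_sp = out$tau_sp),
                            FUN = mean)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Paired comparison of two result vectors
#'
#' Tallies per-pair wins and runs the two-sided Wilcoxon signed-rank test on
#' the paired differences, with rejection decided at alpha = 0.05. When all
#' pairs are tied (identical vectors) there is no evidence against equality:
#' p is reported as 1 with a warning.
#'
#' @param a,b paired numeric result vectors (e.g. per-dataset AUCs), equal
#'   length >= 5
#' @param names labels for the two methods (used in \code{winnerLabel})
#' @return list with \code{winsA}, \code{winsB}, \code{ties},
#'   \code{p.value}, \code{reject} (at 0.05), and \code{winnerLabel} in the
#'   style \code{"lr (10)"}
#' @export
pairedComparison <- function(a, b, names = c("A", "B")) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  winsA <- sum(a > b)
  winsB <- sum(b > a)
  ties <- sum(a == b)
  if (all(a == b)) {
    warning("all pairs tied; no evidence against equality")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                      alternative = "two.sided")$p.value)
  }
  winner <- if (winsA >= winsB) sprintf("%s (%d)", names[1], winsA)
            else sprintf("%s (%d)", names[2], winsB)
  list(winsA = winsA, winsB = winsB, ties = ties, p.value = p,
       reject = is.finite(p) && p < 0.05, winnerLabel = winner)
}
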