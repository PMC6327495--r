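test_that("the sparsity filter is inclusive at the threshold and drops empty features", {
  recs <- list(
    ok    = stats::setNames(c(rep(list(numeric(0)), 2), rep(list(c(1, 2)), 8)),
                            paste0("o", 1:10)),
    full  = stats::setNames(rep(list(c(3, 1)), 10), paste0("o", 1:10)),
    dead  = stats::setNames(rep(list(numeric(0)), 10), paste0("o", 1:10)))
  x <- SparseSeriesSet(recs, stats::setNames(rep(c("a", "b"), 5), paste0("o", 1:10)))
  expect_setequal(filterFeatures(x, 0.2), c("ok", "full"))   # 0.2 is inclusive
  expect_equal(filterFeatures(x, 0.1), "full")
  expect_setequal(filterFeatures(x, 1.0), c("ok", "full"))   # fully empty dropped
  expect_error(filterFeatures(x, 0), "tauSp")
})

test_that("fitting requires two classes and survives feature filtering", {
  x <- simulateSparseSeries(n = 30L, seed = 2L)
  oneClass <- x
  oneClass@labels[] <- "same"
  expect_error(fitShapeletModel(oneClass, "plain"), "two classes")
  model <- fitShapeletModel(x, "plain", seed = 3L)
  expect_s4_class(model, "ShapeletModel")
  expect_equal(length(model@shapelets), length(model@featureIds))
  slModel <- fitShapeletModel(x, "sl", seed = 3L)
  expect_length(slModel@shapelets, 0L)
})

test_that("transform encodes records as shapelet distances with learned empty encodings", {
  x <- tinyDataset()
  for (st in c("plain", "mc", "lr")) {
    model <- fitShapeletModel(x, st, seed = 11L)
    fm <- transformFeatures(model, x)
    expect_false(anyNA(fm))
    vals <- as.matrix(fm[, model@featureIds])
    expect_true(all(vals >= 0))
    # for each retained feature some training object attains a low distance:
    # the shapelet's own source record contains it (distance 0) unless an
    # empty encoding overrode the column
    for (z in model@shapelets) {
      col <- fm[[z@featureId]]
      nonEmptyIdx <- vapply(records(x, z@featureId), length, integer(1)) > 0
      expect_lte(min(col[nonEmptyIdx]), nchar(z@sequence))
    }
    # empty records receive exactly the learned encoding
    for (z in model@shapelets) {
      emptyIdx <- vapply(records(x, z@featureId), length, integer(1)) == 0
      if (any(emptyIdx))
        expect_true(all(fm[[z@featureId]][emptyIdx] == z@emptyEncoding))
    }
  }
})

test_that("strategy-specific empty encodings match their definitions", {
  x <- tinyDataset()
  mPlain <- fitShapeletModel(x, "plain", seed = 1L)
  for (z in mPlain@shapelets)
    expect_equal(z@emptyEncoding, nchar(z@sequence))
  mMc <- fitShapeletModel(x, "mc", seed = 1L)
  symb <- lapply(stats::setNames(mMc@alphabetSizes, mMc@alphabetSizes),
                 function(a) discretize(x, a))
  for (z in mMc@shapelets) {
    col <- records(symb[[as.character(z@alphabetSize)]], z@featureId)
    d <- subsequenceDistance(z@sequence, col[!is.na(col)])
    tab <- table(d)
    expect_equal(z@emptyEncoding, as.numeric(names(tab)[which.max(tab)]))
  }
  mLr <- fitShapeletModel(x, "lr", seed = 1L)
  for (z in mLr@shapelets) {
    if (z@emptySide == "left") expect_equal(z@emptyEncoding, 0)
    else expect_gte(z@emptyEncoding, 1)
  }
})

test_that("the sl baseline encodes raw lengths and ignores measurement values", {
  x <- tinyDataset()
  model <- fitShapeletModel(x, "sl")
  fm <- transformFeatures(model, x)
  for (f in model@featureIds)
    expect_equal(fm[[f]], unname(vapply(records(x, f), length, integer(1)) + 0))
  # change all values, keep lengths: sl output unchanged
  recs <- lapply(x@records, function(col) lapply(col, function(v) v * 10 + 3))
  x2 <- SparseSeriesSet(recs, classLabels(x))
  fm2 <- transformFeatures(model, x2)
  expect_equal(fm2[, model@featureIds], fm[, model@featureIds])
})

test_that("transform of unseen data uses training state only and follows row order", {
  train <- simulateSparseSeries(n = 40L, seed = 13L)
  test <- simulateSparseSeries(n = 20L, seed = 14L)
  model <- fitShapeletModel(train, "lr", seed = 13L)
  fm <- transformFeatures(model, test)
  expect_equal(fm$object_id, objectIds(test))
  # permuting test rows permutes output rows identically
  perm <- rev(objectIds(test))
  fmPerm <- transformFeatures(model, test[perm])
  reindexed <- fm[match(perm, fm$object_id), ]
  rownames(reindexed) <- NULL
  expect_equal(fmPerm, reindexed)
  # refitting on the same training data is unaffected by the test set
  expect_identical(model@shapelets[[1]]@sequence,
                   fitShapeletModel(train, "lr", seed = 13L)@shapelets[[1]]@sequence)
})

test_that("a record containing its shapelet exactly transforms to zero", {
  x <- tinyDataset()
  model <- fitShapeletModel(x, "plain", seed = 2L)
  z <- model@shapelets[[1]]
  symb <- discretize(x, z@alphabetSize)
  col <- records(symb, z@featureId)
  hits <- names(col)[!is.na(col) & vapply(col, function(t)
    !is.na(t) && grepl(z@sequence, t, fixed = TRUE), logical(1))]
  fm <- transformFeatures(model, x)
  for (o in hits)
    expect_equal(fm[[z@featureId]][fm$object_id == o], 0)
})

test_that("model serialization round trips and is seed-sensitive", {
  x <- simulateSparseSeries(n = 30L, seed = 21L)
  model <- fitShapeletModel(x, "lr", seed = 7L)
  p1 <- withr::local_tempfile(fileext = ".json")
  writeShapeletModel(model, p1)
  back <- readShapeletModel(p1)
  expect_equal(transformFeatures(back, x), transformFeatures(model, x))
  # same seed -> byte-identical documents
  p2 <- withr::local_tempfile(fileext = ".json")
  writeShapeletModel(fitShapeletModel(x, "lr", seed = 7L), p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed -> different document
  p3 <- withr::local_tempfile(fileext = ".json")
  writeShapeletModel(fitShapeletModel(x, "lr", seed = 8L), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
  # truncated JSON errors
  txt <- readLines(p1)
  p4 <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], p4)
  expect_error(readShapeletModel(p4), "parse")
})
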