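test_that("long-format reading builds sorted records and all-empty fills", {
  mdir <- withr::local_tempdir()
  mpath <- file.path(mdir, "m.csv")
  lpath <- file.path(mdir, "l.csv")
  writeLines(c(
    "object_id,feature_id,time,value",
    "p1,crp,2,10.5",
    "p1,crp,1,9.0",
    "p1,crp,3,11.0",
    "p2,crp,1,4.0",
    "p1,na,1,140"), mpath)
  writeLines(c("object_id,label", "p1,case", "p2,control", "p3,control"), lpath)
  x <- readLongCSV(mpath, lpath)
  expect_equal(nObjects(x), 3L)
  expect_equal(nFeatures(x), 2L)
  # out-of-order times are sorted ascending
  expect_equal(records(x, "crp")[["p1"]], c(9.0, 10.5, 11.0))
  # object in labels but not measurements gets all-empty records
  expect_length(records(x, "crp")[["p3"]], 0L)
  expect_length(records(x, "na")[["p2"]], 0L)
  expect_equal(unname(classLabels(x)["p3"]), "control")
})

test_that("duplicate timestamps keep file order and unlabeled objects error", {
  mdir <- withr::local_tempdir()
  mpath <- file.path(mdir, "m.csv")
  lpath <- file.path(mdir, "l.csv")
  writeLines(c("object_id,feature_id,time,value",
               "p1,crp,1,5", "p1,crp,1,7", "p1,crp,0,3"), mpath)
  writeLines(c("object_id,label", "p1,case", "p2,control"), lpath)
  x <- readLongCSV(mpath, lpath)
  expect_equal(records(x, "crp")[["p1"]], c(3, 5, 7))

  writeLines(c("object_id,feature_id,time,value", "ghost,crp,1,5"), mpath)
  expect_error(readLongCSV(mpath, lpath), "missing from labels")

  writeLines(c("object_id,feature_id,time,value", "p1,crp,notatime,5"), mpath)
  expect_error(readLongCSV(mpath, lpath), "non-numeric time at data line 1")
})

test_that("empty measurements file yields an all-empty labelled dataset", {
  mdir <- withr::local_tempdir()
  mpath <- file.path(mdir, "m.csv")
  lpath <- file.path(mdir, "l.csv")
  writeLines("object_id,feature_id,time,value", mpath)
  writeLines(c("object_id,label", "a,x", "b,y", "c,x"), lpath)
  x <- readLongCSV(mpath, lpath)
  expect_equal(nObjects(x), 3L)
  expect_true(all(vapply(records(x, featureIds(x)[1]), length, integer(1)) == 0L))
})

test_that("read -> write -> read round trip is the identity", {
  x <- simulateSparseSeries(n = 25L, m = 3L, roles = c("motif", "sparsity", "noise"),
                            seed = 11L)
  mdir <- withr::local_tempdir()
  mpath <- file.path(mdir, "m.csv")
  lpath <- file.path(mdir, "l.csv")
  writeLongCSV(x, mpath, lpath, shuffle = TRUE, jitter = TRUE, seed = 4L)
  y <- readLongCSV(mpath, lpath)
  expect_equal(sort(objectIds(y)), sort(objectIds(x)))
  expect_equal(classLabels(y)[objectIds(x)], classLabels(x))
  for (f in featureIds(x)) {
    # features with no measurements anywhere cannot reappear, but sampled
    # data always has some; compare record by record
    expect_true(f %in% featureIds(y))
    for (o in objectIds(x))
      expect_equal(records(y, f)[[o]], records(x, f)[[o]], tolerance = 1e-9)
  }
})

test_that("sparsityFraction counts empty records and rejects unknown features", {
  recs <- list(f = stats::setNames(
    c(rep(list(numeric(0)), 2), rep(list(c(1, 2)), 8)), paste0("o", 1:10)))
  x <- SparseSeriesSet(recs, stats::setNames(rep(c("a", "b"), 5), paste0("o", 1:10)))
  expect_equal(sparsityFraction(x, "f"), 0.2)
  expect_error(sparsityFraction(x, "nope"), "unknown feature")
  # invariant to object ordering
  y <- x[rev(objectIds(x))]
  expect_equal(sparsityFraction(y, "f"), 0.2)
})

test_that("feature matrix writing refuses degenerate input and round trips", {
  fm <- data.frame(object_id = c("a", "b", "c"),
                   f1 = c(0.5, 2.25, 4), f2 = c(1, 0, 3.5),
                   label = c("x", "y", "x"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureMatrix(fm, path)
  back <- readFeatureMatrix(path)
  expect_equal(back$f1, fm$f1)
  expect_equal(back$f2, fm$f2)
  expect_equal(back$label, fm$label)

  expect_error(writeFeatureMatrix(fm[, c("object_id", "label")], "x.csv"),
               "no feature columns")
  fm$f1[2] <- NaN
  expect_error(writeFeatureMatrix(fm, path), "non-finite")
})

test_that("container validity catches inconsistent construction", {
  expect_error(new("SparseSeriesSet",
                   records = list(f = list(o1 = c(1, 2))),
                   labels = c(o1 = "a", o2 = "b"),
                   featureIds = "f", objectIds = c("o1", "o2")),
               "named by objectIds")
  expect_error(SparseSeriesSet(records = list(f = list(o1 = c(1, 2))),
                               labels = c(o1 = NA)),
               "NA")
})
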