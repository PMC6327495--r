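symbolicFromStrings <- function(strings, labels, alpha = 2L) {
  ids <- paste0("o", seq_along(strings))
  new("SymbolicSeriesSet",
      records = list(f = stats::setNames(strings, ids)),
      labels = stats::setNames(labels, ids),
      featureIds = "f", objectIds = ids,
      alphabetSize = as.integer(alpha), paaRatio = 1)
}

test_that("candidates from a single short record enumerate its substrings", {
  symb <- symbolicFromStrings(c("abc", NA), c("x", "y"), alpha = 3L)
  cands <- sampleCandidates(symb, "f", count = 1000L, seed = 1L)
  expect_setequal(unique(cands$sequence), c("a", "b", "c", "ab", "bc", "abc"))
  expect_equal(nrow(cands), 6L)  # all (record, start, length) positions
})

test_that("candidate sampling is deterministic and respects record bounds", {
  symb <- symbolicFromStrings(c("ababab", "babab", "aaaa", NA),
                              c("x", "y", "x", "y"))
  c1 <- sampleCandidates(symb, "f", count = 30L, seed = 9L)
  c2 <- sampleCandidates(symb, "f", count = 30L, seed = 9L)
  expect_identical(c1, c2)
  c3 <- sampleCandidates(symb, "f", count = 30L, seed = 10L)
  expect_false(identical(c1, c3))
  expect_equal(nrow(c1), 30L)
  # every candidate is a substring of its source record
  for (i in seq_len(nrow(c1))) {
    src <- records(symb, "f")[[c1$object_id[i]]]
    expect_identical(substr(src, c1$start[i], c1$start[i] + c1$length[i] - 1L),
                     c1$sequence[i])
  }
  expect_error(sampleCandidates(symbolicFromStrings(NA_character_, "x"), "f"),
               "no non-empty records")
})

test_that("sampled candidate lengths are approximately uniform in 1..l_max", {
  # enough records that 10,000 draws stay in the sampling (not enumeration)
  # regime: 1800 records of length 3 offer 10,800 distinct positions
  strings <- rep("aba", 1800)
  symb <- symbolicFromStrings(strings, rep(c("x", "y"), 900))
  cands <- sampleCandidates(symb, "f", count = 10000L, seed = 3L)
  tab <- table(factor(cands$length, levels = 1:3))
  p <- stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.001)
})

test_that("a single candidate and alphabet is selected as-is", {
  symb <- symbolicFromStrings(c("abba", "bbbb", "abab"), c("p", "n", "p"))
  z <- selectShapelet(list(`2` = symb), "f",
                      list(`2` = data.frame(sequence = "ab", object_id = "o1",
                                            start = 1L, length = 2L)),
                      strategy = "plain")
  expect_s4_class(z, "SShapelet")
  expect_equal(z@sequence, "ab")
  expect_equal(z@alphabetSize, 2L)
  expect_equal(z@emptyEncoding, 2)  # plain: |s*|
})

test_that("gain ties across alphabets resolve to the smaller alphabet", {
  # identical columns under both alphabets; same candidate; equal gains
  s2 <- symbolicFromStrings(c("aa", "ab", "bb", "ba"), c("p", "p", "n", "n"), 2L)
  s3 <- symbolicFromStrings(c("aa", "ab", "cc", "ca"), c("p", "p", "n", "n"), 3L)
  cand <- data.frame(sequence = "a", object_id = "o1", start = 1L, length = 1L)
  z <- selectShapelet(list(`2` = s2, `3` = s3), "f",
                      list(`2` = cand, `3` = cand), strategy = "plain")
  expect_equal(z@alphabetSize, 2L)
})

test_that("a planted class-exclusive motif is recovered with high gain", {
  x <- simulateSparseSeries(n = 150L, m = 3L,
                            roles = c("motif", "noise", "noise"),
                            qPos = 0, qNeg = 0, qNoise = 0, seed = 31L)
  zs <- discoverShapelets(x, "lr", candidatesPerFeature = 100L, seed = 31L)
  H <- labelEntropy(classLabels(x))
  expect_gte(zs[["f1.motif"]]@gain, 0.9 * H)
  # informative feature beats the noise features
  expect_gt(zs[["f1.motif"]]@gain,
            max(zs[["f2.noise"]]@gain, zs[["f3.noise"]]@gain))
})

test_that("discovery returns one shapelet per retained feature, deterministically", {
  x <- simulateSparseSeries(n = 40L, m = 4L,
                            roles = c("motif", "sparsity", "noise", "noise"),
                            seed = 5L)
  z1 <- discoverShapelets(x, "plain", seed = 77L)
  z2 <- discoverShapelets(x, "plain", seed = 77L)
  expect_equal(length(z1), length(filterFeatures(x, 1.0)))
  expect_equal(names(z1), filterFeatures(x, 1.0))
  for (f in names(z1)) {
    expect_identical(z1[[f]]@sequence, z2[[f]]@sequence)
    expect_identical(z1[[f]]@deltaOsp, z2[[f]]@deltaOsp)
    expect_identical(z1[[f]]@gain, z2[[f]]@gain)
  }
})

test_that("informative features outrank noise features across seeds", {
  diffs <- vapply(1:8, function(seed) {
    x <- simulateSparseSeries(n = 80L, m = 5L,
                              roles = c("motif", "motif", "noise", "noise", "noise"),
                              qPos = 0, qNeg = 0, qNoise = 0, seed = seed)
    zs <- discoverShapelets(x, "plain", seed = seed)
    g <- vapply(zs, function(z) z@gain, numeric(1))
    min(g[1:2]) - max(g[3:5])
  }, numeric(1))
  expect_gt(stats::median(diffs), 0)
})
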