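test_that("seqPrd matches the nested-loop oracle exactly", {
  expect_equal(as.numeric(seqPrd(1, 1, p = 1)), 0)
  expect_equal(as.numeric(seqPrd(c(0, 2), 1, p = 1)), 2)
  expect_equal(as.numeric(seqPrd(c(1, 3), c(2, 4), p = 2)), 12)
  expect_equal(as.numeric(seqPrd(numeric(0), c(1, 2), p = 3)), 0)
  expect_error(seqPrd(c(2, 1), 3, p = 1), "non-decreasing")

  set.seed(71)
  for (i in 1:60) {
    k <- sample(1:20, 1); m <- sample(1:20, 1)
    a <- sort(sample(-20:20, k, replace = TRUE))
    b <- sort(sample(-20:20, m, replace = TRUE))
    p <- sample(1:7, 1)
    oracle <- sum(abs(outer(a, b, "-"))^p)
    expect_identical(as.numeric(seqPrd(a, b, p)), oracle)
    expect_identical(attr(seqPrd(a, b, p), "exact"),
                     sprintf("%.0f", oracle))
  }
  # real-valued inputs take the double path and stay close
  a <- sort(runif(10, -3, 3)); b <- sort(runif(8, -3, 3))
  expect_equal(as.numeric(seqPrd(a, b, 3)), sum(abs(outer(a, b, "-"))^3),
               tolerance = 1e-12)
})

test_that("getCntr emits median-path lca contributions in sorted order", {
  at <- annotateTree(readNewick("((a,b),c);"), "depth")
  sp <- medianSplit(at, 5L)          # split at the cherry {a,b}
  expect_equal(getCntr(at, sp, "c"), 0)
  expect_equal(getCntr(at, sp, character(0)), numeric(0))
  expect_error(getCntr(at, sp, "a"), "subset")

  cat4 <- annotateTree(readNewick("(((a,b),c),d);"), "depth")
  spc <- medianSplit(cat4, 7L)       # the node above {a,b}
  expect_setequal(lowerLeaves(spc), c("a", "b"))
  expect_equal(getCntr(cat4, spc, c("c", "d")), c(0, 1))

  set.seed(73)
  for (i in 1:25) {
    at <- asDescending(annotateTree(
      randomTree(sample(4:40, 1), sample(c("yule", "uniform"), 1)),
      sample(c("depth", "height", "size"), 1)))
    sp <- medianSplit(at)
    X <- sample(upperLeaves(sp),
                sample(0:length(upperLeaves(sp)), 1))
    g <- getCntr(at, sp, X)
    expect_length(g, length(X))
    expect_false(is.unsorted(g))
    # values agree with a direct lca computation against the median leaf
    if (length(X) > 0) {
      anyB <- lowerLeaves(sp)[1]
      M <- copheneticVector(at)
      expect_setequal(g, M[X, anyB])
      expect_equal(sort(g), sort(unname(M[X, anyB])))
    }
  }
})

test_that("each of the ten partial distances matches its restricted oracle", {
  set.seed(79)
  cats <- c("N1", "N2", "N3", "N4", "S1", "S2", "S3", "S4", "D1", "D2")
  for (i in 1:25) {
    n <- sample(6:32, 1)
    kind <- sample(c("depth", "height", "size"), 1)
    pair <- randomAnnotatedPair(n, kind)
    cls <- classifyPairs(medianSplit(pair[[1]]), medianSplit(pair[[2]]))
    for (p in sample(1:5, 2)) {
      parts <- partialDistances(pair[[1]], pair[[2]], p)
      for (cat in cats) {
        expect_equal(unname(parts[cat]),
                     restrictedOracle(pair[[1]], pair[[2]], p, cls, cat),
                     info = sprintf("cat %s n %d p %d", cat, n, p))
      }
      expect_equal(sum(parts),
                   rOracleDistance(pair[[1]], pair[[2]], p)$powerSum)
    }
  }
})

test_that("the L-infinity partial maxima match their restricted oracles", {
  set.seed(83)
  cats <- c("N1", "N2", "N3", "N4", "S1", "S2", "S3", "S4", "D1", "D2")
  for (i in 1:15) {
    n <- sample(6:32, 1)
    pair <- randomAnnotatedPair(n, sample(c("depth", "height", "size"), 1))
    a1 <- asDescending(pair[[1]]); a2 <- asDescending(pair[[2]])
    idx <- sharedLeafIndex(a1, a2)
    parts <- cophdist:::.cppTopPartialsInf(
      cophdist:::.encodeTree(a1, idx), cophdist:::.encodeTree(a2, idx),
      length(idx))
    ord <- names(idx)
    D <- abs(copheneticVector(a1, ord) - copheneticVector(a2, ord))
    cls <- classifyPairs(medianSplit(a1), medianSplit(a2), ord)
    for (cat in cats) {
      sel <- upper.tri(D, diag = TRUE) & cls == cat
      oracle <- if (any(sel)) max(D[sel]) else -Inf
      expect_equal(unname(parts[cat]), oracle,
                   info = sprintf("cat %s n %d", cat, n))
    }
  }
})

test_that("fast and naive algorithms agree bit-exactly on random pairs", {
  set.seed(89)
  for (i in 1:60) {
    n <- sample(2:96, 1)
    kind <- sample(c("depth", "height", "size"), 1)
    p <- sample(c(1, 2, 3, 4, 5, 10, 13, Inf), 1)
    pair <- randomAnnotatedPair(n, kind)
    f <- cophDist(pair[[1]], pair[[2]], p = p, algorithm = "fast")
    g <- cophDist(pair[[1]], pair[[2]], p = p, algorithm = "naive")
    if (is.finite(p)) {
      expect_identical(powerSumExact(f), powerSumExact(g))
    } else {
      expect_identical(powerSum(f), powerSum(g))
    }
  }
  # identical annotated trees at any p
  at <- annotateTree(randomTree(40, "yule", seed = 4), "height")
  expect_equal(distanceValue(cophDist(at, at, p = 7)), 0)
  expect_equal(distanceValue(cophDist(at, at, p = Inf)), 0)
})

test_that("deep caterpillar trees are handled (no recursion blow-up)", {
  n <- 300
  labs <- sprintf("t%d", 1:n)
  cater <- function(ls) {
    s <- sprintf("(%s,%s)", ls[1], ls[2])
    for (i in 3:length(ls)) s <- sprintf("(%s,%s)", s, ls[i])
    paste0(s, ";")
  }
  t1 <- readNewick(cater(labs))
  t2 <- readNewick(cater(rev(labs)))
  f <- cophDist(t1, t2, p = 3, contribution = "depth")
  g <- cophDist(t1, t2, p = 3, contribution = "depth", algorithm = "naive")
  expect_identical(powerSumExact(f), powerSumExact(g))
})

test_that("weighted contributions agree within floating tolerance", {
  set.seed(97)
  for (i in 1:15) {
    n <- sample(4:64, 1)
    tp <- lapply(randomTreePair(n, "yule"), withRandomLengths)
    kind <- sample(c("weighted_depth", "weighted_height"), 1)
    p <- sample(1:10, 1)
    f <- cophDist(tp[[1]], tp[[2]], p = p, contribution = kind)
    g <- cophDist(tp[[1]], tp[[2]], p = p, contribution = kind,
                  algorithm = "naive")
    expect_equal(powerSum(f), powerSum(g), tolerance = 1e-9)
    expect_true(is.na(powerSumExact(f)))
  }
  # p beyond the real-valued cap is refused rather than silently wrong
  tp <- lapply(randomTreePair(8, "yule", seed = 6), withRandomLengths)
  expect_error(cophDist(tp[[1]], tp[[2]], p = 16,
                        contribution = "weighted_depth"), "p <= 15")
})

test_that("binomials from the multiplicative recurrence match Pascal's triangle", {
  for (p in c(0, 1, 2, 7, 30, 100, 200)) {
    expect_identical(binomialCoefficients(p), unname(pascalRow(p)))
  }
})

test_that("distance results are internally consistent", {
  pair <- randomAnnotatedPair(30, "size")
  r <- cophDist(pair[[1]], pair[[2]], p = 4)
  expect_equal(distanceValue(r), powerSum(r)^(1 / 4))
  expect_equal(normOrder(r), 4)
  expect_true(isIntegerValued(pair[[1]]))
  expect_output(show(r), "power sum")
  # huge exact power sums overflow the double slot but not the distance
  big <- randomAnnotatedPair(64, "size")
  rb <- cophDist(big[[1]], big[[2]], p = 100)
  expect_true(is.finite(distanceValue(rb)))
  expect_false(is.na(powerSumExact(rb)))
})
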