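test_that("the three unweighted contributions match hand-computed values", {
  phy <- readNewick("(a,(b,c));")
  root <- length(phy$tip.label) + 1L

  d <- annotateTree(phy, "depth")
  expect_equal(xiValues(d)[root], 0)      # no root edge: depth of root is 0
  expect_equal(contributionDirection(d), "descending")
  expect_equal(unname(xiValues(d)[match(c("a", "b", "c"), phy$tip.label)]),
               c(1, 2, 2))

  s <- annotateTree(phy, "size")
  expect_equal(contributionDirection(s), "ascending")
  expect_equal(xiValues(s)[root], 3)
  expect_equal(sort(xiValues(s)), c(1, 1, 1, 2, 3))

  h <- annotateTree(phy, "height")
  expect_equal(xiValues(h)[root], 2)
  expect_equal(unname(xiValues(h)[match("a", phy$tip.label)]), 0)
  expect_true(isIntegerValued(d) && isIntegerValued(s) && isIntegerValued(h))
})

test_that("weighted contributions sum branch lengths, with the root edge in depths only", {
  w <- readNewick("((a:1,b:2):0.5,c:3);")
  wd <- annotateTree(w, "weighted_depth")
  expect_equal(unname(xiValues(wd)[match("b", w$tip.label)]), 2.5)
  expect_false(isIntegerValued(wd))

  r <- readNewick("((a:1,b:2):0.5,c:3):0.25;")
  wdr <- annotateTree(r, "weighted_depth")
  expect_equal(unname(xiValues(wdr)[match("b", r$tip.label)]), 2.75)
  # heights live inside the subtree: the root edge plays no part
  whr <- annotateTree(r, "weighted_height")
  wh <- annotateTree(w, "weighted_height")
  expect_equal(xiValues(whr), xiValues(wh))

  expect_error(annotateTree(readNewick("(a,(b,c));"), "weighted_depth"),
               "branch lengths")
})

test_that("unit branch lengths reduce weighted kinds to the unweighted ones", {
  set.seed(7)
  for (i in 1:20) {
    phy <- randomTree(sample(2:40, 1), sample(c("yule", "uniform"), 1))
    phy$edge.length <- rep(1, nrow(phy$edge))
    expect_equal(xiValues(annotateTree(phy, "weighted_depth")),
                 xiValues(annotateTree(phy, "depth")))
    expect_equal(xiValues(annotateTree(phy, "weighted_height")),
                 xiValues(annotateTree(phy, "height")))
  }
})

test_that("every annotation is path-monotone in its declared direction", {
  set.seed(11)
  kinds <- c("depth", "height", "size", "weighted_depth", "weighted_height")
  for (i in 1:100) {
    phy <- withRandomLengths(randomTree(sample(2:64, 1),
                                        sample(c("yule", "uniform"), 1)))
    for (k in kinds) {
      at <- annotateTree(phy, k)  # class validity enforces monotonicity
      ed <- treePhylo(at)$edge
      dxi <- xiValues(at)[ed[, 2]] - xiValues(at)[ed[, 1]]
      if (contributionDirection(at) == "descending")
        expect_true(all(dxi >= -1e-12))
      else expect_true(all(dxi <= 1e-12))
    }
  }
})

test_that("descending normalization negates, is idempotent, and leaves distances alone", {
  at <- annotateTree(readNewick("(a,(b,c));"), "size")
  d1 <- asDescending(at)
  expect_equal(xiValues(d1), -xiValues(at))
  expect_equal(contributionDirection(d1), "descending")
  expect_true(isIntegerValued(d1))
  expect_equal(xiValues(asDescending(d1)), xiValues(d1))  # idempotent

  # the oracle works on the raw ascending values; cophDist normalizes
  # internally -- equality means joint negation changed nothing
  set.seed(23)
  for (i in 1:20) {
    pair <- randomAnnotatedPair(sample(4:16, 1),
                                kind = sample(c("height", "size"), 1))
    for (p in c(1, 2, 3)) {
      expect_equal(powerSum(cophDist(pair[[1]], pair[[2]], p = p)),
                   rOracleDistance(pair[[1]], pair[[2]], p)$powerSum)
    }
  }
})

test_that("a tree pair with opposite contribution directions is rejected", {
  t1 <- readNewick("((a,b),c);")
  t2 <- readNewick("(a,(b,c));")
  expect_error(cophDist(t1, t2, p = 2, contribution = c("depth", "size")),
               "direction")
  # mixed kinds of a common direction are allowed (a cost, not a metric)
  r <- cophDist(t1, t2, p = 2, contribution = c("height", "size"))
  expect_s4_class(r, "DistanceResult")
  expect_gte(distanceValue(r), 0)
})

test_that("custom annotations are validated for monotonicity", {
  phy <- readNewick("(a,(b,c));")
  ok <- annotateTree(phy, xi = c(5, 7, 8, 1, 3), direction = "descending")
  expect_s4_class(ok, "AnnotatedTree")
  expect_error(annotateTree(phy, xi = c(5, 0, 8, 1, 3),
                            direction = "descending"), "monotone")
})
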