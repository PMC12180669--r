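test_that("cophenetic vectors match hand enumeration", {
  at <- annotateTree(readNewick("(a,(b,c));"), "depth")
  M <- copheneticVector(at)
  expect_equal(M["a", "a"], 1)
  expect_equal(M["a", "b"], 0)
  expect_equal(M["a", "c"], 0)
  expect_equal(M["b", "b"], 2)
  expect_equal(M["b", "c"], 1)
  expect_equal(M["c", "c"], 2)

  S <- copheneticVector(annotateTree(readNewick("(a,(b,c));"), "size"))
  expect_equal(unname(S[c("a", "b", "c"), c("a", "b", "c")]),
               matrix(c(1, 3, 3, 3, 1, 2, 3, 2, 1), 3, 3))

  # constant contribution: every entry equals the constant
  phy <- randomTree(9, "yule", seed = 2)
  cst <- annotateTree(phy, xi = rep(4, 17), direction = "descending")
  expect_true(all(copheneticVector(cst) == 4))
})

test_that("cophenetic vector agrees with an ape::mrca lookup", {
  set.seed(53)
  for (i in 1:25) {
    phy <- randomTree(sample(2:40, 1), sample(c("yule", "uniform"), 1))
    at <- annotateTree(phy, sample(c("depth", "height", "size"), 1))
    ord <- sort(phy$tip.label, method = "radix")
    mr <- ape::mrca(phy)[ord, ord]
    ref <- matrix(xiValues(at)[mr], nrow(mr), dimnames = dimnames(mr))
    expect_equal(copheneticVector(at, ord), ref)
  }
})

test_that("naive distance reproduces the worked three-leaf example", {
  t1 <- readNewick("((a,b),c);")
  t2 <- readNewick("(a,(b,c));")
  r1 <- cophDist(t1, t2, p = 1, contribution = "depth", algorithm = "naive")
  expect_identical(powerSumExact(r1), "4")
  expect_equal(distanceValue(r1), 4)
  r2 <- cophDist(t1, t2, p = 2, contribution = "depth", algorithm = "naive")
  expect_identical(powerSumExact(r2), "4")
  expect_equal(distanceValue(r2), 2)
  ri <- cophDist(t1, t2, p = Inf, contribution = "depth",
                 algorithm = "naive")
  expect_equal(distanceValue(ri), 1)
  r0 <- cophDist(t1, t1, p = 3, contribution = "depth", algorithm = "naive")
  expect_equal(distanceValue(r0), 0)
})

test_that("naive distance is symmetric and matches the R oracle", {
  set.seed(59)
  for (i in 1:20) {
    pair <- randomAnnotatedPair(sample(2:24, 1),
                                sample(c("depth", "height", "size"), 1))
    for (p in c(1, 2, 3, Inf)) {
      ab <- cophDist(pair[[1]], pair[[2]], p = p, algorithm = "naive")
      ba <- cophDist(pair[[2]], pair[[1]], p = p, algorithm = "naive")
      expect_equal(powerSum(ab), powerSum(ba))
      expect_equal(powerSum(ab), rOracleDistance(pair[[1]], pair[[2]],
                                                 p)$powerSum)
    }
  }
})

test_that("same-kind distances behave like a metric on sampled triples", {
  set.seed(61)
  for (i in 1:12) {
    n <- sample(4:32, 1)
    kind <- sample(c("depth", "height", "size"), 1)
    labs <- sprintf("t%d", seq_len(n))
    trio <- lapply(1:3, function(j)
      annotateTree(randomTree(n, sample(c("yule", "uniform"), 1),
                              labels = labs), kind))
    for (p in c(1, 2, 3, Inf)) {
      d <- function(a, b) distanceValue(cophDist(a, b, p = p,
                                                 algorithm = "naive"))
      dab <- d(trio[[1]], trio[[2]])
      dbc <- d(trio[[2]], trio[[3]])
      dac <- d(trio[[1]], trio[[3]])
      expect_gte(dab, 0)
      expect_lte(dac, dab + dbc + 1e-9)               # triangle inequality
      expect_equal(d(trio[[1]], trio[[1]]), 0)        # identity
    }
    # depth vectors identify the topology: distinct trees are separated
    if (kind == "depth") {
      same <- isTRUE(ape::all.equal.phylo(treePhylo(trio[[1]]),
                                          treePhylo(trio[[2]]),
                                          use.edge.length = FALSE))
      dd <- distanceValue(cophDist(trio[[1]], trio[[2]], p = 1,
                                   algorithm = "naive"))
      if (!same) expect_gt(dd, 0) else expect_equal(dd, 0)
    }
  }
})

test_that("d_p decreases with p and dominates d_inf", {
  set.seed(67)
  for (i in 1:10) {
    pair <- randomAnnotatedPair(sample(4:48, 1),
                                sample(c("depth", "height", "size"), 1))
    ps <- c(1, 2, 3, 5, 10, 15)
    ds <- vapply(ps, function(p)
      distanceValue(cophDist(pair[[1]], pair[[2]], p = p,
                             algorithm = "naive")), numeric(1))
    dinf <- distanceValue(cophDist(pair[[1]], pair[[2]], p = Inf,
                                   algorithm = "naive"))
    expect_true(all(diff(ds) <= 1e-9))
    expect_true(all(ds >= dinf - 1e-9))
  }
})
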