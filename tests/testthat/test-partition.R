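test_that("median descent lands where the worked examples say", {
  # (a,(b,c)): across all tie-breakings exactly the two cherry leaves
  phy <- readNewick("(a,(b,c));")
  med <- medianVertices(phy)
  expect_length(med, 2)
  expect_setequal(phy$tip.label[med], c("b", "c"))
  expect_true(medianVertex(phy) %in% med)

  # ((a,b),(c,d)) with the left-first tie-break: the node above {a,b}
  q <- readNewick("((a,b),(c,d));")
  t <- medianVertex(q)
  expect_setequal(cophdist:::.tipsUnder(q, t), c("a", "b"))
  expect_true(medianBoundsHold(q, t))

  # two-leaf tree: a median vertex is a leaf
  two <- readNewick("(a,b);")
  t2 <- medianVertex(two)
  expect_lte(t2, 2)
  expect_true(medianBoundsHold(two, t2))

  expect_error(medianVertex(readNewick("(a,b,c);")), "non-binary")
})

test_that("median vertices satisfy the sandwich bounds on random trees", {
  set.seed(31)
  for (i in 1:200) {
    phy <- randomTree(sample(2:256, 1), sample(c("yule", "uniform"), 1))
    expect_true(medianBoundsHold(phy, medianVertex(phy)))
  }
})

test_that("splitting partitions the leaves and records the median path", {
  phy <- readNewick("((a,b),c);")
  # split at the cherry node (any non-root vertex is allowed)
  cherry <- 5L  # the internal node above {a, b}
  expect_setequal(cophdist:::.tipsUnder(phy, cherry), c("a", "b"))
  sp <- medianSplit(phy, cherry)
  expect_setequal(lowerLeaves(sp), c("a", "b"))
  expect_setequal(upperLeaves(sp), "c")
  expect_equal(medianPathNodes(sp), c(4L, cherry))
  expect_error(medianSplit(phy, 4L), "root")

  set.seed(37)
  for (i in 1:60) {
    phy <- randomTree(sample(2:64, 1), sample(c("yule", "uniform"), 1))
    sp <- medianSplit(phy)
    expect_setequal(c(upperLeaves(sp), lowerLeaves(sp)), phy$tip.label)
    expect_length(intersect(upperLeaves(sp), lowerLeaves(sp)), 0)
  }
})

test_that("contraction keeps original lca contributions on the survivors", {
  at <- annotateTree(readNewick("((a,b),c);"), "depth")
  ct <- contractTree(at, c("a", "c"))
  expect_s4_class(ct, "AnnotatedTree")
  phy <- treePhylo(ct)
  expect_setequal(phy$tip.label, c("a", "c"))
  root <- length(phy$tip.label) + 1L
  expect_equal(xiValues(ct)[root], 0)                            # old root
  expect_equal(unname(xiValues(ct)[match("a", phy$tip.label)]), 2)
  expect_equal(unname(xiValues(ct)[match("c", phy$tip.label)]), 1)

  # contracting to all leaves is the identity on the cophenetic vector
  at2 <- annotateTree(randomTree(12, "yule", seed = 5), "size")
  full <- contractTree(at2, treePhylo(at2)$tip.label)
  expect_equal(copheneticVector(full), copheneticVector(at2))

  # sentinels
  expect_null(contractTree(at, character(0)))
  single <- contractTree(at, "b")
  expect_equal(single, c(b = 2))
})

test_that("contraction preserves all surviving pairwise lca contributions", {
  set.seed(41)
  kinds <- c("depth", "height", "size", "weighted_depth")
  for (i in 1:120) {
    phy <- withRandomLengths(randomTree(sample(3:48, 1),
                                        sample(c("yule", "uniform"), 1)))
    at <- annotateTree(phy, sample(kinds, 1))
    keep <- sample(phy$tip.label, sample(2:length(phy$tip.label), 1))
    ct <- contractTree(at, keep)
    ord <- sort(keep, method = "radix")
    expect_equal(copheneticVector(ct, ord),
                 copheneticVector(at)[ord, ord])
  }
})

test_that("the ten categories partition all n(n+1)/2 leaf pairs", {
  set.seed(43)
  cats <- c("N1", "N2", "N3", "N4", "S1", "S2", "S3", "S4", "D1", "D2")
  for (i in 1:40) {
    n <- sample(2:32, 1)
    tp <- randomTreePair(n, sample(c("yule", "uniform"), 1))
    s1 <- medianSplit(tp[[1]])
    s2 <- medianSplit(tp[[2]])
    cls <- classifyPairs(s1, s2)
    ut <- cls[upper.tri(cls, diag = TRUE)]
    expect_length(ut, n * (n + 1) / 2)
    expect_true(all(ut %in% cats))
    # expected cell-pair counts from the per-leaf membership cells
    ord <- rownames(cls)
    nAA <- sum(!(ord %in% s1@B) & !(ord %in% s2@B))
    nAB <- sum(!(ord %in% s1@B) & (ord %in% s2@B))
    nBA <- sum((ord %in% s1@B) & !(ord %in% s2@B))
    nBB <- sum((ord %in% s1@B) & (ord %in% s2@B))
    expected <- c(N1 = nAA * (nAA + 1) / 2, N2 = nAB * (nAB + 1) / 2,
                  N3 = nBA * (nBA + 1) / 2, N4 = nBB * (nBB + 1) / 2,
                  S1 = nAA * nBA, S2 = nAB * nBB, S3 = nAA * nAB,
                  S4 = nBA * nBB, D1 = nAA * nBB, D2 = nAB * nBA)
    got <- table(factor(ut, levels = cats))
    expect_equal(as.numeric(got), unname(expected[cats]))
    # diagonal pairs are always non-mixed
    expect_true(all(diag(cls) %in% c("N1", "N2", "N3", "N4")))
  }
})
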