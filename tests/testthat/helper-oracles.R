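# Shared fixtures and independent oracles for the test suite.
# Everything here is deliberately simple-minded: plain double loops over
# cophenetic vectors, decimal-string addition, canonical topology strings.

# naive R distance from the reference cophenetic vectors (independent of
# the C++ engines); suitable for small n and moderate p only
rOracleDistance <- function(at1, at2, p) {
  ord <- sort(treePhylo(at1)$tip.label, method = "radix")
  M1 <- copheneticVector(at1, ord)
  M2 <- copheneticVector(at2, ord)
  D <- abs(M1 - M2)[upper.tri(M1, diag = TRUE)]
  if (is.infinite(p)) return(list(powerSum = max(D), distance = max(D)))
  ps <- sum(D^p)
  list(powerSum = ps, distance = ps^(1 / p))
}

# power sum restricted to the pairs of one category (category matrix from
# classifyPairs)
restrictedOracle <- function(at1, at2, p, categoryMatrix, category) {
  ord <- rownames(categoryMatrix)
  D <- abs(copheneticVector(at1, ord) - copheneticVector(at2, ord))
  sel <- upper.tri(D, diag = TRUE) & categoryMatrix == category
  sum(D[sel]^p)
}

# a random annotated pair on a common label set
randomAnnotatedPair <- function(n, kind = "depth",
                                model = sample(c("yule", "uniform"), 1)) {
  tp <- randomTreePair(n, model)
  list(annotateTree(tp[[1]], kind), annotateTree(tp[[2]], kind))
}

# attach random branch lengths to a phylo
withRandomLengths <- function(phy, min = 0.1, max = 2) {
  phy$edge.length <- runif(nrow(phy$edge), min, max)
  phy
}

# ---- decimal-string arithmetic (oracle for exact binomials) --------------

# a + b for non-negative decimal strings
addDec <- function(a, b) {
  da <- rev(as.integer(strsplit(a, "")[[1]]))
  db <- rev(as.integer(strsplit(b, "")[[1]]))
  k <- max(length(da), length(db))
  da <- c(da, rep(0L, k - length(da)))
  db <- c(db, rep(0L, k - length(db)))
  s <- da + db
  carry <- 0L
  for (i in seq_len(k)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 10L
    s[i] <- s[i] %% 10L
  }
  while (carry > 0L) {
    s <- c(s, carry %% 10L)
    carry <- carry %/% 10L
  }
  while (length(s) > 1 && s[length(s)] == 0L) s <- s[-length(s)]
  paste(rev(s), collapse = "")
}

# row p of Pascal's triangle as decimal strings (addition-only recurrence,
# independent of the package's multiplicative recurrence)
pascalRow <- function(p) {
  row <- "1"
  if (p == 0) return(row)
  for (i in seq_len(p)) {
    prev <- row
    row <- c("1", if (length(prev) > 1)
      mapply(addDec, prev[-length(prev)], prev[-1]) else character(0), "1")
  }
  row
}

# canonical topology string: children ordered by their smallest leaf label
canonicalTopology <- function(phy) {
  ca <- cophdist:::.childArrays(phy)
  root <- length(phy$tip.label) + 1L
  rec <- function(v) {
    if (v <= length(phy$tip.label)) return(phy$tip.label[v])
    a <- rec(ca$lft[v])
    b <- rec(ca$rgh[v])
    if (a < b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
  }
  paste0(rec(root), ";")
}

# the sandwich bounds a median vertex must satisfy
medianBoundsHold <- function(phy, t) {
  n <- length(phy$tip.label)
  lower <- length(cophdist:::.tipsUnder(phy, t))
  upper <- n - lower + 1
  lower >= n / 4 && lower <= n / 2 && upper >= n / 2 && upper <= 3 * n / 4 + 1
}
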