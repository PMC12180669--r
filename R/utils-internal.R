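# Internal helpers shared across modules.  Trees are ape 'phylo' objects;
# node numbering follows ape (tips 1..n, internal nodes n+1..2n-1).

# NULL if phy is a valid rooted binary tree with unique labels, else message
.checkBinaryPhylo <- function(phy) {
  if (!inherits(phy, "phylo")) return("not a phylo object")
  if (is.null(phy$tip.label) || length(phy$tip.label) < 2)
    return("tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    return(sprintf("duplicate leaf label(s): %s", paste(dup, collapse = ", ")))
  }
  deg <- tabulate(phy$edge[, 1], nbins = length(phy$tip.label) + phy$Nnode)
  internal <- (length(phy$tip.label) + 1):(length(phy$tip.label) + phy$Nnode)
  bad <- internal[deg[internal] != 2]
  if (length(bad) > 0) {
    v <- bad[1]
    tips <- .tipsUnder(phy, v)
    return(sprintf("non-binary vertex (%d children) above clade {%s}",
                   deg[v], paste(head(sort(tips), 6), collapse = ", ")))
  }
  if (phy$Nnode != length(phy$tip.label) - 1)
    return("tree is not a rooted binary tree (|V| != 2n - 1)")
  NULL
}

.assertBinaryPhylo <- function(phy) {
  msg <- .checkBinaryPhylo(phy)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  invisible(phy)
}

.rootNode <- function(phy) length(phy$tip.label) + 1L

# child arrays: first edge row encountered is the left child (this fixed
# orientation is what makes the median-descent tie-break reproducible)
.childArrays <- function(phy) {
  nv <- length(phy$tip.label) + phy$Nnode
  lft <- integer(nv)
  rgh <- integer(nv)
  par <- integer(nv)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1]; ch <- e[i, 2]
    par[ch] <- p
    if (lft[p] == 0L) lft[p] <- ch else rgh[p] <- ch
  }
  list(par = par, lft = lft, rgh = rgh, nv = nv)
}

# tip labels below a node (node may be a tip)
.tipsUnder <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  ca <- .childArrays(phy)
  acc <- character(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= ntip) acc <- c(acc, phy$tip.label[v])
    else stack <- c(stack, ca$lft[v], ca$rgh[v])
  }
  acc
}

# postorder vertex sequence (children before parents)
.postorderNodes <- function(ca, root) {
  out <- integer(ca$nv)
  stack <- integer(ca$nv)
  stack[1] <- root
  top <- 1L
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- v
    if (ca$lft[v] > 0L) {
      stack[top + 1L] <- ca$lft[v]
      stack[top + 2L] <- ca$rgh[v]
      top <- top + 2L
    }
  }
  rev(out[seq_len(k)])
}

# subtree leaf counts per vertex
.subtreeSizes <- function(ca, root) {
  cnt <- integer(ca$nv)
  for (v in .postorderNodes(ca, root)) {
    cnt[v] <- if (ca$lft[v] == 0L) 1L else cnt[ca$lft[v]] + cnt[ca$rgh[v]]
  }
  cnt
}

# Encode an AnnotatedTree for the C++ engines.  leafIndex: named integer
# (1-based positions in the shared lexicographic leaf order).
.encodeTree <- function(at, leafIndex) {
  phy <- at@tree
  ntip <- length(phy$tip.label)
  ca <- .childArrays(phy)
  leaf <- rep(-1L, ca$nv)
  leaf[seq_len(ntip)] <- leafIndex[phy$tip.label] - 1L
  list(parent = ca$par - 1L, left = ca$lft - 1L, right = ca$rgh - 1L,
       leaf = leaf, xi = as.numeric(at@xi))
}

# Rebuild a phylo (+ xi) from the 0-based arrays the C++ contraction
# returns.  labels: the global (lexicographic) label vector indexed by
# global leaf id + 1.  Returns NULL for an empty tree and a named xi scalar
# for a single surviving leaf.
.phyloFromArrays <- function(lst, labels) {
  nvert <- length(lst$parent)
  if (nvert == 0L) return(NULL)
  par <- lst$parent + 1L
  lft <- lst$left + 1L
  rgh <- lst$right + 1L
  leafid <- lst$leaf + 1L  # global ids, 0 -> internal
  if (nvert == 1L) {
    out <- lst$xi[1]
    names(out) <- labels[leafid[1]]
    return(out)
  }
  root <- which(par == 0L)
  ntip <- sum(leafid > 0L)
  newid <- integer(nvert)
  nextTip <- 1L
  nextInt <- ntip + 1L
  # preorder numbering: root becomes ntip + 1 as ape expects
  stack <- integer(nvert)
  stack[1] <- root
  top <- 1L
  order <- integer(nvert)
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    order[k] <- v
    if (leafid[v] > 0L) {
      newid[v] <- nextTip
      nextTip <- nextTip + 1L
    } else {
      newid[v] <- nextInt
      nextInt <- nextInt + 1L
      stack[top + 1L] <- rgh[v]
      stack[top + 2L] <- lft[v]
      top <- top + 2L
    }
  }
  nonroot <- order[order != root]
  edge <- cbind(newid[par[nonroot]], newid[nonroot])
  tipv <- which(leafid > 0L)
  tip.label <- character(ntip)
  tip.label[newid[tipv]] <- labels[leafid[tipv]]
  phy <- list(edge = edge, tip.label = tip.label, Nnode = ntip - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  xi <- numeric(2L * ntip - 1L)
  xi[newid] <- lst$xi
  list(phy = phy, xi = xi)
}

.isWholeNumber <- function(x, tol = 1e-9) all(abs(x - round(x)) < tol)

# run expr under a temporary seed (no effect on the global RNG stream when
# seed is NULL)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
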