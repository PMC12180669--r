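#' Median vertex of a rooted binary tree
#'
#' Descends from the root, always moving to the child with the larger
#' subtree (left child on ties), until the current vertex holds at most
#' half of the leaves.  The returned vertex `t` satisfies the sandwich
#' bounds \eqn{n/4 \le |T_t| \le n/2} and \eqn{n/2 \le |T^t| \le 3n/4 + 1},
#' where \eqn{T_t} is the subtree at `t` (lower tree) and \eqn{T^t} the
#' remainder with that subtree replaced by a leaf (upper tree,
#' \eqn{|T^t| = n - |T_t| + 1}).
#'
#' @param x a rooted binary `phylo` or [AnnotatedTree-class] with at least
#'   2 leaves.
#' @return the phylo node number of the median vertex.
#' @examples
#' medianVertex(readNewick("(a,(b,c));"))   # a leaf of the cherry (b,c)
#' @seealso [medianVertices()] for all tie-breakings, [medianSplit()]
#' @export
medianVertex <- function(x) {
  phy <- if (is(x, "AnnotatedTree")) x@tree else x
  .assertBinaryPhylo(phy)
  n <- length(phy$tip.label)
  if (n < 2) stop("median vertex needs at least 2 leaves", call. = FALSE)
  ca <- .childArrays(phy)
  root <- .rootNode(phy)
  cnt <- .subtreeSizes(ca, root)
  t <- root
  while (2L * cnt[t] > n) {
    l <- ca$lft[t]; r <- ca$rgh[t]
    t <- if (cnt[l] >= cnt[r]) l else r
  }
  t
}

#' All median vertices reachable by the descent
#'
#' Enumerates every vertex the median descent can end at when ties between
#' equal-sized children are broken in all possible ways.  Intended for
#' small trees (the enumeration branches at every tie).
#'
#' @inheritParams medianVertex
#' @return sorted integer vector of phylo node numbers.
#' @export
medianVertices <- function(x) {
  phy <- if (is(x, "AnnotatedTree")) x@tree else x
  .assertBinaryPhylo(phy)
  n <- length(phy$tip.label)
  ca <- .childArrays(phy)
  root <- .rootNode(phy)
  cnt <- .subtreeSizes(ca, root)
  out <- integer(0)
  frontier <- root
  while (length(frontier) > 0) {
    v <- frontier[1]
    frontier <- frontier[-1]
    if (2L * cnt[v] <= n) {
      out <- c(out, v)
    } else {
      l <- ca$lft[v]; r <- ca$rgh[v]
      nxt <- if (cnt[l] > cnt[r]) l else if (cnt[r] > cnt[l]) r else c(l, r)
      frontier <- c(frontier, nxt)
    }
  }
  sort(unique(out))
}

#' Split a tree at a vertex into upper and lower leaf sets
#'
#' @param x a rooted binary `phylo` or [AnnotatedTree-class].
#' @param t the split vertex (defaults to [medianVertex()]); must not be
#'   the root.
#' @return a [MedianSplit-class]: `B` holds the leaves below `t`, `A` the
#'   remaining leaves, and the median path runs from the root to `t`.
#' @export
medianSplit <- function(x, t = NULL) {
  phy <- if (is(x, "AnnotatedTree")) x@tree else x
  .assertBinaryPhylo(phy)
  if (is.null(t)) t <- medianVertex(phy)
  t <- as.integer(t)
  root <- .rootNode(phy)
  if (t == root)
    stop("splitting at the root is degenerate (empty upper tree)",
         call. = FALSE)
  ca <- .childArrays(phy)
  B <- .tipsUnder(phy, t)
  A <- setdiff(phy$tip.label, B)
  path <- t
  v <- t
  while (v != root) {
    v <- ca$par[v]
    path <- c(v, path)
  }
  new("MedianSplit", vertex = t, A = A, B = B,
      medianPath = as.integer(path), n = length(phy$tip.label))
}

#' Restrict an annotated tree to a subset of its leaves
#'
#' Contracts the tree to the induced topology on `keep` (suppressing the
#' degree-2 vertices that arise), while every surviving vertex keeps the
#' contribution value of the original vertex it corresponds to -- the
#' original lca of its leaf set.  Contributions are never recomputed on the
#' contracted shape: for all `x, y` in `keep`,
#' `xi_contracted(lca_contracted(x, y)) == xi_original(lca_original(x, y))`,
#' which is the property the divide-and-conquer recursion relies on.
#'
#' @param at an [AnnotatedTree-class].
#' @param keep character vector of leaf labels to retain.
#' @return an [AnnotatedTree-class]; for a single kept leaf, a named
#'   numeric scalar (its contribution); for an empty `keep`, `NULL`.
#' @export
contractTree <- function(at, keep) {
  stopifnot(is(at, "AnnotatedTree"))
  labels <- at@tree$tip.label
  if (!all(keep %in% labels))
    stop("keep contains labels not in the tree: ",
         paste(setdiff(keep, labels), collapse = ", "), call. = FALSE)
  ord <- sort(labels, method = "radix")
  idx <- seq_along(ord)
  names(idx) <- ord
  enc <- .encodeTree(at, idx)
  mask <- ord %in% keep
  res <- .cppContract(enc, mask)
  dec <- .phyloFromArrays(res, ord)
  if (is.null(dec) || is.numeric(dec)) return(dec)
  new("AnnotatedTree", tree = dec$phy, xi = dec$xi,
      direction = at@direction, integerValued = at@integerValued,
      kind = at@kind)
}

#' Classify all leaf pairs against two median splits
#'
#' Every unordered leaf pair (diagonal pairs included) falls into exactly
#' one of ten categories according to the position of its two leaves
#' relative to the splits of the two trees: four non-mixed categories
#' (`N1` = AA|A'A', `N2` = AA|B'B', `N3` = BB|A'A', `N4` = BB|B'B'), four
#' single-mixed (`S1` = AB|A'A', `S2` = AB|B'B', `S3` = AA|A'B',
#' `S4` = BB|A'B') and two double-mixed (`D1` = AB|A'B', `D2` = AB|B'A').
#'
#' @param split1,split2 [MedianSplit-class] objects for the two trees
#'   (same leaf set).
#' @param order optional character vector fixing the leaf order of the
#'   returned matrix (defaults to the lexicographic order).
#' @return a symmetric character matrix of category labels.
#' @export
classifyPairs <- function(split1, split2, order = NULL) {
  labels <- sort(c(split1@A, split1@B), method = "radix")
  if (!setequal(labels, c(split2@A, split2@B)))
    stop("splits are over different leaf sets", call. = FALSE)
  if (is.null(order)) order <- labels
  inB1 <- order %in% split1@B
  inB2 <- order %in% split2@B
  cell <- ifelse(!inB1 & !inB2, "AA",
          ifelse(!inB1 & inB2, "AB",
          ifelse(inB1 & !inB2, "BA", "BB")))
  lookup <- c("AA.AA" = "N1", "AB.AB" = "N2", "BA.BA" = "N3", "BB.BB" = "N4",
              "AA.BA" = "S1", "AB.BB" = "S2", "AA.AB" = "S3", "BA.BB" = "S4",
              "AA.BB" = "D1", "AB.BA" = "D2")
  n <- length(order)
  out <- matrix("", n, n, dimnames = list(order, order))
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- paste(sort(c(cell[i], cell[j])), collapse = ".")
      out[i, j] <- out[j, i] <- lookup[[key]]
    }
  }
  out
}
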