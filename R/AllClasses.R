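#' Annotated rooted binary tree
#'
#' A rooted binary tree (an [ape::phylo] object) together with a per-vertex
#' contribution value \eqn{\xi}, the monotonicity direction of the
#' contribution along root-to-leaf paths, and a flag recording whether all
#' contributions are integers (which selects the exact arithmetic path in
#' the distance algorithms).
#'
#' The `xi` slot is indexed by the phylo node number (tips `1..n`, then
#' internal nodes `n+1..2n-1`).  Validity requires the tree to be rooted and
#' strictly binary, the labels unique, and `xi` monotone along every edge in
#' the declared direction: descending means every child's value is at least
#' its parent's; ascending the reverse.
#'
#' @slot tree a rooted, binary `phylo` object with unique tip labels.
#' @slot xi numeric vector of contribution values, one per vertex.
#' @slot direction `"descending"` or `"ascending"`.
#' @slot integerValued logical; `TRUE` iff every `xi` value is an integer.
#' @slot kind the contribution kind used to build the annotation (or
#'   `"custom"`).
#' @seealso [annotateTree()], [asDescending()]
#' @export
setClass("AnnotatedTree",
  representation(
    tree = "ANY",
    xi = "numeric",
    direction = "character",
    integerValued = "logical",
    kind = "character"
  )
)

setValidity("AnnotatedTree", function(object) {
  phy <- object@tree
  if (!inherits(phy, "phylo")) return("'tree' must be a phylo object")
  msg <- .checkBinaryPhylo(phy)
  if (!is.null(msg)) return(msg)
  nv <- length(phy$tip.label) + phy$Nnode
  if (length(object@xi) != nv)
    return(sprintf("xi has length %d, tree has %d vertices",
                   length(object@xi), nv))
  if (!(object@direction %in% c("ascending", "descending")))
    return("direction must be 'ascending' or 'descending'")
  if (any(!is.finite(object@xi))) return("xi values must be finite")
  ed <- phy$edge
  tol <- 1e-9 * max(1, max(abs(object@xi)))
  dxi <- object@xi[ed[, 2]] - object@xi[ed[, 1]]  # child minus parent
  bad <- if (object@direction == "descending") dxi < -tol else dxi > tol
  if (any(bad))
    return(sprintf("xi is not path-monotone (%s) on %d edge(s)",
                   object@direction, sum(bad)))
  iv <- all(abs(object@xi - round(object@xi)) < 1e-9)
  if (!identical(object@integerValued, iv))
    return("integerValued flag does not match the xi values")
  TRUE
})

#' Median split of a rooted binary tree
#'
#' The decomposition of a tree at a median vertex `t`: the lower tree is the
#' subtree rooted at `t` (leaf set `B`), the upper tree is the remainder
#' with that subtree replaced by a placeholder leaf (leaf set `A`, which
#' excludes the placeholder).  `A` and `B` partition the leaf labels, and
#' the median path runs from the root down to `t` inclusive.
#'
#' @slot vertex integer phylo node number of the median vertex.
#' @slot A character vector of upper-tree leaf labels.
#' @slot B character vector of lower-tree leaf labels.
#' @slot medianPath integer vector of node numbers, root first, `vertex`
#'   last.
#' @slot n total number of leaves.
#' @seealso [medianVertex()], [medianSplit()]
#' @export
setClass("MedianSplit",
  representation(
    vertex = "integer",
    A = "character",
    B = "character",
    medianPath = "integer",
    n = "integer"
  )
)

setValidity("MedianSplit", function(object) {
  if (length(intersect(object@A, object@B)) > 0)
    return("A and B must be disjoint")
  if (length(object@A) + length(object@B) != object@n)
    return("A and B must partition the leaf set")
  if (tail(object@medianPath, 1) != object@vertex)
    return("medianPath must end at the median vertex")
  TRUE
})

#' Result of a cophenetic distance computation
#'
#' For finite p the power sum is \eqn{\sum_{i \le j} |\xi(\mathrm{lca}_T) -
#' \xi'(\mathrm{lca}_{T'})|^p} and the distance its p-th root; for the
#' L-infinity norm both slots hold the maximum absolute difference.  When
#' both annotations are integer-valued the power sum is an exact integer,
#' reported verbatim in `powerSumExact` (the numeric `powerSum` is its
#' closest double, and may round or overflow to `Inf` for very large p).
#'
#' @slot p the norm order (a positive integer, or `Inf`).
#' @slot powerSum numeric power sum (or maximum for `p = Inf`).
#' @slot powerSumExact exact decimal string, or `NA` for real-valued
#'   contributions.
#' @slot distance the distance value `powerSum^(1/p)`.
#' @slot algorithm `"fast"` or `"naive"`.
#' @slot integerValued logical.
#' @slot n number of leaves.
#' @seealso [cophDist()]
#' @export
setClass("DistanceResult",
  representation(
    p = "numeric",
    powerSum = "numeric",
    powerSumExact = "character",
    distance = "numeric",
    algorithm = "character",
    integerValued = "logical",
    n = "integer"
  )
)

setValidity("DistanceResult", function(object) {
  if (length(object@p) != 1 || (is.finite(object@p) && object@p < 1))
    return("p must be a single value >= 1 or Inf")
  if (is.finite(object@distance) && object@distance < 0)
    return("distance must be non-negative")
  if (is.finite(object@powerSum) && is.finite(object@distance)) {
    if ((object@powerSum == 0) != (object@distance == 0))
      return("distance is zero iff the power sum is zero")
  }
  TRUE
})

setMethod("show", "AnnotatedTree", function(object) {
  cat(sprintf("AnnotatedTree: %d leaves, contribution '%s' (%s%s)\n",
              length(object@tree$tip.label), object@kind, object@direction,
              if (object@integerValued) ", integer-valued" else ""))
  rng <- range(object@xi)
  cat(sprintf("  xi range: [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "MedianSplit", function(object) {
  cat(sprintf("MedianSplit at node %d: |A| = %d, |B| = %d (n = %d), median path length %d\n",
              object@vertex, length(object@A), length(object@B), object@n,
              length(object@medianPath)))
})

setMethod("show", "DistanceResult", function(object) {
  pTxt <- if (is.finite(object@p)) sprintf("L%g", object@p) else "Linf"
  cat(sprintf("%s cophenetic distance (%s algorithm, n = %d)\n", pTxt,
              object@algorithm, object@n))
  if (is.finite(object@p)) {
    ps <- if (!is.na(object@powerSumExact)) object@powerSumExact
          else format(object@powerSum)
    cat(sprintf("  power sum: %s\n  distance:  %.10g\n", ps, object@distance))
  } else {
    cat(sprintf("  distance (max |xi - xi'|): %.10g\n", object@distance))
  }
})

# ---- accessors ------------------------------------------------------------

#' @describeIn AnnotatedTree the underlying `phylo` tree.
#' @param x an object.
#' @export
treePhylo <- function(x) {
  stopifnot(is(x, "AnnotatedTree"))
  x@tree
}

#' @describeIn AnnotatedTree the per-vertex contribution values.
#' @export
xiValues <- function(x) {
  stopifnot(is(x, "AnnotatedTree"))
  x@xi
}

#' @describeIn AnnotatedTree the monotonicity direction.
#' @export
contributionDirection <- function(x) {
  stopifnot(is(x, "AnnotatedTree"))
  x@direction
}

#' @describeIn AnnotatedTree whether all contributions are integers.
#' @export
isIntegerValued <- function(x) {
  stopifnot(is(x, "AnnotatedTree"))
  x@integerValued
}

#' @describeIn MedianSplit upper-tree leaf labels.
#' @param x an object.
#' @export
upperLeaves <- function(x) {
  stopifnot(is(x, "MedianSplit"))
  x@A
}

#' @describeIn MedianSplit lower-tree leaf labels.
#' @export
lowerLeaves <- function(x) {
  stopifnot(is(x, "MedianSplit"))
  x@B
}

#' @describeIn MedianSplit node numbers on the root-to-median path.
#' @export
medianPathNodes <- function(x) {
  stopifnot(is(x, "MedianSplit"))
  x@medianPath
}

#' @describeIn DistanceResult the numeric power sum.
#' @param x an object.
#' @export
powerSum <- function(x) {
  stopifnot(is(x, "DistanceResult"))
  x@powerSum
}

#' @describeIn DistanceResult the exact integer power sum as a decimal
#'   string (`NA` for real-valued contributions).
#' @export
powerSumExact <- function(x) {
  stopifnot(is(x, "DistanceResult"))
  x@powerSumExact
}

#' @describeIn DistanceResult the distance value.
#' @export
distanceValue <- function(x) {
  stopifnot(is(x, "DistanceResult"))
  x@distance
}

#' @describeIn DistanceResult the norm order p.
#' @export
normOrder <- function(x) {
  stopifnot(is(x, "DistanceResult"))
  x@p
}
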