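#' Lp cophenetic distance between two rooted binary trees
#'
#' Computes \eqn{d_p(T, T') = (\sum_{i \le j} |\xi(\mathrm{lca}_T(x_i,x_j))
#' - \xi'(\mathrm{lca}_{T'}(x_i,x_j))|^p)^{1/p}} for a finite integer
#' \eqn{p \ge 1}, or the maximum absolute difference for `p = Inf`, with a
#' fixed lexicographic leaf ordering shared by both trees.
#'
#' The two contribution functions must run in the same direction (both
#' ascending or both descending); mixing kinds of the same direction (say
#' subtree height against subtree size) is allowed and yields a cost rather
#' than a metric.  Ascending pairs are jointly negated to the descending
#' convention internally, which changes no pairwise difference.
#'
#' `algorithm = "fast"` uses the median-vertex divide-and-conquer: each
#' level splits both trees at a median vertex, classifies leaf pairs into
#' ten categories, handles the four non-mixed categories by recursion on
#' lca-preserving contractions and the six mixed categories by dedicated
#' near-linear routines, down to a naive base case of `baseThreshold`
#' leaves.  `algorithm = "naive"` is the direct quadratic double loop.
#' Both return identical power sums -- bit-exactly so for integer-valued
#' contributions, where all arithmetic is exact.  For real-valued
#' (weighted) contributions the computation runs in double precision and
#' `p` is capped at `maxRealP`, beyond which the alternating binomial
#' expansions lose too much precision.
#'
#' @param tree1,tree2 `phylo` objects (annotated on the fly with
#'   `contribution`) or ready-made [AnnotatedTree-class] objects over the
#'   same leaf set.
#' @param p the norm order: a single integer `>= 1`, or `Inf`.
#' @param contribution contribution kind(s) passed to [annotateTree()];
#'   either one kind for both trees or a vector of two.
#' @param algorithm `"fast"` (divide and conquer) or `"naive"`
#'   (quadratic reference).
#' @param baseThreshold recursion base-case size for the fast algorithm;
#'   subproblems with at most this many leaves are handled naively.
#' @param maxRealP largest finite `p` accepted for real-valued
#'   contributions.
#' @return a [DistanceResult-class].
#' @examples
#' t1 <- readNewick("((a,b),c);")
#' t2 <- readNewick("(a,(b,c));")
#' cophDist(t1, t2, p = 1, contribution = "depth")   # power sum 4
#' cophDist(t1, t2, p = Inf, contribution = "depth") # distance 1
#' @seealso [copheneticVector()], [seqPrd()], [getCntr()]
#' @export
cophDist <- function(tree1, tree2, p = 2,
                     contribution = "depth",
                     algorithm = c("fast", "naive"),
                     baseThreshold = 5L, maxRealP = 15L) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(p) == 1, is.numeric(p))
  if (is.finite(p)) {
    if (p < 1 || p != round(p))
      stop("p must be a positive integer or Inf", call. = FALSE)
    p <- as.integer(p)
  }
  contribution <- rep_len(as.character(contribution), 2L)
  at1 <- if (is(tree1, "AnnotatedTree")) tree1
         else annotateTree(tree1, contribution[1])
  at2 <- if (is(tree2, "AnnotatedTree")) tree2
         else annotateTree(tree2, contribution[2])
  if (at1@direction != at2@direction)
    stop("contribution functions run in opposite directions (",
         at1@kind, " is ", at1@direction, ", ", at2@kind, " is ",
         at2@direction, "); a tree pair needs a common direction",
         call. = FALSE)
  idx <- sharedLeafIndex(at1, at2)
  at1 <- asDescending(at1)
  at2 <- asDescending(at2)
  integerMode <- at1@integerValued && at2@integerValued
  if (!integerMode && is.finite(p) && p > maxRealP)
    stop("real-valued contributions support p <= ", maxRealP,
         " (set maxRealP to override at your own numerical risk)",
         call. = FALSE)
  n <- length(idx)
  e1 <- .encodeTree(at1, idx)
  e2 <- .encodeTree(at2, idx)
  if (is.infinite(p)) {
    v <- if (algorithm == "fast")
      .cppCophDistInf(e1, e2, as.integer(baseThreshold), n)
    else .cppNaiveDistInf(e1, e2, n)
    return(new("DistanceResult", p = Inf, powerSum = v,
               powerSumExact = NA_character_, distance = v,
               algorithm = algorithm, integerValued = integerMode,
               n = as.integer(n)))
  }
  r <- if (algorithm == "fast")
    .cppCophDist(e1, e2, p, integerMode, as.integer(baseThreshold), n)
  else .cppNaiveDist(e1, e2, p, integerMode, n)
  ps <- r$value
  dist <- if (is.finite(ps)) ps^(1 / p) else exp(r$log / p)
  new("DistanceResult", p = as.numeric(p), powerSum = ps,
      powerSumExact = if (is.null(r$exact)) NA_character_ else r$exact,
      distance = dist, algorithm = algorithm,
      integerValued = integerMode, n = as.integer(n))
}

#' Pairwise absolute power sum of two sorted sequences
#'
#' Evaluates \eqn{\sum_{i,j} |\alpha_i - \beta_j|^p} for two non-decreasing
#' sequences in \eqn{O(p(k+m))} time via streaming prefix power sums and a
#' binomial expansion, instead of the \eqn{O(p k m)} nested loop.  This is
#' the engine behind the crossed double-mixed partial distance.  When all
#' inputs are integers the computation is exact (arbitrary precision); the
#' exact decimal value is attached as attribute `"exact"`.
#'
#' @param alpha,beta numeric vectors sorted non-decreasingly (either may be
#'   empty, giving 0).
#' @param p a finite integer norm order `>= 1`.
#' @return the power sum as a numeric scalar, with attribute `"exact"`.
#' @examples
#' seqPrd(c(0, 2), 1, p = 1)       # |0-1| + |2-1| = 2
#' seqPrd(c(1, 3), c(2, 4), p = 2) # 1 + 9 + 1 + 1 = 12
#' @export
seqPrd <- function(alpha, beta, p) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(p) == 1,
            is.finite(p), p >= 1, p == round(p))
  if (is.unsorted(alpha) || is.unsorted(beta))
    stop("seqPrd requires non-decreasing sequences", call. = FALSE)
  if (length(alpha) == 0 || length(beta) == 0) {
    out <- 0
    attr(out, "exact") <- "0"
    return(out)
  }
  integerMode <- .isWholeNumber(alpha) && .isWholeNumber(beta)
  r <- .cppSeqPrd(as.numeric(alpha), as.numeric(beta), as.integer(p),
                  integerMode)
  out <- r$value
  attr(out, "exact") <- if (is.null(r$exact)) NA_character_ else r$exact
  out
}

#' Median-path counter sequence (GetCntr)
#'
#' For a set `X` of upper-tree leaves, returns the contribution values
#' \eqn{\xi(\mathrm{lca}(x, t))} for each `x` in `X`, where `t` is the
#' median vertex of the split.  Each such lca lies on the median path;
#' values are emitted in root-to-median order, so for a descending
#' contribution the sequence is non-decreasing -- exactly the sortedness
#' [seqPrd()] requires, without an explicit sort.
#'
#' @param at an [AnnotatedTree-class].
#' @param split a [MedianSplit-class] of the same tree.
#' @param X character vector of leaf labels, a subset of `upperLeaves(split)`.
#' @return numeric vector of length `length(X)`.
#' @examples
#' at <- annotateTree(readNewick("((a,b),c);"), "depth")
#' sp <- medianSplit(at)
#' getCntr(at, sp, "c")
#' @export
getCntr <- function(at, split, X) {
  stopifnot(is(at, "AnnotatedTree"), is(split, "MedianSplit"))
  if (length(X) == 0) return(numeric(0))
  if (!all(X %in% split@A))
    stop("X must be a subset of the upper-tree leaves A", call. = FALSE)
  phy <- at@tree
  ca <- .childArrays(phy)
  path <- split@medianPath
  onPath <- logical(ca$nv)
  onPath[path] <- TRUE
  pos <- integer(ca$nv)
  pos[path] <- seq_along(path)
  counts <- integer(length(path))
  for (lab in X) {
    v <- match(lab, phy$tip.label)
    while (!onPath[v]) v <- ca$par[v]
    counts[pos[v]] <- counts[pos[v]] + 1L
  }
  rep(at@xi[path], counts)
}

#' Binomial coefficients by the multiplicative recurrence
#'
#' Returns \eqn{\binom{p}{i}} for `i = 0..p`, computed exactly through
#' \eqn{a_i = a_{i-1}(p - i + 1)/i} in arbitrary-precision arithmetic, as
#' decimal strings (they overflow doubles beyond p of about 60).
#'
#' @param p a non-negative integer.
#' @return character vector of length `p + 1`.
#' @export
binomialCoefficients <- function(p) {
  stopifnot(length(p) == 1, is.finite(p), p >= 0, p == round(p))
  .cppBinom(as.integer(p))
}

#' Top-level partial distances of the ten pair categories
#'
#' Splits both trees at their median vertices and returns the ten partial
#' power sums (categories `N1..N4`, `S1..S4`, `D1`, `D2`; see
#' [classifyPairs()]) computed by the category-specific routines.  Their
#' sum equals the total power sum.  Intended for component-level
#' validation; values are returned as doubles.
#'
#' @param at1,at2 [AnnotatedTree-class] objects over the same leaf set,
#'   same direction.
#' @param p a finite integer norm order.
#' @return named numeric vector of length 10.
#' @export
partialDistances <- function(at1, at2, p) {
  stopifnot(is(at1, "AnnotatedTree"), is(at2, "AnnotatedTree"),
            length(p) == 1, is.finite(p), p >= 1, p == round(p))
  if (at1@direction != at2@direction)
    stop("contribution directions differ", call. = FALSE)
  idx <- sharedLeafIndex(at1, at2)
  at1 <- asDescending(at1)
  at2 <- asDescending(at2)
  integerMode <- at1@integerValued && at2@integerValued
  .cppTopPartials(.encodeTree(at1, idx), .encodeTree(at2, idx),
                  as.integer(p), integerMode, length(idx))
}
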