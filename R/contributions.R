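#' Annotate a tree with a path-monotonic contribution function
#'
#' Computes the per-vertex contribution \eqn{\xi} used to fill cophenetic
#' vectors.  Supported kinds:
#' \describe{
#'   \item{`depth`}{number of edges from the vertex to the root
#'     (descending: ancestors have smaller values).}
#'   \item{`height`}{maximum number of edges from the vertex to a leaf of
#'     its subtree (ascending).}
#'   \item{`size`}{number of leaves in the subtree (ascending).  Defined
#'     combinatorially; branch lengths are ignored.}
#'   \item{`weighted_depth`}{sum of branch lengths from the vertex to the
#'     root; a root-edge length (`phy$root.edge`), if present, is added to
#'     every vertex's value (descending).}
#'   \item{`weighted_height`}{maximum branch-length sum from the vertex to
#'     a leaf of its subtree; the root edge does not participate, a
#'     vertex's height being internal to its subtree (ascending).}
#' }
#' A custom annotation can be supplied through `xi` + `direction`; it is
#' validated for per-edge monotonicity but nothing more.
#'
#' @param phy a rooted binary `phylo` (or an [AnnotatedTree-class], returned
#'   unchanged).
#' @param kind contribution kind, one of `"depth"`, `"height"`, `"size"`,
#'   `"weighted_depth"`, `"weighted_height"`.
#' @param xi optional numeric vector of custom contributions, one per
#'   vertex in phylo node order; overrides `kind`.
#' @param direction required with `xi`: `"ascending"` or `"descending"`.
#' @return an [AnnotatedTree-class].
#' @examples
#' at <- annotateTree(readNewick("(a,(b,c));"), "size")
#' xiValues(at)
#' @export
annotateTree <- function(phy,
                         kind = c("depth", "height", "size",
                                  "weighted_depth", "weighted_height"),
                         xi = NULL, direction = NULL) {
  if (is(phy, "AnnotatedTree")) return(phy)
  .assertBinaryPhylo(phy)
  if (!is.null(xi)) {
    if (is.null(direction))
      stop("a custom 'xi' needs an explicit 'direction'", call. = FALSE)
    return(new("AnnotatedTree", tree = phy, xi = as.numeric(xi),
               direction = direction,
               integerValued = .isWholeNumber(xi), kind = "custom"))
  }
  kind <- match.arg(kind)
  weighted <- kind %in% c("weighted_depth", "weighted_height")
  if (weighted) {
    if (is.null(phy$edge.length) || anyNA(phy$edge.length))
      stop("contribution '", kind,
           "' needs branch lengths on every edge", call. = FALSE)
    w <- phy$edge.length
  } else {
    w <- rep(1, nrow(phy$edge))
  }
  ca <- .childArrays(phy)
  root <- .rootNode(phy)
  nv <- ca$nv
  ewt <- numeric(nv)                  # weight of the edge above each vertex
  ewt[phy$edge[, 2]] <- w
  xi <- numeric(nv)
  if (kind %in% c("depth", "weighted_depth")) {
    for (v in rev(.postorderNodes(ca, root)))   # preorder
      if (v != root) xi[v] <- xi[ca$par[v]] + ewt[v]
    if (kind == "weighted_depth" && !is.null(phy$root.edge))
      xi <- xi + phy$root.edge
    dir <- "descending"
  } else if (kind == "size") {
    xi <- as.numeric(.subtreeSizes(ca, root))
    dir <- "ascending"
  } else {  # height / weighted_height
    for (v in .postorderNodes(ca, root)) {
      if (ca$lft[v] > 0L)
        xi[v] <- max(xi[ca$lft[v]] + ewt[ca$lft[v]],
                     xi[ca$rgh[v]] + ewt[ca$rgh[v]])
    }
    dir <- "ascending"
  }
  new("AnnotatedTree", tree = phy, xi = xi, direction = dir,
      integerValued = .isWholeNumber(xi), kind = kind)
}

#' Normalize an annotation to the descending convention
#'
#' The divide-and-conquer machinery assumes descending contributions
#' (ancestors carry smaller-or-equal values).  An ascending annotation is
#' converted by negating every \eqn{\xi}; applied jointly to both trees of
#' a pair this leaves every pairwise difference \eqn{|\xi(u) - \xi'(u')|} --
#' and hence every distance -- unchanged, and preserves integer-valuedness.
#' A descending annotation is returned as is (so the operation is
#' idempotent).
#'
#' @param at an [AnnotatedTree-class].
#' @return an [AnnotatedTree-class] with `direction == "descending"`.
#' @export
asDescending <- function(at) {
  stopifnot(is(at, "AnnotatedTree"))
  if (at@direction == "descending") return(at)
  new("AnnotatedTree", tree = at@tree, xi = -at@xi,
      direction = "descending", integerValued = at@integerValued,
      kind = at@kind)
}

# direction implied by a contribution kind
.kindDirection <- function(kind) {
  if (kind %in% c("depth", "weighted_depth")) "descending" else "ascending"
}
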