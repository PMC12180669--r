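#' Cophenetic vector of an annotated tree
#'
#' The cophenetic vector collects \eqn{\xi(\mathrm{lca}(x_i, x_j))} over all
#' leaf pairs \eqn{i \le j}, diagonal included (the lca of a leaf with
#' itself is the leaf, so entry \eqn{(i,i)} is \eqn{\xi(x_i)}).  This is a
#' deliberately plain reference implementation: it resolves each lca by
#' comparing explicit root-to-leaf ancestor paths, in \eqn{O(n^2)} time.
#'
#' @param at an [AnnotatedTree-class].
#' @param order optional character vector of leaf labels fixing the
#'   ordering (defaults to lexicographic).
#' @return a symmetric numeric matrix with `order` as dimnames; the upper
#'   triangle including the diagonal is the cophenetic vector.
#' @examples
#' at <- annotateTree(readNewick("(a,(b,c));"), "depth")
#' copheneticVector(at)
#' @export
copheneticVector <- function(at, order = NULL) {
  stopifnot(is(at, "AnnotatedTree"))
  phy <- at@tree
  if (is.null(order)) order <- sort(phy$tip.label, method = "radix")
  if (!setequal(order, phy$tip.label))
    stop("'order' must cover exactly the leaf set", call. = FALSE)
  ca <- .childArrays(phy)
  root <- .rootNode(phy)
  tipOf <- match(order, phy$tip.label)
  # root-to-leaf ancestor paths
  paths <- lapply(tipOf, function(tp) {
    p <- tp
    v <- tp
    while (v != root) {
      v <- ca$par[v]
      p <- c(v, p)
    }
    p
  })
  n <- length(order)
  M <- matrix(0, n, n, dimnames = list(order, order))
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- paths[[i]]; b <- paths[[j]]
      k <- min(length(a), length(b))
      common <- which(a[seq_len(k)] == b[seq_len(k)])
      lca <- a[max(common)]
      M[i, j] <- M[j, i] <- at@xi[lca]
    }
  }
  M
}
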