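#' Read a rooted binary tree from Newick
#'
#' Parses a single Newick string (or the first tree in a file) and validates
#' it as a rooted, strictly binary tree with unique leaf labels.  Branch
#' lengths, when present, are kept as edge weights; a length attached to the
#' outermost group is kept as the root-edge weight (`$root.edge`).  Internal
#' node labels are ignored.  Quoted leaf labels are supported; unquoted
#' labels should be restricted to `[A-Za-z0-9_.-]`.
#'
#' @param x a Newick string (must contain the terminating `";"`) or the path
#'   to a file holding one tree.
#' @return a `phylo` object.
#' @examples
#' phy <- readNewick("(a,(b,c));")
#' writeNewick(phy)
#' @seealso [writeNewick()], [sharedLeafIndex()]
#' @export
readNewick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  isText <- grepl(";", x, fixed = TRUE)
  if (!isText && !file.exists(x))
    stop("'", x, "' is neither a Newick string (no ';') nor an existing file",
         call. = FALSE)
  txt <- if (isText) x else paste(readLines(x, warn = FALSE), collapse = "")
  .checkNewickSyntax(txt)
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: unreadable tree", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  .assertBinaryPhylo(phy)
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  phy
}

# cheap structural scan so syntax errors can name a position
.checkNewickSyntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  inq <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inq <- !inq
    if (inq) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at position %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  if (!grepl(";", txt, fixed = TRUE))
    stop("Newick parse error: missing ';' terminator", call. = FALSE)
  invisible(TRUE)
}

#' Write a tree in Newick format
#'
#' The inverse of [readNewick()]: edge weights and the root-edge weight are
#' preserved, so reading the output back yields a tree isomorphic to the
#' input with identical labels and weights.
#'
#' @param phy a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
writeNewick <- function(phy, file = NULL) {
  .assertBinaryPhylo(phy)
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Common leaf ordering for a tree pair
#'
#' The cophenetic vector depends on a fixed leaf ordering shared by both
#' trees; this returns the lexicographic (byte-order, locale-independent)
#' ordering of the common label set as a named index vector.
#'
#' @param t1,t2 `phylo` or [AnnotatedTree-class] objects over the same leaf
#'   label set.
#' @return named integer vector mapping each label to its position
#'   `1..n`.
#' @export
sharedLeafIndex <- function(t1, t2) {
  l1 <- if (is(t1, "AnnotatedTree")) t1@tree$tip.label else t1$tip.label
  l2 <- if (is(t2, "AnnotatedTree")) t2@tree$tip.label else t2$tip.label
  if (!setequal(l1, l2)) {
    dif <- sort(c(setdiff(l1, l2), setdiff(l2, l1)))
    stop("leaf sets differ; symmetric difference: {",
         paste(dif, collapse = ", "), "}", call. = FALSE)
  }
  lab <- sort(unique(l1), method = "radix")
  idx <- seq_along(lab)
  names(idx) <- lab
  idx
}
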