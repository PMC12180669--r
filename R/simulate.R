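#' Random rooted binary trees under the Yule or uniform model
#'
#' Two classic null models for phylogenetic tree shape, both producing
#' unweighted (no branch length) rooted binary trees:
#' \describe{
#'   \item{`yule`}{start from a two-leaf cherry and repeatedly split a
#'     uniformly chosen leaf until `n` leaves are present; labels are then
#'     assigned by a uniform random permutation.}
#'   \item{`uniform`}{sequential insertion: leaf `k+1` is attached to an
#'     edge chosen uniformly among the `2k - 1` positions (every edge plus
#'     a new-root position), which makes each of the \eqn{(2n-3)!!} labeled
#'     topologies equally likely.}
#' }
#'
#' @param n number of leaves (`>= 2`).
#' @param model `"yule"` or `"uniform"`.
#' @param labels leaf labels; defaults to `t1..tn`.
#' @param seed optional integer; when given the draw is performed under
#'   [withr::with_seed()] so the global RNG stream is untouched and the
#'   same seed always returns the same tree.
#' @return a `phylo` object.
#' @examples
#' phy <- randomTree(8, "yule", seed = 1)
#' identical(writeNewick(phy), writeNewick(randomTree(8, "yule", seed = 1)))
#' @export
randomTree <- function(n, model = c("yule", "uniform"), labels = NULL,
                       seed = NULL) {
  model <- match.arg(model)
  stopifnot(length(n) == 1, n >= 2, n == round(n))
  n <- as.integer(n)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  .withSeed(seed, {
    if (model == "yule") .randomYule(n, labels) else .randomUniform(n, labels)
  })
}

.randomYule <- function(n, labels) {
  nv <- 2L * n - 1L
  par <- integer(nv); lft <- integer(nv); rgh <- integer(nv)
  # root 1 with cherry 2,3
  par[2:3] <- 1L; lft[1] <- 2L; rgh[1] <- 3L
  leaves <- c(2L, 3L)
  cnt <- 2L
  nextid <- 4L
  while (cnt < n) {
    i <- sample.int(cnt, 1L)
    v <- leaves[i]
    a <- nextid; b <- nextid + 1L
    nextid <- nextid + 2L
    par[a] <- v; par[b] <- v
    lft[v] <- a; rgh[v] <- b
    leaves[i] <- a
    cnt <- cnt + 1L
    leaves[cnt] <- b
  }
  leafLab <- character(nv)
  leafLab[leaves] <- sample(labels)
  .arraysToPhylo(par, lft, rgh, root = 1L, leafLab = leafLab)
}

.randomUniform <- function(n, labels) {
  nv <- 2L * n - 1L
  par <- integer(nv); lft <- integer(nv); rgh <- integer(nv)
  leafLab <- character(nv)
  root <- 1L
  leafLab[1L] <- labels[1]
  nextid <- 2L
  for (j in 2:n) {
    u <- sample.int(nextid - 1L, 1L)   # any existing vertex: its parent
                                       # edge, or the root position if u
                                       # is the root
    w <- nextid; l <- nextid + 1L
    nextid <- nextid + 2L
    leafLab[l] <- labels[j]
    if (u == root) {
      lft[w] <- root; rgh[w] <- l
      par[root] <- w; par[l] <- w
      root <- w
    } else {
      pu <- par[u]
      if (lft[pu] == u) lft[pu] <- w else rgh[pu] <- w
      par[w] <- pu
      lft[w] <- u; rgh[w] <- l
      par[u] <- w; par[l] <- w
    }
  }
  .arraysToPhylo(par, lft, rgh, root, leafLab)
}

# convert parent/child arrays (1-based, 0 = none) into a phylo object
.arraysToPhylo <- function(par, lft, rgh, root, leafLab) {
  nv <- length(par)
  lst <- list(parent = ifelse(seq_len(nv) == root, -1L, par - 1L),
              left = lft - 1L, right = rgh - 1L,
              leaf = integer(nv), xi = numeric(nv))
  isLeaf <- lft == 0L
  labs <- leafLab[isLeaf]
  ord <- sort(labs, method = "radix")
  lst$leaf <- rep(-1L, nv)
  lst$leaf[isLeaf] <- match(leafLab[isLeaf], ord) - 1L
  dec <- .phyloFromArrays(lst, ord)
  dec$phy
}

#' A pair of independent random trees on a common label set
#'
#' @inheritParams randomTree
#' @return list of two `phylo` objects sharing `labels`.
#' @export
randomTreePair <- function(n, model = c("yule", "uniform"), labels = NULL,
                           seed = NULL) {
  model <- match.arg(model)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  .withSeed(seed, list(randomTree(n, model, labels),
                       randomTree(n, model, labels)))
}

#' Sampled distributions of cophenetic distances
#'
#' Draws `q` independent pairs of random `n`-leaf trees and computes the
#' cophenetic distance of every pair for each combination of contribution
#' kind and norm order, mirroring a distribution study: frequencies of
#' finite-p distances are grouped into `bins` equal-width bins over the
#' observed range, while L-infinity distances (integers, for the unweighted
#' kinds) are tabulated exactly without binning.  Mean and standard
#' deviation are reported per (kind, p).
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n leaves per tree.
#' @param q number of tree pairs.
#' @param contributions character vector of contribution kinds.
#' @param p numeric vector of norm orders (may include `Inf`).
#' @param bins number of histogram bins for finite p.
#' @param seed optional integer seed (see [randomTree()]).
#' @return a list with elements `histogram` (data.frame: kind, p, bin_lo,
#'   bin_hi, count), `summary` (kind, p, mean, sd) and `values` (long
#'   data.frame of raw distances).
#' @export
sampleDistribution <- function(model = c("yule", "uniform"), n = 100L,
                               q = 100L,
                               contributions = c("depth", "height", "size"),
                               p = c(1, 2, Inf), bins = 200L, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2, q >= 1)
  combos <- expand.grid(kind = contributions, p = p,
                        stringsAsFactors = FALSE)
  .withSeed(seed, {
    vals <- matrix(0, nrow = q, ncol = nrow(combos))
    for (i in seq_len(q)) {
      pair <- randomTreePair(n, model)
      ann1 <- lapply(unique(contributions), function(k)
        annotateTree(pair[[1]], k))
      ann2 <- lapply(unique(contributions), function(k)
        annotateTree(pair[[2]], k))
      names(ann1) <- names(ann2) <- unique(contributions)
      for (cc in seq_len(nrow(combos))) {
        k <- combos$kind[cc]
        vals[i, cc] <- distanceValue(
          cophDist(ann1[[k]], ann2[[k]], p = combos$p[cc]))
      }
    }
    hist <- list(); summ <- list()
    for (cc in seq_len(nrow(combos))) {
      v <- vals[, cc]
      if (is.infinite(combos$p[cc])) {
        tb <- table(v)
        hist[[cc]] <- data.frame(kind = combos$kind[cc], p = combos$p[cc],
                                 bin_lo = as.numeric(names(tb)),
                                 bin_hi = as.numeric(names(tb)),
                                 count = as.integer(tb))
      } else if (max(v) == min(v)) {
        hist[[cc]] <- data.frame(kind = combos$kind[cc], p = combos$p[cc],
                                 bin_lo = min(v), bin_hi = max(v),
                                 count = length(v))
      } else {
        br <- seq(min(v), max(v), length.out = bins + 1L)
        idx <- findInterval(v, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
        cnt <- tabulate(idx, nbins = bins)
        hist[[cc]] <- data.frame(kind = combos$kind[cc], p = combos$p[cc],
                                 bin_lo = br[-length(br)], bin_hi = br[-1],
                                 count = cnt)
      }
      summ[[cc]] <- data.frame(kind = combos$kind[cc], p = combos$p[cc],
                               mean = mean(v), sd = sd(v))
    }
    values <- do.call(rbind, lapply(seq_len(nrow(combos)), function(cc)
      data.frame(kind = combos$kind[cc], p = combos$p[cc],
                 distance = vals[, cc])))
    list(histogram = do.call(rbind, hist),
         summary = do.call(rbind, summ),
         values = values,
         model = model, n = n, q = q)
  })
}

#' Write a sampled distribution as TSV
#'
#' @param x result of [sampleDistribution()].
#' @param histFile,summaryFile output paths (either may be `NULL` to
#'   skip).  `Inf` is rendered as `"inf"` in the `p` column.
#' @return `x`, invisibly.
#' @export
writeDistributionTSV <- function(x, histFile = NULL, summaryFile = NULL) {
  fmt <- function(df) {
    df$p <- ifelse(is.infinite(df$p), "inf", format(df$p, trim = TRUE))
    df
  }
  if (!is.null(histFile))
    write.table(fmt(x$histogram), histFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(summaryFile))
    write.table(fmt(x$summary), summaryFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(x)
}
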