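#' Oracle self-test: fast versus naive algorithm
#'
#' Draws seeded random tree pairs across models, sizes, contribution kinds
#' and norm orders, computes every distance with both the divide-and-conquer
#' and the naive algorithm, and reports mismatches.  For integer-valued
#' contributions the comparison is bit-exact on the exact power sums; for
#' `p = Inf` the two maxima are compared as doubles.
#'
#' `perturb = TRUE` injects a deliberate fault on the first pair: one leaf
#' contribution fed only to the fast path is lowered by 1, which moves a
#' single cophenetic entry (the leaf's diagonal term) and therefore must
#' change any finite-p power sum; the perturbed pair is pinned to `p = 2`
#' so the fault cannot hide behind an unchanged maximum.  It is a sanity
#' check that the comparison would actually detect a disagreement.
#'
#' @param pairs number of tree pairs to test.
#' @param seed optional integer seed.
#' @param nMin,nMax range of leaf counts (drawn log-uniformly).
#' @param contributions kinds to sample from.
#' @param p norm orders to sample from (may include `Inf`).
#' @param perturb inject a fault into the first comparison.
#' @return a list: `tested`, `mismatches`, `details` (data.frame with one
#'   row per pair) -- and nonzero `mismatches` means failure.
#' @export
selfTest <- function(pairs = 50L, seed = NULL, nMin = 2L, nMax = 128L,
                     contributions = c("depth", "height", "size"),
                     p = c(1, 2, 3, 5, 10, Inf), perturb = FALSE) {
  stopifnot(pairs >= 1, nMin >= 2, nMax >= nMin)
  .withSeed(seed, {
    rows <- vector("list", pairs)
    mism <- 0L
    for (i in seq_len(pairs)) {
      n <- round(exp(runif(1, log(nMin), log(nMax))))
      n <- max(nMin, min(nMax, n))
      model <- sample(c("yule", "uniform"), 1)
      kind <- sample(contributions, 1)
      pp <- sample(p, 1)
      tp <- randomTreePair(n, model)
      at1 <- annotateTree(tp[[1]], kind)
      at2 <- annotateTree(tp[[2]], kind)
      at1fast <- at1
      if (perturb && i == 1L) {
        # lower one leaf contribution (still monotone: depth leaves top out
        # their path, height/size leaves bottom it) in the fast input only
        pp <- 2
        xi <- at1@xi
        xi[1L] <- xi[1L] - 1
        at1fast <- new("AnnotatedTree", tree = at1@tree, xi = xi,
                       direction = at1@direction,
                       integerValued = at1@integerValued, kind = at1@kind)
      }
      fast <- cophDist(at1fast, at2, p = pp, algorithm = "fast")
      naiv <- cophDist(at1, at2, p = pp, algorithm = "naive")
      ok <- if (is.finite(pp) && fast@integerValued)
        identical(fast@powerSumExact, naiv@powerSumExact)
      else isTRUE(all.equal(fast@powerSum, naiv@powerSum,
                            tolerance = 1e-9))
      if (!ok) mism <- mism + 1L
      rows[[i]] <- data.frame(n = n, model = model, kind = kind, p = pp,
                              ok = ok)
    }
    list(tested = pairs, mismatches = mism,
         details = do.call(rbind, rows))
  })
}

#' Runtime comparison of the fast and naive algorithms
#'
#' Times both algorithms on locally generated Yule tree pairs over a grid
#' of sizes and norm orders.  Purely observational -- runtimes are
#' hardware-dependent and nothing is asserted.
#'
#' @param n integer vector of leaf counts.
#' @param p integer vector of norm orders.
#' @param q pairs per grid cell.
#' @param contribution contribution kind.
#' @param seed optional integer seed for tree generation.
#' @return data.frame with columns `n`, `p`, `algorithm`, `meanSeconds`.
#' @export
benchGrid <- function(n = c(200L, 400L), p = c(1L, 2L), q = 3L,
                      contribution = "depth", seed = NULL) {
  pairsByN <- .withSeed(seed, {
    out <- lapply(n, function(nn)
      lapply(seq_len(q), function(i) randomTreePair(nn, "yule")))
    names(out) <- as.character(n)
    out
  })
  rows <- list()
  for (nn in n) {
    anns <- lapply(pairsByN[[as.character(nn)]], function(tp)
      list(annotateTree(tp[[1]], contribution),
           annotateTree(tp[[2]], contribution)))
    for (pp in p) {
      for (alg in c("fast", "naive")) {
        tm <- system.time({
          for (a in anns) cophDist(a[[1]], a[[2]], p = pp, algorithm = alg)
        })[["elapsed"]]
        rows[[length(rows) + 1L]] <-
          data.frame(n = nn, p = pp, algorithm = alg, meanSeconds = tm / q)
      }
    }
  }
  do.call(rbind, rows)
}
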