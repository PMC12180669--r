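---
title: "Generalized cophenetic distances under all Lp norms: methods and design"
author: "cophdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized cophenetic distances under all Lp norms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophdist)
```

## The distance

Fix a rooted binary tree $T$ on leaves $x_1, \dots, x_n$ and a per-vertex
*contribution function* $\xi$.  The cophenetic vector of $(T, \xi)$ is
$\varphi(T,\xi) = [\xi(\mathrm{lca}_T(x_i, x_j))]_{i \le j}$, with the
diagonal included ($\mathrm{lca}(x,x) = x$).  For two trees on the same
leaves, the generalized $L_p$ cophenetic distance is

$$ d_p(T, T') = \Big( \sum_{i \le j} \big|\xi(\mathrm{lca}_T(x_i,x_j)) -
\xi'(\mathrm{lca}_{T'}(x_i,x_j))\big|^p \Big)^{1/p}, \qquad
d_\infty(T,T') = \max_{i \le j} |\cdot| . $$

The package supports the three classic integer-valued contributions —
vertex depth (edges to the root), subtree height, subtree leaf count — and
their branch-length-weighted depth/height variants.  All are
*path-monotonic*: monotone along every root-to-leaf path, descending for
depths (ancestors smaller) and ascending for heights and sizes.  $d_p$ is a
metric when both trees use the same kind of contribution; mixing kinds of a
common direction (e.g. height against size) is allowed and yields an
asymmetric cost useful when the trees come from different sources, such as
a gene tree compared against a species tree.

The leaf ordering is fixed lexicographically (byte order) on the labels and
applied identically to both trees, so results are machine- and
locale-independent.  Only a *fixed* ordering matters; the particular choice
does not affect any distance.

Two conventions worth noting:

* **Diagonal pairs** $\langle x, x\rangle$ are part of the vector; each
  contributes $|\xi(x) - \xi'(x)|^p$.
* **Root edge.**  A Newick tree may carry a length on its outermost group
  (`phylo$root.edge`).  It is added to every *weighted depth* (the tree
  hangs below a rooting edge) but does not participate in *weighted
  height*: a vertex's height is internal to its subtree.  Unweighted depth
  ignores it, being a pure edge count.

## Normalization to descending contributions

The divide-and-conquer machinery assumes descending contributions.  An
ascending annotation is negated (jointly for both trees), which leaves
every pairwise difference $|\xi(u) - \xi'(u')|$ — and hence every distance
— unchanged, preserves integer-valuedness exactly, and is idempotent.
Negation was chosen over alternatives (e.g. subtracting from a per-tree
maximum) precisely because it needs no tree-dependent offset that could
differ between the two trees and corrupt differences.

## The divide-and-conquer algorithm

`cophDist(..., algorithm = "fast")` implements a median-vertex
decomposition:

1. **Median vertex.**  Starting at the root, descend to the child with the
   larger subtree until the current vertex $t$ holds at most $n/2$ leaves.
   The subtree $T_t$ (the *lower tree*, leaves $B$) then has between $n/4$
   and $n/2$ leaves, and the *upper tree* $T^t$ (with $T_t$ replaced by a
   placeholder leaf, remaining leaves $A$) has between $n/2$ and $3n/4+1$
   vertices-worth of leaves.  Ties between equal-sized children go left,
   where "left" is the first child encountered in the edge table — any
   deterministic rule is valid; this one is reproducible across machines.
   The median is defined *procedurally* (an output of this descent), not
   as any vertex satisfying the size bounds: in `(a,(b,c))` the leaf `a`
   also satisfies the bounds, but only `b` and `c` are reachable by the
   descent.

2. **Classification.**  With median splits $(A, B)$ and $(A', B')$ of the
   two trees, every leaf falls in one of four cells $A{\cap}A'$,
   $A{\cap}B'$, $B{\cap}A'$, $B{\cap}B'$, and every unordered leaf pair in
   one of ten categories: four *non-mixed* (both leaves in the same cell),
   four *single-mixed*, two *double-mixed* (see `classifyPairs()`).
   Diagonal pairs are always non-mixed, so exactly one recursive call sees
   each of them.

3. **Non-mixed categories** are handled by recursion on both trees
   *contracted* to the cell's leaf set.  Contraction keeps, on every
   surviving vertex, the contribution of the original vertex it
   corresponds to (the original lca of its leaf set) — values are never
   recomputed on the contracted shape.  This is the linchpin: it makes the
   recursive subproblem's cophenetic entries identical to the originals.
   Empty cells contribute 0 and singleton cells just their diagonal term;
   subproblems of at most `baseThreshold` leaves (default 5, matching the
   recursion's analysis; exposed as a knob) are evaluated naively.

4. **Double-mixed categories.**  For pairs with one leaf above and one
   below the median in both trees, both lcas sit on the median paths and
   collapse to $\mathrm{lca}(x, t)$; the aligned type reduces to a single
   sum scaled by $|B \cap B'|$.  The crossed type reduces to
   $\sum_{i,j} |\alpha_i - \beta_j|^p$ over two sorted sequences
   (`getCntr()` emits them sorted for free by walking the median path
   top-down), which `seqPrd()` evaluates in $O(p(k+m))$ by streaming
   prefix power sums through a binomial expansion.

5. **Single-mixed categories** use a bottom-up sweep over the upper (or
   lower) part of one tree, accumulating per-vertex power-sum vectors
   $\langle \sum_x \beta_x^l \rangle_{l=0..p}$ of the partner-tree anchor
   values $\beta_x = \xi'(\mathrm{lca}_{T'}(x, t'))$.  For even $p$,
   $|a-b|^p = (a-b)^p$ and a single vector per vertex suffices.  For odd
   $p$ the sweep splits each leaf set by the sign of
   $\xi(v.\mathrm{parent}) - \beta_x$, which requires locating, for each
   leaf $x$, its highest ancestor $\omega_x$ with $\xi(\omega_x) \ge
   \beta_x$: a binary search over the sorted array of ancestors maintained
   during depth-first traversal.  Among tied ancestors the one closest to
   the root is chosen, so the correction sets
   $\Omega_v = \{x : \xi(v) \ge \beta_x > \xi(v.\mathrm{parent})\}$ stay
   disjoint even when $\xi$ ties along a path.  The remaining three
   single-mixed categories are obtained by the stated adaptations: run the
   sweep over the lower tree instead of the upper, and/or swap the two
   input trees.  Every variant is validated against its restricted
   brute-force oracle in the test suite, which pins down any orientation
   ambiguity empirically.

6. **$L_\infty$** is a separate max-monoid code path mirroring the $p=1$
   structure: partial sums become partial maxima, `seqPrd` degenerates to
   $\max(|\alpha_1-\beta_m|, |\alpha_k-\beta_1|)$, and the single-mixed
   sweeps propagate per-subtree minima/maxima of $\beta$.  No
   extrapolation from large finite $p$ is involved.

One pseudocode-level reading deserves a note: in the unified recursion the
lower leaf set of the second tree is $L_{T'} \setminus A'$ (the complement
of its own upper set); an alternative reading ($L_{T'} \setminus B$) would
mix leaf sets across trees and breaks the partition, so the former is
implemented.

## Exact arithmetic

The alternating binomial expansions in `seqPrd` and the single-mixed
sweeps are numerically brutal: at $p = 100$ the intermediate terms exceed
the result by many orders of magnitude and 64-bit floats cancel
catastrophically (and $\xi^p$ overflows them outright).  Whenever both
annotations are integer-valued, every power sum, power vector and binomial
coefficient is therefore computed in exact signed arbitrary-precision
integer arithmetic (a compact base-$2^{32}$ limb implementation in the
compiled core).  This makes the fast and naive algorithms agree
*bit-exactly* at any tested $p$ (the suite goes to 100, binomials to 200),
and the exact decimal power sum is reported in `powerSumExact`.  The
`distance` is still a double: for power sums beyond double range it is
recovered from the exact logarithm as $\exp(\log(\mathrm{ps})/p)$.

Real-valued (weighted) contributions run in double precision.  Supported
$p$ is capped at `maxRealP = 15` by default; the tolerance-based tests
compare fast against naive at relative $10^{-9}$ for $p \le 10$.  Binomial
coefficients for the real path are built by the same multiplicative
recurrence in doubles, exact up to that cap.

## The naive reference

`algorithm = "naive"` is the $\Theta(pn^2)$ double loop, kept deliberately
simple (explicit subtree leaf lists, one matrix of lca contributions per
tree pair) so that it is obviously correct; it serves both as a fallback
for small problems and as the oracle against which every fast-path
component is tested.  For integer contributions it groups equal
differences before exponentiating, so it too is exact at large $p$.  The
pure-R `copheneticVector()` — ancestor-path lca resolution, nothing shared
with the compiled code — is a second, independent oracle used by the test
suite (and cross-checked against `ape::mrca`).

## Random-tree models

`randomTree()` implements the two standard null models, both purely
topological (no branch lengths, matching how the distance distributions
are studied here):

* **Yule**: grow from a cherry by splitting a uniformly chosen leaf until
  $n$ leaves; labels are assigned afterwards by a uniform random
  permutation (the model itself is exchangeable, and no labeling scheme is
  canonical; the uniform assignment is the standard choice).
* **Uniform**: insert leaf $k+1$ on an edge chosen uniformly among the
  $2k-1$ positions (every parent edge plus a new-root position), which
  yields each of the $(2n-3)!!$ labeled topologies with equal probability
  — verified in the suite by a $\chi^2$ test over all 15 topologies at
  $n = 4$.

Every sampling entry point takes a `seed` and runs under
`withr::with_seed`, so draws are reproducible and the caller's RNG stream
is left untouched.  What these simulators emulate is tree *shape* under
two idealized nulls; they do not emulate branch lengths, non-binary nodes,
taxon-sampling biases or any evolutionary process with extinction, so
passing distribution tests says nothing about such features of real data —
for real trees the package is exercised through `readNewick()`.

`sampleDistribution()` draws tree pairs and tabulates distances: finite-p
values into 200 equal-width bins over the observed range (per kind and
$p$), $L_\infty$ values exactly (they are integers for the unweighted
kinds), with per-combination means and standard deviations.  A notable
qualitative feature it reproduces: for the subtree-size contribution at
$n = 100$, $L_\infty$ distances concentrate at 98, the value forced
whenever some leaf pair is a cherry (subtree size 2) in one tree and
separated only by the root (size 100) in the other.

## Problem sizes used by the checks

The test suite validates oracle equivalence on 1000 seeded random pairs
spanning $n \in \{2..256\}$, all three integer contributions, $p \in
\{1..10, 13, 50, 100\}$ and $\infty$; component routines against
brute-force oracles at $n \le 32$; median bounds on 1000 trees up to
$n = 512$; and the distribution mode on 200 pairs per model at $n = 100$
(a deliberate scale-down of the million-pair study such a distribution
would ideally use — the mode is extremely stable, the finer histogram
shape is not asserted).  The runtime comparison uses $n = 2000$, $p = 2$,
where the quadratic algorithm is reliably slower; no absolute runtimes or
crossover sizes are asserted, as those are hardware-dependent.

## Known limitations

* Trees must be strictly binary and rooted; multifurcations are rejected
  rather than resolved.
* Real-valued contributions are limited to moderate $p$ (see above);
  integer contributions have no such limit in correctness, only in time.
* The implementation optimizes clarity of correspondence with the
  published procedure over constant factors; at very large $p$ the exact
  integer arithmetic dominates runtime, and the naive algorithm's
  difference-grouping can make it surprisingly competitive there (the
  asymptotic advantage of the fast path is in $n$, not $p$).
* `medianVertices()` enumerates tie-breakings exhaustively and is meant
  for small trees.
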