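---
title: "Approximating the k-mismatch average common substring measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating the k-mismatch average common substring measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsk)
```

## The measure

Alignment-free phylogenetics needs a pairwise dissimilarity that can be
computed without a multiple alignment.  The *average common substring*
family does this with matching statistics.  For sequences $X$ and $Y$ over a
common alphabet, write $X_i$ for the suffix starting at position $i$ and
$\mathrm{LCP}_k(X_i, Y_j)$ for the longest common prefix of $X_i$ and $Y_j$
allowing at most $k$ mismatched positions.  The per-position statistic is

$$\lambda_k(i) = \max_j \left|\mathrm{LCP}_k(X_i, Y_j)\right|,$$

with $\mu_k(i)$ an attaining position in $Y$, and the (direction-dependent)
measure is the mean

$$\mathrm{ACS}_k(X, Y) = \frac{1}{|X|} \sum_{i=1}^{|X|} \lambda_k(i).$$

Two directed values are combined into the symmetric dissimilarity

$$d(X,Y) = \frac{1}{2}\left(\frac{\log |Y|}{\mathrm{ACS}_k(X,Y)} +
  \frac{\log |X|}{\mathrm{ACS}_k(Y,X)}\right) -
  \left(\frac{\log |X|}{|X|} + \frac{\log |Y|}{|Y|}\right),$$

where the subtracted term is the self-match baseline: for $X = Y$ of length
$n$, $\lambda_0(i) = n - i + 1$, so $\mathrm{ACS}_0 = (n+1)/2$ and
$d = -2\ln n / (n(n+1))$, slightly below zero.  Both closed forms are
asserted in the test suite to $10^{-12}$.

Computing $\lambda_k$ exactly is expensive (the known exact algorithms are
super-linear in $k$), which is why linear-time approximations matter for
genome-scale inputs.  This package implements three of them plus a
brute-force oracle:

* **exact** (`exact_lambda()`): tries every $j$ with a greedy mismatch-budget
  walk.  Quadratic; metered in character comparisons and refused beyond a
  configurable cap (default $10^7$).  It is the ground truth for all
  accuracy statements.
* **kmacs** (`kmacs_lambda()`): anchors at the maximal *exact* match of
  $X_i$ in $Y$ and extends forward through $k$ skipped mismatches:
  $\lambda(i) + 1 + |\mathrm{LCP}_{k-1}(X_{i+\lambda(i)+1},
  Y_{\mu(i)+\lambda(i)+1})|$, iterated.
* **ALFRED-G** (`alfredg_lambda()`): same idea with a 1-mismatch anchor
  ($\lambda_1, \mu_1$), requiring $k \ge 2$.  The anchor here comes from the
  brute-force oracle, so the method is restricted to oracle-sized inputs.
* **adyar** (`adyar_lambda()`): the two-phase forward/backward extension
  heuristic that is the core of this package, described next.

## The two-phase heuristic

A $k$-mismatch common substring consists of up to $k+1$ exact segments
separated by mismatch characters.  Forward-only greedy methods always use
the *first* segment as the anchor; if the maximal exact match of $X_i$
points at the wrong place in $Y$, the whole estimate suffers.  The key
observation is that *any* of the segments can serve as the anchor, and a
maximal exact match elsewhere in $X$ may be an interior segment of a long
$k$-mismatch match that starts earlier.

**Phase 1.**  For each position $i$ with $\lambda(i) > 0$ and each anchor
position $j$ attaining it, two arrays of length $k+1$ are computed by greedy
walks: $L_f[m]$, the $\le m$-mismatch extension forward from $(i, j)$, and
$L_r[m]$, the $\le m$-mismatch extension backward over the characters
strictly before $(i, j)$.  Splitting the budget as $t$ backward plus $k-t$
forward gives, for each $t = 0..k$, a genuine $\le k$-mismatch common
substring of length $L_r[t] + L_f[k-t]$ starting at $s = i - L_r[t]$; the
estimate at $s$ is raised to the maximum over all such candidates.

**Phase 2.**  Dropping the first character of a $\le k$-mismatch match
yields a $\le k$-mismatch match one character shorter, so a single
left-to-right pass applies `values[i] <- max(values[i], values[i-1] - 1)`.
Together with phase 1 this guarantees the estimate dominates the kmacs value
at every position (each kmacs chain is the $t = 0$ candidate of some anchor,
relocated by at most $L_r[0]$ and recovered by the decrement pass).

The phase-2 pass is applied *unconditionally*.  A variant that skips the
update when the dropped character was one of the previous match's mismatch
positions is available (`guard = TRUE`); it is never longer than the
unguarded pass and both remain sound lower bounds, so the unguarded form is
the default.

```{r worked}
X <- "AATCGGT"; Y <- "AATGGGAAACCGGT"
exact_lambda(X, Y, k = 1)$values[1]   # truth: AAT.CGGT matches Y_8 with 1 mismatch
kmacs_lambda(X, Y, k = 1)$values[1]   # forward-only greedy is misled by the anchor at Y_1
adyar_lambda(X, Y, k = 1)$values[1]   # backward extension recovers the full match
```

## Index and implementation choices

All anchor discovery runs on a generalized suffix array over
$X \,\$_1\, Y \,\$_2$ (prefix-doubling construction, Kasai LCP array,
sparse-table RMQ), built per pair in C++.  The two sentinels are unique
codes smaller than every residue, so no reported match ever crosses a
sequence boundary; matching statistics fall out of two rank-order sweeps,
and the full tie set of anchor positions per $i$ is enumerated from the
SA-contiguous block around the suffix's rank.

Decisions a user may care about:

* **Tie policy** (`ties`): when several $j$ attain $\lambda(i)$, the default
  `"all"` extends every one of them and keeps the longest result.  This is
  the accurate (and default) setting; `"first"` reproduces single-anchor
  greedy behavior.  Worst-case work grows with the mean anchor multiplicity
  $z$ (reported in `diagnostics`), and `anchor_limit` bounds it when needed.
* **Walk vs RMQ**: extensions walk the text by default and the LCP/RMQ
  machinery answers `lcp_query()`; the two policies are value-identical by
  construction and a property test enforces it.
* **LCP-0 fallback** (`fallback`): a position whose character never occurs
  in $Y$ has no anchor; the production setting copies the estimate of the
  next suffix (right-to-left assignment), as distance computation wants a
  filled array.  Copied values carry `NA` witnesses and are *estimates*:
  soundness (`values <= exact`) is only guaranteed with `fallback = FALSE`,
  which is what the property tests use.
* **Logarithm base** in the distance is natural log; the choice rescales
  all distances uniformly and cannot change neighbor-joining topology.
  Negative distances from near-identical pairs are kept (NJ tolerates
  them) unless `clamp = TRUE`.
* **Neighbor joining** uses the classic Q-criterion agglomeration with
  deterministic lowest-index tie-breaking, and clamps negative branch
  estimates to zero while transferring the deficit to the sibling edge, so
  trees are bit-reproducible.  Robinson–Foulds distances are raw
  bipartition symmetric-difference counts (the `treedist` convention).

## The synthetic-data generator

`random_sequence()`, `mutate_sequence()` and
`simulate_tree_and_sequences()` make every pipeline stage testable without
downloads.  The mutation model is deliberately minimal: i.i.d. uniform
per-site substitution to a different symbol (Jukes–Cantor-like), no indels,
no rate heterogeneity, no composition bias.  Ambiguity codes (`N`, `X`)
are accepted on input but never generated.  The clock-tree simulator draws
a random coalescent topology and applies one round of per-branch
substitution at a constant probability per branch, making expected
divergence proportional to path edge counts — an additive-enough regime for
NJ to recover the generating topology at low rates.

That is also the regime in which ACS$_k$ is informative, so passing tests
show that the estimators behave correctly *under per-site substitution
divergence*.  They do not show robustness to rearrangement, repeats,
horizontal transfer or indels, all of which real genomes have; the measure
itself (not just this implementation) degrades under strong indel
divergence.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run at desk scale, chosen so the
exact oracle remains the arbiter: accuracy suites use 50 mutated DNA pairs
of length 200 (soundness/dominance, all of $k = 1..5$), 10 pairs of length
1000 at substitution rates 0.05–0.20 (error-percentage comparison), and an
8-taxon, 5-kb end-to-end run at rate 0.02 for tree recovery.  At these sizes
the whole suite completes in about a minute.  All user-facing coordinates
are 1-based (internals are 0-based, converted at the R/C++ boundary);
chains and values returned by different methods are directly comparable
integer match lengths.

Known limitations: ALFRED-G depends on the quadratic oracle for its anchor,
so it does not scale past the comparison cap; the all-anchors tie policy is
worst-case quadratic on pathological repeat structures (cap it with
`anchor_limit`); and the heuristics are lower-bound estimators — they never
overshoot the exact value with the fallback off, but the fallback can.
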