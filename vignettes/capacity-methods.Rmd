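---
title: "Methods: capacity theory, saturated construction, and reorganization cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capacity theory, saturated construction, and reorganization cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(willshawcap)
```

## The model

The network is a single layer of `N` binary input units fully connected to
`N` binary output units through a binary weight matrix `W`. A pattern is an
`S`-subset of active units; cue and target are identical
(auto-association). Storage is clipped Hebbian: the pattern's all-ones
outer-product block is OR-ed into `W`, so storage is idempotent and
monotone — a connection, once made, is never unmade. Recall sums the cue's
active rows and fires every output whose sum reaches the threshold `T`;
recall is exact when the firing set equals the cue's active set. Two
parameters govern interference: the sparsity `S` and the minimum
differentiability `D`, the least number of active cells by which any two
stored patterns may differ (bitwise Hamming distance `2D` for
equal-sparsity vectors).

### Threshold convention

We fire on `sum >= T` with the canonical threshold `T = S - D + 1`. Under
it, a pattern's own outputs (sum `S`) always fire, and the ideal saturated
state places every non-member output sum at exactly `T - 1`, one unit below
firing. An alternative convention fires on `sum > T` with `T = S - D`; the
two are the same rule under the substitution `T_geq = T_strict + 1`, and
both are exposed (`recall(..., strict = TRUE)`, CLI flag
`--threshold-convention`). We made the `>=` form canonical because it lets
the "non-member sums equal `T - 1`" characterization of saturation and the
maximum usable threshold `T = S` (at `D = 1`) hold simultaneously; under a
strict rule with `T_max = S - 1` the same statements are internally
inconsistent unless shifted by one.

## Capacity theory

At the canonical threshold the units partition into `B = N/S` blocks and a
storable pattern selects, for each of the `S` local slots, the block that
contributes that slot's cell. The slots choose independently, giving

$$C(N, S) = (N/S)^S, \qquad C(N, S, D) = (N/S)^{S/D},$$

the second form via the equivalent network `N_eq = N/D`, `S_eq = S/D`
(groups of `D` units co-activate, so one equivalent cell stands for `D`
real cells). `capacity_closed_form` evaluates this by repeated integer
multiplication — exact whenever the result fits in a double's 53-bit
mantissa, which covers every network the package can enumerate; for larger
sweeps `capacity_log10` supplies the always-exact `S log10(N/S)`. We chose
doubles over an arbitrary-precision representation because no quantity
downstream (fractions, tables, comparisons) needs more than the exact
integer range, and the log form carries the large-`N` sweeps.

A literal double-sum expression for the same count,
`sum_{i=0}^{N/S-1} sum_{j=0}^{S} C(S, j) i^j`, telescopes by the binomial
theorem to `sum_{k=1}^{N/S} k^S`, which strictly exceeds `(N/S)^S` whenever
`B > 1` — the two expressions cannot both be the capacity. The brute-force
oracle decides the question: exhaustive search over all pattern families
certifies `(N/S)^{S/D}` as the true maximum on every tractable case (for
example `(4,2)` gives 4, not the literal sum's 5). The package therefore
treats the closed form as authoritative and ships the literal sum only as
`capacity_summation_as_printed`, with a test documenting the discrepancy.
The enumeration the double sum was presumably meant to encode ("block `i`
holds `j` active cells") over-counts by ignoring which local slots the `j`
cells occupy; since no reading of it reproduces the oracle-certified count
we did not attempt to repair it.

Capacity over divisor sparsities at fixed `N` peaks near `S = N/3`
(`optimal_sparsity`); ties are broken toward the smaller `S` because
sparser codes cost fewer active units for the same capacity, and the
tie-break is recorded in the result so tables are self-describing.

## The saturated construction

`build_saturated_matrix` realizes, on the equivalent network, the rule

```
W[i, j] = 1  <=>  block(i) == block(j)  or  perm[b_i](l_i) != perm[b_j](l_j)
```

with one slot permutation per block. Diagonal sub-matrices are all-ones
(the `B` orthogonal basis patterns saturate them); each off-diagonal
sub-matrix has exactly one zero per row and per column, placed where the
two blocks' permuted slots coincide. Cell-to-block assignment is
contiguous (`block = (i - 1) %/% S_eq + 1`); any other labelling is a
permutation similarity with identical capacity.

An alternative way to organize the orientations distinguishes sub-matrices
on the outer boundary of the grid from interior ones, each region sharing a
uniform orientation; stated at that level the rule is under-determined. We
implement the per-block-permutation family above, which provably
satisfies the one-zero-per-row/column constraint and transitive
consistency, and whose valid-pattern count the oracle confirms equals
`(N/S)^{S/D}` for every orientation choice; the two-orientation scheme is a
special case (all boundary blocks sharing one permutation, interior blocks
another). `validate_saturated` checks the structure of an arbitrary matrix,
including the transitive consistency of zero placements across block
triples, and reports violations with block coordinates. `D > 1` is built by
expanding each equivalent cell into a `D x D` all-ones block rather than by
a direct construction — the expansion is exact, and it keeps a single code
path oracle-verified.

## Enumeration by backtracking

A pattern is storable without error in a saturated matrix iff storing it
adds no connection, i.e. all ordered pairs of its cells are already
connected. `enumerate_valid_patterns` finds every such `S`-subset by
depth-first search in lexicographic order: a partial selection is extended
only with cells greater than the last chosen and bidirectionally connected
to all chosen, and a branch is cut when the surviving candidate pool cannot
reach size `S`. Lexicographic discipline makes the output deterministic and
reproducible; a `limit` argument caps the yield, and
`count_valid_patterns` counts without materializing. Correctness, not
speed, is the contract: a naive all-subsets checker serves as the test
oracle up to `N = 12`, and an independent closed-form generator
(`patterns_from_slot_assignments`, one cell per slot, each slot picking a
block) must produce the identical set on canonical specs. For matrices not
produced by the constructor the enumerator still answers the definitional
question ("which subsets add no connection"), but no capacity claim
attaches.

## Baselines

`random_fill` draws uniform random `S`-subsets and accepts a candidate iff
it is new, `D`-different from every stored pattern, and — after tentative
storage — every stored pattern still recalls exactly. Clipped storage is
not entry-wise reversible, so acceptance testing works on the candidate's
incremental effect (only entries inside the candidate's block can change),
which is equivalent to tentative store plus rollback but cheap. Stopping:
when `choose(N, S) <= 20000` the scan over candidates is exhaustive, so
termination is exact (and acceptance is uniform over the addable set,
distributionally identical to rejection sampling); above that, storage
stops after 10,000 consecutive rejections. These two defaults are recorded
in each result's metadata; the source material specifies neither, and the
values were chosen so that the exhaustive regime covers every desk-scale
network while the budget keeps large runs bounded.

`cpa_guided_fill` scores each admissible, recall-preserving candidate by
the cross-pattern activation after acceptance — the summed pre-threshold
activation of non-member outputs over all stored patterns — and stores the
minimizer, breaking ties lexicographically. Member outputs are excluded
from CPA since their sums are pinned at `S` and carry no interference
information. Candidates that would break recall are never scored. The
heuristic helps early but cannot escape a suboptimal prefix: near
saturation all surviving candidates score alike.

## Reorganization cost

Given a suboptimal stored set `R` and an optimal set `O`, `match_patterns`
assigns each `R`-pattern to a distinct `O`-pattern minimizing total bitwise
Hamming distance. "Best-matched" is implemented as a globally optimal
linear assignment (Hungarian method, `clue::solve_LSAP`), since greedy
nearest-matching can be arbitrarily worse; a greedy mode remains available
behind a flag for comparison. `work_curve` then prices the transformation:
sort matched pairs by conversion cost, convert the `k` cheapest by flipping
bits (cost = pairwise Hamming distance) and delete the remaining `|R| - k`
patterns at `S` bits each. Additions of optimal patterns absent from `R`
are free — only flips and deletions are priced — and the constant cost of
evaluating a pattern's viability is excluded by design. The curve's
increments obey `total(k) - total(k-1) = d_k - S` with `d_k` the `k`-th
smallest conversion cost, so with sorted costs the curve is unimodal and
its minimum is well defined. Because the intended x-axis ("incremental
interventions") is ambiguous between patterns converted and bits flipped,
the curve carries both columns (`k` and the cumulative `flips_bits`) and
`plot.work_curve` renders either.

## Numerical and design choices

* Indices are 1-based inside R and 0-based in the plain-text pattern and
  matrix file formats; conversion happens only at the file boundary.
* Degenerate inputs are first-class: `S = N` stores exactly one pattern,
  `S = 1` stores all `N` singletons at `T = 1`; both serve as boundary
  tests.
* Divisibility violations in sweeps are skipped with a message, never
  floored — silently rounding `S` or `D` would change the model.
* The exhaustive oracle refuses candidate spaces above 100 subsets and
  points to `verify_maximal`, which checks maximality in a single pass
  (definitionally, or via the zero-pair certificate valid for saturated
  matrices). Symmetric pruning — pinning the lexicographically smallest
  candidate as the first stored pattern — is justified by unit-relabelling
  symmetry and is validated against the unpruned search.
* All stochastic entry points take an explicit seed; the same seed yields
  the identical stored set.

## Problem sizes, and what the tests do and do not show

The test and verification suite works at desk scale: enumeration grids up
to `N = 24, S = 4` (1296 patterns), exhaustive oracle runs up to 100
candidate patterns, 50-seed random-fill ensembles at `N = 16, S = 4`, and
reorganization on networks up to `N = 8`. These sizes were chosen so that
every claim is either closed-form or independently brute-forced; the
closed-form results themselves hold at any scale by the block argument.
The synthetic setups emulate idealized conditions only — noiseless binary
cues identical to targets, exact-match recall, patterns of exactly equal
sparsity. They say nothing about graded weights, stochastic units,
noise-corrupted cues or pattern completion, all of which are out of scope;
in particular the high capacity here is bought by prioritizing pattern
separation, and threshold settings that favour completion of degraded cues
would trade differently.

## Known limitations

* Capacities above `2^53` are reported in log form only.
* The enumerator and oracle are exponential by nature; they are
  verification tools, not production pattern generators beyond desk scale.
* The reorganization model prices bits, not operations: it ignores the
  search cost of deciding which patterns to convert, and assumes the
  optimal target set is available (it is, deterministically, from the
  construction).
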