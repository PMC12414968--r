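# willshawcap

Pattern-storage capacity of single-layer binary feedforward associative
networks — closed-form theory, a deterministic construction that attains it,
and the tooling to test both.

## The problem

A single-layer, fully connected feedforward network with *N* binary input
units, *N* binary output units and binary (clipped Hebbian, Willshaw-type)
weights stores an auto-associative pattern — a binary vector with *S* active
units — by setting `W[i, j] = 1` for every ordered pair of active units
*(i, j)*; superimposed patterns are clipped to keep the matrix binary. A cue
is recalled by summing its active rows through *W* and firing every output
whose sum reaches the threshold *T*; recall is *exact* when the firing set
equals the cue. Store too many patterns and interference makes recall fail —
the onset of catastrophic forgetting.

How many patterns fit? With sparsity *S*, a minimum pattern
differentiability *D* (any two stored patterns must differ in at least *D*
active cells) and the matching threshold *T = S − D + 1*, the maximum is

```
C(N, S, D) = (N / S)^(S / D)
```

For *D* = 1 this is `(N/S)^S`: the *N* units split into *B = N/S* blocks,
and a storable pattern picks one cell per local slot, each slot choosing a
block independently. For *D* > 1 the network behaves like an equivalent
smaller network with `N_eq = N/D`, `S_eq = S/D`. At fixed *N* the capacity
peaks near *S ≈ N/3*, and it decreases as the differentiability constraint
*D* tightens.

The package provides, as separately testable pieces:

* **Closed-form capacity** (`capacity_closed_form`, `capacity_general`,
  `optimal_sparsity`, sweeps) — and `capacity_summation_as_printed`, a
  literal double-sum variant retained purely to document its discrepancy
  with the closed form.
* **A deterministic construction** (`grid_spec`, `build_saturated_matrix`)
  of a fully *saturated* matrix: diagonal sub-matrices all-ones, every
  off-diagonal sub-matrix with exactly one zero per row and column, the
  zero placement generated by per-block slot permutations. In this state
  every non-member output sum sits exactly one unit below threshold.
* **A backtracking enumerator** (`enumerate_valid_patterns`) that yields
  every pattern storable in the saturated matrix without adding a
  connection — exactly `(N/S)^(S/D)` of them.
* **Baselines** (`random_fill`, `cpa_guided_fill`): random sequential
  storage, and a variant guided by cross-pattern activation (CPA), the
  summed sub-threshold interference on non-member outputs. Both typically
  stall below the maximum.
* **A brute-force oracle** (`max_capacity_exhaustive`, `verify_maximal`)
  giving exact ground truth on tiny networks.
* **Reorganization analysis** (`match_patterns`, `work_curve`): the minimum
  work, in bit flips plus *S*-bit pattern deletions, to convert a
  suboptimal stored set into an optimal one, using an optimal Hungarian
  pattern matching.

## Worked example

```r
library(willshawcap)

params <- network_params(12, 4)          # N = 12, S = 4, D = 1, T = 4
W <- build_saturated_matrix(grid_spec(params))
pats <- enumerate_valid_patterns(W, 4)
length(pats)                             # 81  == capacity_closed_form(12, 4)
is_saturated_state(W, pats, params$T)    # TRUE

random_fill(params, seed = 1)
#> Sequential fill (random/exhaustive-scan (495 candidates)): 63 patterns
#>   stored (N = 12, S = 4, D = 1)
#>   theoretical maximum 81, fraction 77.8%

optimal_sparsity(12)$table
#>    S capacity
#> 1  1       12
#> 2  2       36
#> 3  3       64
#> 4  4       81      <- peak at S = N/3
#> 5  6       64
#> 6 12        1
```

The construction reaches all 81 = (12/4)^4 storable patterns; random
trial-and-error storage with seed 1 stalls at 63 (77.8%). Reorganizing a
suboptimal set is costed in bits — converting the two invalid 2-subsets of
a 4-unit network into optimal ones, for instance:

```r
O <- enumerate_valid_patterns(
  build_saturated_matrix(grid_spec(network_params(4, 2),
                                   perms = list(1:2, 2:1))), 2)
work_curve(list(c(1, 4), c(2, 3)), O, S = 2)
#>  k flips_bits removal_bits total_bits
#>  0          0            4          4
#>  1          2            2          4
#>  2          4            0          4
#> minimum work: 4 bits at k = 0 patterns converted
```

A thin command-line interface wraps the same functions
(`inst/cli/netcap.R`; subcommands `build-matrix`, `enumerate`, `baseline`,
`compare`, `sweep-n`, `sweep-s`, `reorganize`, `oracle`), reading flat
`key=value` config files and writing plain-text pattern/matrix files and
CSV tables with metadata headers. Pattern and matrix files use 0-based
indices.

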