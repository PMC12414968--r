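#' Empty binary connectivity matrix
#'
#' @param N number of units; the matrix is `N x N` (rows index input units,
#'   columns index output units).
#' @return integer matrix of zeros.
#' @export
empty_connectivity <- function(N) {
  N <- as_count(N, "N")
  matrix(0L, N, N)
}

#' Store a pattern by clipped Hebbian superposition
#'
#' Writes the all-ones outer-product block of the pattern's active units
#' into the binary connectivity matrix: `W[i, j] <- 1` for every ordered
#' pair of active units `(i, j)`. Superposition is clipped (binary OR), so
#' storage is idempotent and monotone: no entry ever decreases.
#'
#' @param W binary `N x N` connectivity matrix.
#' @param p integer vector of 1-based active unit indices.
#' @return the updated matrix.
#' @examples
#' W <- empty_connectivity(4)
#' W <- store_pattern(W, c(1, 2))
#' @export
store_pattern <- function(W, p) {
  p <- check_pattern(p, nrow(W))
  W[p, p] <- 1L
  W
}

#' Store a collection of patterns
#'
#' @param W binary connectivity matrix.
#' @param patterns list of active-index vectors (or a `pattern_set`).
#' @return the updated matrix.
#' @export
store_patterns <- function(W, patterns) {
  for (p in patterns) W <- store_pattern(W, p)
  W
}

#' Thresholded recall of a cue pattern
#'
#' The cue's active units are summed through the connectivity matrix and
#' each output unit fires iff its pre-threshold sum reaches the threshold:
#' `sum >= T` by default, or `sum > T` under the strict-inequality
#' convention (`strict = TRUE`, in which the maximum usable threshold is
#' `S - 1` rather than `S`).
#'
#' @param W binary connectivity matrix.
#' @param p cue pattern (1-based active indices).
#' @param T integer firing threshold.
#' @param strict logical; fire on `sum > T` instead of `sum >= T`.
#' @return list with `active` (sorted indices of firing output units) and
#'   `sums` (integer vector of all `N` pre-threshold sums).
#' @examples
#' W <- store_pattern(empty_connectivity(4), c(1, 2))
#' recall(W, c(1, 2), T = 2)
#' @export
recall <- function(W, p, T, strict = FALSE) {
  p <- check_pattern(p, nrow(W))
  if (T < 1L) stop("threshold T must be >= 1", call. = FALSE)
  sums <- if (length(p) == 1L) as.integer(W[p, ]) else
    as.integer(colSums(W[p, , drop = FALSE]))
  active <- if (strict) which(sums > T) else which(sums >= T)
  list(active = as.integer(active), sums = sums)
}

#' Test exact recall of a pattern
#'
#' A pattern is recalled exactly when the set of firing output units equals
#' the cue's active set.
#'
#' @inheritParams recall
#' @return logical.
#' @export
is_exact_recall <- function(W, p, T, strict = FALSE) {
  r <- recall(W, p, T, strict = strict)
  identical(r$active, check_pattern(p, nrow(W)))
}

#' Cross-pattern activation (CPA)
#'
#' Summed pre-threshold activation of the non-member output units over all
#' stored patterns: for each pattern, every output unit outside its active
#' set contributes its pre-threshold sum. Member outputs are excluded —
#' their sums are pinned at `S` and carry no interference information.
#' CPA is a heuristic measure of interference; it never decreases as
#' patterns are stored.
#'
#' @param W binary connectivity matrix.
#' @param patterns list of active-index vectors.
#' @return non-negative integer (as double, to avoid overflow at scale).
#' @export
cross_pattern_activation <- function(W, patterns) {
  total <- 0
  for (p in patterns) {
    r <- recall(W, p, T = 1L)
    total <- total + sum(r$sums[-p])
  }
  total
}

#' Test for the ideal saturated state
#'
#' In the capacity-attaining saturated state every stored pattern recalls
#' exactly and every non-member output sum sits exactly one unit below the
#' firing threshold (`T - 1`).
#'
#' @param W binary connectivity matrix.
#' @param patterns list of active-index vectors.
#' @param T firing threshold.
#' @return logical; `TRUE` vacuously for an empty pattern set.
#' @export
is_saturated_state <- function(W, patterns, T) {
  for (p in patterns) {
    p <- check_pattern(p, nrow(W))
    r <- recall(W, p, T)
    if (!identical(r$active, p)) return(FALSE)
    nonmember <- r$sums[-p]
    if (length(nonmember) && any(nonmember != T - 1L)) return(FALSE)
  }
  TRUE
}

#' Active-cell difference between two equal-sparsity patterns
#'
#' Number of active cells of `a` not active in `b` (symmetric for equal
#' sparsity); the bitwise Hamming distance is twice this.
#'
#' @param a,b active-index vectors of equal length.
#' @return integer.
#' @export
active_difference <- function(a, b) {
  length(setdiff(a, b))
}
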