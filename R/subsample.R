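#' Enumerate every pattern storable without error in a saturated matrix
#'
#' A sparsity-`S` pattern is valid for a saturated connectivity matrix when
#' storing it would add no new connection, i.e. `W[i, j] == 1` for every
#' ordered pair of its active cells. For the grid-constructed matrices this
#' coincides with simultaneous exact recall of all enumerated patterns.
#' Enumeration proceeds by recursive backtracking in lexicographic order of
#' active-index lists: a partial selection is extended only with indices
#' greater than the last chosen and bidirectionally connected to every
#' chosen cell, and a branch is pruned as soon as the candidate pool cannot
#' reach size `S`. The output order is deterministic.
#'
#' @param W binary connectivity matrix; a cell can be active only if its
#'   diagonal entry is 1.
#' @param S pattern sparsity.
#' @param limit optional cap on the number of patterns yielded.
#' @return list of sorted active-index vectors, in lexicographic order.
#' @examples
#' W <- build_saturated_matrix(grid_spec(network_params(6, 2)))
#' length(enumerate_valid_patterns(W, 2)) # 9 == (6/2)^2
#' @export
enumerate_valid_patterns <- function(W, S, limit = Inf) {
  acc <- new.env(parent = emptyenv())
  acc$patterns <- vector("list", 64L)
  acc$n <- 0L
  walk_valid_patterns(W, S, limit, function(p) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$patterns)) {
      length(acc$patterns) <- 2L * length(acc$patterns)
    }
    acc$patterns[[acc$n]] <- p
  })
  acc$patterns[seq_len(acc$n)]
}

#' Count valid patterns without materializing them
#'
#' @inheritParams enumerate_valid_patterns
#' @return integer count (the achieved capacity of the matrix).
#' @export
count_valid_patterns <- function(W, S, limit = Inf) {
  n <- 0L
  walk_valid_patterns(W, S, limit, function(p) n <<- n + 1L)
  n
}

# Backtracking core: calls visit(pattern) for each valid S-subset in
# lexicographic order, stopping after `limit` yields.
walk_valid_patterns <- function(W, S, limit, visit) {
  N <- nrow(W)
  S <- as_count(S, "S")
  if (S > N) stop("S must not exceed the matrix dimension", call. = FALSE)
  A <- (W == 1L) & (t(W) == 1L)   # bidirectional connectivity
  start <- which(diag(W) == 1L)
  yielded <- 0L
  recurse <- function(chosen, cand) {
    if (yielded >= limit) return(invisible())
    if (length(chosen) == S) {
      yielded <<- yielded + 1L
      visit(chosen)
      return(invisible())
    }
    need <- S - length(chosen)
    for (k in seq_along(cand)) {
      if (yielded >= limit) return(invisible())
      if (length(cand) - k + 1L < need) break  # pool too small to finish
      c0 <- cand[k]
      rest <- cand[cand > c0]
      rest <- rest[A[c0, rest]]
      if (length(rest) >= need - 1L) {
        recurse(c(chosen, c0), rest)
      }
    }
    invisible()
  }
  if (S == 0L) return(invisible())
  recurse(integer(0), start)
  invisible()
}

#' Closed-form slot-assignment pattern generation
#'
#' Independent cross-check of the backtracking enumerator for canonical
#' (identity-permutation, `D = 1`) grid specs: every valid pattern picks,
#' for each local slot `s` in `1:S`, one block `b_s`, giving the cell
#' `(b_s - 1) * S + s`; there are exactly `B^S` such assignments and they
#' coincide with the enumerator's output as a set.
#'
#' @param spec a canonical [grid_spec()] (identity perms, `D = 1`).
#' @return list of sorted active-index vectors.
#' @export
patterns_from_slot_assignments <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$params$D != 1L) {
    stop("slot-assignment generation requires D = 1", call. = FALSE)
  }
  if (!all(vapply(spec$perms, function(pm) identical(pm, seq_len(spec$S_eq)),
                  logical(1)))) {
    stop("slot-assignment generation requires identity permutations",
         call. = FALSE)
  }
  B <- spec$B; S <- spec$params$S
  if (B^S > 2^20) stop("B^S too large to materialize", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(seq_len(B)), S)))
  slots <- seq_len(S)
  lapply(seq_len(nrow(grid)), function(r) {
    unname(sort((grid[r, ] - 1L) * S + slots))
  })
}
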