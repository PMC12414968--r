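#' Grid specification for the saturated-matrix construction
#'
#' The construction works on the equivalent network (`N_eq = N/D`,
#' `S_eq = S/D`): units partition into `B = N_eq/S_eq` contiguous blocks of
#' `S_eq` cells, block `b` holding cells `(b-1)*S_eq + 1, ..., b*S_eq`.
#' Each block carries a permutation of its local slots — the orientation of
#' its sub-matrices; any choice of per-block permutations yields an optimal
#' matrix, so the family member is a free parameter (identity by default).
#'
#' @param params a [network_params()] object satisfying the divisibility
#'   invariants (`S | N`, `D | S`, `D | N`).
#' @param perms optional list of `B` integer permutations of `1:S_eq`;
#'   defaults to the identity for every block.
#' @return object of class `grid_spec` with elements `params`, `N_eq`,
#'   `S_eq`, `B`, `perms`.
#' @examples
#' grid_spec(network_params(12, 4))
#' @export
grid_spec <- function(params, perms = NULL) {
  stopifnot(inherits(params, "network_params"))
  check_divisible(params$N, params$S, params$D)
  eq <- equivalent_params(params$N, params$S, params$D)
  B <- eq$N_eq %/% eq$S_eq
  if (is.null(perms)) {
    perms <- rep(list(seq_len(eq$S_eq)), B)
  }
  if (length(perms) != B) {
    stop(sprintf("perms must have one permutation per block (B = %d)", B),
         call. = FALSE)
  }
  for (pm in perms) {
    if (!identical(sort(as.integer(pm)), seq_len(eq$S_eq))) {
      stop("each perms entry must be a permutation of 1:S_eq", call. = FALSE)
    }
  }
  structure(
    list(params = params, N_eq = eq$N_eq, S_eq = eq$S_eq, B = B,
         perms = lapply(perms, as.integer)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Grid construction: N = %d, S = %d, D = %d; equivalent N_eq = %d, S_eq = %d, B = %d blocks\n",
    x$params$N, x$params$S, x$params$D, x$N_eq, x$S_eq, x$B))
  invisible(x)
}

#' Orthogonal basis patterns of the grid construction
#'
#' The `B = N/S` pairwise-disjoint block patterns that seed the grid: basis
#' pattern `b` activates all `S` units of block `b`. Their union covers all
#' `N` units and they saturate the diagonal sub-matrices.
#'
#' @param spec a [grid_spec()].
#' @return list of `B` active-index vectors (a pattern set).
#' @export
basis_patterns <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  S <- spec$params$S
  lapply(seq_len(spec$B), function(b) ((b - 1L) * S + 1L):(b * S))
}

#' Deterministically build a fully saturated connectivity matrix
#'
#' On the equivalent network, cell `i` connects to cell `j` iff they share
#' a block or their permuted local slots differ:
#' `W[i, j] = 1  <=>  block(i) == block(j) | perm[b_i](l_i) != perm[b_j](l_j)`.
#' Diagonal sub-matrices are all-ones; every off-diagonal sub-matrix has
#' exactly one zero per row and per column. For `D > 1` every equivalent
#' cell expands into a `D x D` all-ones sub-block. The matrix stores
#' exactly `(N/S)^(S/D)` patterns — the theoretical maximum — and no
#' further valid pattern would add a connection.
#'
#' @param spec a [grid_spec()].
#' @return binary integer `N x N` matrix.
#' @examples
#' build_saturated_matrix(grid_spec(network_params(4, 2)))
#' @export
build_saturated_matrix <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  N_eq <- spec$N_eq; S_eq <- spec$S_eq; D <- spec$params$D
  blk <- (seq_len(N_eq) - 1L) %/% S_eq + 1L
  loc <- (seq_len(N_eq) - 1L) %% S_eq + 1L
  pv <- mapply(function(b, l) spec$perms[[b]][l], blk, loc)
  same_block <- outer(blk, blk, `==`)
  perm_differ <- outer(pv, pv, `!=`)
  W_eq <- matrix(as.integer(same_block | perm_differ), N_eq, N_eq)
  if (D > 1L) {
    W_eq <- W_eq %x% matrix(1L, D, D)
    storage.mode(W_eq) <- "integer"
  }
  W_eq
}

#' Validate the saturated-matrix structure
#'
#' Checks, on the equivalent network, that (a) diagonal sub-matrices are
#' all-ones, (b) every off-diagonal sub-matrix has exactly one zero per row
#' and per column, and (c) zero placements are mutually consistent — the
#' zero bijection of every block pair is generated by a single family of
#' per-block permutations (transitive consistency). For `D > 1` the matrix
#' must additionally be an exact `D x D` block replication of an equivalent
#' matrix.
#'
#' @param W binary `N x N` matrix.
#' @param spec a [grid_spec()] describing the expected structure.
#' @return character vector of violation messages; empty if valid.
#' @export
validate_saturated <- function(W, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  N <- spec$params$N
  if (!is.matrix(W) || nrow(W) != N || ncol(W) != N) {
    stop(sprintf("W must be a %d x %d matrix", N, N), call. = FALSE)
  }
  D <- spec$params$D; N_eq <- spec$N_eq; S_eq <- spec$S_eq; B <- spec$B
  violations <- character()
  if (D > 1L) {
    W_eq <- matrix(0L, N_eq, N_eq)
    for (i in seq_len(N_eq)) {
      for (j in seq_len(N_eq)) {
        blkij <- W[((i - 1L) * D + 1L):(i * D), ((j - 1L) * D + 1L):(j * D)]
        u <- unique(as.vector(blkij))
        if (length(u) != 1L) {
          violations <- c(violations, sprintf(
            "equivalent cell (%d,%d): D x D expansion block is not constant",
            i, j))
          u <- blkij[1L, 1L]
        }
        W_eq[i, j] <- u[1L]
      }
    }
  } else {
    W_eq <- W
  }

  sub <- function(a, b) {
    W_eq[((a - 1L) * S_eq + 1L):(a * S_eq),
         ((b - 1L) * S_eq + 1L):(b * S_eq), drop = FALSE]
  }
  # zero bijection of each off-diagonal pair: local row -> local col
  zmap <- vector("list", B * B)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      M <- sub(a, b)
      if (a == b) {
        if (any(M != 1L)) {
          violations <- c(violations, sprintf(
            "diagonal sub-matrix of block %d is not all-ones", a))
        }
        next
      }
      zr <- rowSums(M == 0L); zc <- colSums(M == 0L)
      if (any(zr != 1L) || any(zc != 1L)) {
        violations <- c(violations, sprintf(
          "off-diagonal sub-matrix (%d,%d) lacks exactly one zero per row/column",
          a, b))
        next
      }
      zmap[[(a - 1L) * B + b]] <- apply(M == 0L, 1L, which)
    }
  }
  if (length(violations) == 0L && B >= 2L) {
    # recover candidate per-block permutations from block 1 and re-check all
    p <- vector("list", B)
    p[[1L]] <- seq_len(S_eq)
    for (b in 2:B) {
      z1b <- zmap[[(1L - 1L) * B + b]]   # l_row -> l_col with p_b(l_col) == p_1(l_row)
      p[[b]] <- order(z1b)               # p_b = inverse of z_1b
    }
    for (a in seq_len(B)) {
      for (b in seq_len(B)) {
        if (a == b) next
        expected <- order(p[[b]])[p[[a]]]  # z_ab = p_b^{-1} o p_a
        if (!identical(as.integer(zmap[[(a - 1L) * B + b]]), as.integer(expected))) {
          violations <- c(violations, sprintf(
            "zero placement of sub-matrix (%d,%d) is inconsistent with the permutation family",
            a, b))
        }
      }
    }
  }
  violations
}
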