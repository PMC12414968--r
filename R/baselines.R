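# Fast addability test used by the sequential-storage baselines, the
# exhaustive oracle and the maximality verifier.
#
# A candidate S-subset `cand` is addable to the stored set iff
#   (a) it differs from every stored pattern by >= D active cells,
#   (b) after clipped storage of its block, the candidate itself recalls
#       exactly (no non-member output of the candidate reaches T), and
#   (c) no stored pattern acquires a spuriously firing output.
# Storage only touches entries (i, j) with i, j in cand, so the update to
# each stored pattern's pre-threshold sums is local to the columns of
# `cand` and computable from the overlap with the candidate block.
#
# W          current binary matrix
# A          P x N matrix of pre-threshold sums, stored_mat %*% W
# stored_mat P x N 0/1 membership matrix of the stored patterns
addable_fast <- function(W, A, stored_mat, cand, S, D, T) {
  s_cand <- if (length(cand) == 1L) W[cand, ] else colSums(W[cand, , drop = FALSE])
  if (any(s_cand[-cand] >= T)) return(FALSE)   # candidate's own recall
  P <- nrow(stored_mat)
  if (P > 0L) {
    Bm <- stored_mat[, cand, drop = FALSE]     # P x S overlap with cand
    overlap <- rowSums(Bm)
    if (any(overlap > S - D)) return(FALSE)    # pairwise differentiability
    Wcc <- W[cand, cand, drop = FALSE]
    newA <- A[, cand, drop = FALSE] - Bm %*% Wcc + overlap
    if (any(newA >= T & Bm == 0L)) return(FALSE)  # spurious firing of stored
  }
  TRUE
}

# all S-subsets of 1:N as columns, in lexicographic order
all_subsets <- function(N, S) {
  if (S == N) matrix(seq_len(N), ncol = 1L) else utils::combn(N, S)
}

fill_result <- function(params, patterns, W, mode, seed, extra = list()) {
  achieved <- length(patterns)
  theo <- tryCatch(capacity_general(params$N, params$S, params$D),
                   error = function(e) NA_real_)
  structure(
    c(list(params = params, patterns = patterns, W = W,
           capacity_achieved = achieved, capacity_theoretical = theo,
           fraction_pct = if (is.na(theo)) NA_real_ else 100 * achieved / theo,
           mode = mode, seed = seed),
      extra),
    class = "fill_result"
  )
}

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf(
    "Sequential fill (%s): %d patterns stored (N = %d, S = %d, D = %d)\n",
    x$mode, x$capacity_achieved, x$params$N, x$params$S, x$params$D))
  if (!is.na(x$capacity_theoretical)) {
    cat(sprintf("  theoretical maximum %s, fraction %.1f%%\n",
                format(x$capacity_theoretical, big.mark = ","),
                x$fraction_pct))
  }
  invisible(x)
}

#' Random sequential pattern storage
#'
#' Repeatedly draws uniform random sparsity-`S` candidate patterns and
#' stores a candidate iff it is new, differs from every stored pattern by
#' at least `D` active cells, and — after clipped storage — every stored
#' pattern (including itself) still recalls exactly at the canonical
#' threshold. For small networks (`choose(N, S) <=` `exhaustive_limit`)
#' termination is exact: storage stops when a full scan finds no addable
#' candidate (acceptances are drawn uniformly from the addable set, which
#' is distributionally identical to uniform rejection sampling). For
#' larger networks storage stops after `attempt_budget` consecutive
#' rejections. This trial-and-error strategy typically stalls below the
#' theoretical maximum because early unstructured correlations saturate
#' the matrix prematurely.
#'
#' @param params a [network_params()] object.
#' @param seed integer seed for reproducibility (same seed, same stored
#'   set); `NULL` uses the current RNG state.
#' @param attempt_budget consecutive-rejection budget for large networks.
#' @param exhaustive_limit candidate-count cutoff below which termination
#'   is checked by exhaustive scan.
#' @return a `fill_result`: stored `patterns`, final matrix `W`, achieved
#'   and theoretical capacity and their percentage `fraction_pct`, plus
#'   run metadata (`mode`, `seed`).
#' @examples
#' random_fill(network_params(8, 2), seed = 1)
#' @export
random_fill <- function(params, seed = NULL, attempt_budget = 10000L,
                        exhaustive_limit = 20000L) {
  stopifnot(inherits(params, "network_params"))
  with_local_seed(seed)
  N <- params$N; S <- params$S; D <- params$D; T <- params$T
  W <- empty_connectivity(N)
  patterns <- list()
  stored_mat <- matrix(0L, 0L, N)
  A <- matrix(0L, 0L, N)
  K <- choose(N, S)

  accept <- function(cand) {
    W <<- store_pattern(W, cand)
    patterns[[length(patterns) + 1L]] <<- cand
    m <- integer(N); m[cand] <- 1L
    stored_mat <<- rbind(stored_mat, m)
    A <<- stored_mat %*% W
  }

  if (K <= exhaustive_limit) {
    cands <- all_subsets(N, S)
    repeat {
      found <- FALSE
      for (k in sample.int(ncol(cands))) {
        cand <- cands[, k]
        if (addable_fast(W, A, stored_mat, cand, S, D, T)) {
          accept(cand)
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
    mode <- sprintf("random/exhaustive-scan (%d candidates)", K)
  } else {
    consecutive <- 0L
    while (consecutive < attempt_budget) {
      cand <- sort(sample.int(N, S))
      if (addable_fast(W, A, stored_mat, cand, S, D, T)) {
        accept(cand)
        consecutive <- 0L
      } else {
        consecutive <- consecutive + 1L
      }
    }
    mode <- sprintf("random/rejection-budget (%d)", attempt_budget)
  }
  fill_result(params, patterns, W, mode, seed)
}

#' CPA-guided sequential pattern storage
#'
#' Like [random_fill()], but at each step the candidate chosen among the
#' admissible, recall-preserving ones is the one whose acceptance yields
#' the minimal [cross_pattern_activation()] (summed non-member
#' pre-threshold interference); ties are broken by lexicographic order of
#' the pattern. Candidates violating exact recall are never scored. The
#' heuristic reduces interference locally but is not guaranteed to reach
#' the theoretical maximum — once the early picks are suboptimal all
#' remaining candidates may score identically.
#'
#' @inheritParams random_fill
#' @param candidate_pool_size number of random candidates sampled per step
#'   for large networks; ignored (full scan) when
#'   `choose(N, S) <= exhaustive_limit`.
#' @param max_empty_pools sampled-mode stopping rule: stop after this many
#'   consecutive steps whose pool contains no addable candidate.
#' @return a `fill_result` (see [random_fill()]).
#' @export
cpa_guided_fill <- function(params, seed = NULL, candidate_pool_size = 100L,
                            exhaustive_limit = 20000L,
                            max_empty_pools = 10L) {
  stopifnot(inherits(params, "network_params"))
  with_local_seed(seed)
  N <- params$N; S <- params$S; D <- params$D; T <- params$T
  W <- empty_connectivity(N)
  patterns <- list()
  stored_mat <- matrix(0L, 0L, N)
  A <- matrix(0L, 0L, N)
  K <- choose(N, S)
  exhaustive <- K <= exhaustive_limit
  cands <- if (exhaustive) all_subsets(N, S) else NULL
  empty_pools <- 0L

  repeat {
    pool <- if (exhaustive) {
      cands
    } else {
      ix <- replicate(candidate_pool_size, sort(sample.int(N, S)))
      ord <- do.call(order, lapply(seq_len(S), function(r) ix[r, ]))
      ix[, ord, drop = FALSE]
    }
    best <- NULL; best_cpa <- Inf
    for (k in seq_len(ncol(pool))) {
      cand <- pool[, k]
      if (!addable_fast(W, A, stored_mat, cand, S, D, T)) next
      W2 <- store_pattern(W, cand)
      cpa <- cross_pattern_activation(W2, c(patterns, list(cand)))
      if (cpa < best_cpa) {  # pool is lexicographic, so first min wins ties
        best_cpa <- cpa
        best <- cand
      }
    }
    if (is.null(best)) {
      if (exhaustive) break
      empty_pools <- empty_pools + 1L
      if (empty_pools >= max_empty_pools) break
      next
    }
    empty_pools <- 0L
    W <- store_pattern(W, best)
    patterns[[length(patterns) + 1L]] <- best
    m <- integer(N); m[best] <- 1L
    stored_mat <- rbind(stored_mat, m)
    A <- stored_mat %*% W
  }
  mode <- if (exhaustive) {
    sprintf("cpa/exhaustive-scan (%d candidates)", K)
  } else {
    sprintf("cpa/pool-%d", candidate_pool_size)
  }
  fill_result(params, patterns, W, mode, seed,
              extra = list(final_cpa = cross_pattern_activation(W, patterns)))
}

# seed the RNG when a seed is supplied; NULL leaves the current state
with_local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible()
}
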