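#' Brute-force maximum capacity for tiny networks
#'
#' Exact maximum number of sparsity-`S` patterns that can be stored with
#' simultaneous exact recall at the canonical threshold while respecting
#' the pairwise `D`-difference constraint, found by depth-first search over
#' all `choose(N, S)` candidate patterns in lexicographic order with
#' best-so-far pruning (a branch is abandoned when even accepting every
#' remaining candidate could not beat the incumbent). Because clipped
#' storage is monotone, validity of a family is downward-closed, so the
#' search extends a family only with candidates that keep every stored
#' pattern exactly recallable.
#'
#' This is the independent ground truth against which the closed-form
#' capacity `(N/S)^(S/D)` and the constructive enumerator are verified.
#'
#' @param params a [network_params()] object.
#' @param max_candidates refuse to search when `choose(N, S)` exceeds this
#'   bound (use the enumerator plus [verify_maximal()] instead).
#' @param symmetric_prune if `TRUE` (default when `D == 1`), fix the
#'   lexicographically smallest candidate `1:S` as the first stored
#'   pattern; valid because unit relabelling maps maximum families to
#'   maximum families, so some maximum family contains `1:S`.
#' @return list with `max_count` and `witness` (a list of patterns
#'   attaining it).
#' @examples
#' max_capacity_exhaustive(network_params(4, 2))$max_count # 4
#' @export
max_capacity_exhaustive <- function(params, max_candidates = 100L,
                                    symmetric_prune = (params$D == 1L)) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N; S <- params$S; D <- params$D; T <- params$T
  K <- choose(N, S)
  if (K > max_candidates) {
    stop(sprintf(
      "choose(N, S) = %d exceeds the search bound (%d); use the enumerator plus verify_maximal instead",
      K, max_candidates), call. = FALSE)
  }
  cands <- all_subsets(N, S)
  best <- list(max_count = 0L, witness = list())

  recurse <- function(i, patterns, W, stored_mat, A) {
    if (length(patterns) > best$max_count) {
      best <<- list(max_count = length(patterns), witness = patterns)
    }
    if (i > K) return(invisible())
    if (length(patterns) + (K - i + 1L) <= best$max_count) return(invisible())
    cand <- cands[, i]
    if (addable_fast(W, A, stored_mat, cand, S, D, T)) {
      W2 <- store_pattern(W, cand)
      m <- integer(N); m[cand] <- 1L
      sm2 <- rbind(stored_mat, m)
      recurse(i + 1L, c(patterns, list(cand)), W2, sm2, sm2 %*% W2)
    }
    # skip candidate i — unless the first pattern is pinned by symmetry
    if (!(symmetric_prune && length(patterns) == 0L && i == 1L)) {
      recurse(i + 1L, patterns, W, stored_mat, A)
    }
    invisible()
  }
  recurse(1L, list(), empty_connectivity(N), matrix(0L, 0L, N),
          matrix(0L, 0L, N))
  best
}

#' Verify that a stored pattern set is maximal
#'
#' `TRUE` iff no sparsity-`S` subset outside `patterns` can be added to `W`
#' with every exact recall (existing and new) preserved at the canonical
#' threshold — a single pass over all candidates. For a saturated matrix
#' the zero-pair certificate is available: a candidate not in the
#' enumerated set necessarily contains a pair of cells with `W == 0`, so
#' storing it would add a connection.
#'
#' @param W binary connectivity matrix with `patterns` already stored.
#' @param patterns list of stored active-index vectors.
#' @param params a [network_params()] object.
#' @param method `"definitional"` (store tentatively, test all recalls) or
#'   `"zero_pair"` (candidate rejected iff it contains a zero pair of `W`;
#'   valid certificate for saturated matrices only).
#' @return logical.
#' @export
verify_maximal <- function(W, patterns, params,
                           method = c("definitional", "zero_pair")) {
  stopifnot(inherits(params, "network_params"))
  method <- match.arg(method)
  N <- params$N; S <- params$S; D <- params$D; T <- params$T
  cands <- all_subsets(N, S)
  key <- function(p) paste(p, collapse = ",")
  have <- new.env(parent = emptyenv())
  for (p in patterns) assign(key(sort(p)), TRUE, envir = have)
  stored_mat <- do.call(rbind, lapply(patterns, function(p) {
    m <- integer(N); m[p] <- 1L; m
  }))
  if (is.null(stored_mat)) stored_mat <- matrix(0L, 0L, N)
  A <- stored_mat %*% W
  for (k in seq_len(ncol(cands))) {
    cand <- cands[, k]
    if (!is.null(have[[key(cand)]])) next
    ok <- if (method == "zero_pair") {
      all(W[cand, cand] == 1L)        # no zero pair => addable for saturated W
    } else {
      addable_fast(W, A, stored_mat, cand, S, D, T)
    }
    if (ok) return(FALSE)
  }
  TRUE
}
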