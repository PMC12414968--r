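# Shared fixtures and independent reference implementations.

# The worked 4-unit, sparsity-2 saturated matrix (zeros on the
# anti-diagonal of each off-diagonal sub-matrix); a member of the
# per-block-permutation family with perms (identity, swap).
canonical_W4 <- matrix(as.integer(c(
  1, 1, 1, 0,
  1, 1, 0, 1,
  1, 0, 1, 1,
  0, 1, 1, 1
)), nrow = 4, byrow = TRUE)

canonical_spec4 <- function() {
  grid_spec(network_params(4, 2), perms = list(1:2, 2:1))
}

# Independent naive enumeration oracle: check the all-pairs-ones condition
# over every S-subset (usable up to N ~ 12).
brute_force_valid_patterns <- function(W, S) {
  N <- nrow(W)
  cands <- utils::combn(N, S)
  keep <- apply(cands, 2, function(p) all(W[p, p] == 1L))
  lapply(which(keep), function(k) cands[, k])
}

# Independent recall: multiply the full binary cue vector through W.
recall_via_vector <- function(W, p, T) {
  x <- integer(nrow(W)); x[p] <- 1L
  sums <- as.integer(x %*% W)
  which(sums >= T)
}

pattern_key <- function(p) paste(sort(p), collapse = ",")

same_pattern_set <- function(a, b) {
  setequal(vapply(a, pattern_key, character(1)),
           vapply(b, pattern_key, character(1)))
}

# Mutual exact recall of a whole family under its own stored matrix.
family_mutually_recalls <- function(patterns, params) {
  W <- store_patterns(empty_connectivity(params$N), patterns)
  all(vapply(patterns, function(p) is_exact_recall(W, p, params$T),
             logical(1)))
}
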