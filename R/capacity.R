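#' Closed-form maximum storage capacity
#'
#' The maximum number of sparsity-`S` patterns storable with exact recall in
#' an `N`-unit clipped-Hebbian network at the maximum threshold is
#' `C = (N/S)^S`: the units partition into `B = N/S` blocks and each of the
#' `S` local slots independently picks a block. The value is computed by
#' exact repeated integer multiplication (exact for results up to `2^53`,
#' which covers all enumerable scales; beyond that a warning is issued and
#' the double-precision value returned — use [capacity_log10()] for very
#' large networks).
#'
#' @param N network size; `S` must divide `N`.
#' @param S pattern sparsity.
#' @return capacity as a double holding an exact integer when representable.
#' @examples
#' capacity_closed_form(12, 4) # 81
#' @export
capacity_closed_form <- function(N, S) {
  N <- as_count(N, "N"); S <- as_count(S, "S")
  check_divisible(N, S)
  B <- N %/% S
  out <- 1
  exact <- TRUE
  for (k in seq_len(S)) {
    out <- out * B
    if (out > 2^53) exact <- FALSE
  }
  if (!exact) {
    warning("capacity exceeds 2^53; value is not exactly representable",
            call. = FALSE)
  }
  out
}

#' Base-10 logarithm of the closed-form capacity
#'
#' `log10 C = S * log10(N/S)`; exact in floating point at any scale, used
#' by the size sweeps where the capacity itself overflows.
#'
#' @inheritParams capacity_closed_form
#' @return double.
#' @export
capacity_log10 <- function(N, S) {
  N <- as_count(N, "N"); S <- as_count(S, "S")
  check_divisible(N, S)
  S * log10(N / S)
}

#' Literal evaluation of the printed double-sum capacity expression
#'
#' Evaluates `sum_{i=0}^{N/S-1} sum_{j=0}^{S} choose(S, j) * i^j` exactly as
#' printed, which by the binomial theorem equals `sum_{k=1}^{N/S} k^S`.
#' For `N/S > 1` this strictly exceeds the closed-form `(N/S)^S`, which the
#' exhaustive oracle certifies as the true maximum; the literal sum is kept
#' only as a documented reference and is never used as the authoritative
#' capacity.
#'
#' @inheritParams capacity_closed_form
#' @return double.
#' @examples
#' capacity_summation_as_printed(4, 2) # 5, vs capacity_closed_form(4, 2) == 4
#' @export
capacity_summation_as_printed <- function(N, S) {
  N <- as_count(N, "N"); S <- as_count(S, "S")
  check_divisible(N, S)
  B <- N %/% S
  total <- 0
  for (i in 0:(B - 1L)) {
    total <- total + sum(choose(S, 0:S) * i^(0:S))
  }
  total
}

#' Equivalent network for differentiability D > 1
#'
#' A network with minimum active-cell difference `D` between patterns
#' behaves, for capacity purposes, like a smaller network at the maximum
#' threshold: `N_eq = N/D`, `S_eq = S/D`. Each equivalent cell corresponds
#' to a group of `D` units that are always co-active.
#'
#' @param N network size.
#' @param S pattern sparsity.
#' @param D minimum active-cell difference; must divide `N` and `S`.
#' @return list with `N_eq` and `S_eq`.
#' @examples
#' equivalent_params(8, 4, 2) # N_eq = 4, S_eq = 2
#' @export
equivalent_params <- function(N, S, D) {
  N <- as_count(N, "N"); S <- as_count(S, "S"); D <- as_count(D, "D")
  check_divisible(N, S, D)
  list(N_eq = N %/% D, S_eq = S %/% D)
}

#' Closed-form capacity for general differentiability
#'
#' `C(N, S, D) = (N/S)^(S/D)`, via the equivalent-network transform.
#'
#' @inheritParams equivalent_params
#' @return double (exact integer when representable).
#' @export
capacity_general <- function(N, S, D = 1L) {
  eq <- equivalent_params(N, S, D)
  capacity_closed_form(eq$N_eq, eq$S_eq)
}

#' Capacity-optimal pattern sparsity for a fixed network size
#'
#' Evaluates the closed-form capacity over a set of admissible sparsities
#' (by default every divisor of `N` that also satisfies the `D`
#' divisibility constraints) and returns the maximizer. The optimum sits
#' near `S = N/3`: the capacity `(N/S)^(S/D)` trades block count against
#' exponent. Ties are broken toward the smaller `S` (sparser codes), and
#' the tie-break rule is recorded in the result.
#'
#' @param N network size.
#' @param D minimum active-cell difference.
#' @param S_values admissible sparsities; defaults to all divisors of `N`
#'   compatible with `D`. Inadmissible values passed explicitly are an
#'   error.
#' @return list with `S_opt`, `capacity_opt`, `tie_break = "smallest_S"`,
#'   and `table`, a data.frame with columns `S` and `capacity`.
#' @examples
#' optimal_sparsity(12)$S_opt # 4 == N/3
#' @export
optimal_sparsity <- function(N, D = 1L, S_values = NULL) {
  N <- as_count(N, "N"); D <- as_count(D, "D")
  if (is.null(S_values)) {
    S_values <- divisors_of(N)
    S_values <- S_values[S_values %% D == 0L & N %% D == 0L]
  }
  if (length(S_values) == 0L) {
    stop("no admissible sparsity values", call. = FALSE)
  }
  S_values <- sort(unique(as.integer(S_values)))
  caps <- vapply(S_values, function(S) capacity_general(N, S, D), numeric(1))
  best <- which(caps == max(caps))[1L]  # smallest S on ties
  list(
    S_opt = S_values[best],
    capacity_opt = caps[best],
    tie_break = "smallest_S",
    table = data.frame(S = S_values, capacity = caps)
  )
}

divisors_of <- function(N) {
  k <- seq_len(N)
  k[N %% k == 0L]
}
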