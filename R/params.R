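#' Network and pattern parameters
#'
#' Bundle the parameters of a single-layer binary feedforward associative
#' network: the number of input units `N` (equal to the number of output
#' units), the pattern sparsity `S` (absolute count of active units per
#' pattern), the minimum pattern differentiability `D` (minimum number of
#' active cells by which any two stored patterns must differ; the bitwise
#' Hamming distance between two equal-sparsity patterns is `2 * D`), and the
#' integer firing threshold `T` under the convention that an output unit
#' fires iff its pre-threshold sum is `>= T`.
#'
#' The canonical threshold is `T = S - D + 1`: with it, the ideal saturated
#' state places every non-member output sum exactly one unit below firing.
#' An alternative strict-inequality convention ("fire iff sum > T", with
#' `T = S - D`) is numerically identical to the canonical one via
#' `T_canonical = T_strict + 1` and is available through the `strict`
#' argument of [recall()] and the CLI `threshold_convention` option.
#'
#' @param N positive integer, number of input (= output) units.
#' @param S positive integer, active units per pattern, `1 <= S <= N`.
#' @param D positive integer, minimum active-cell difference between stored
#'   patterns, `1 <= D <= S`.
#' @param T integer firing threshold; defaults to the canonical
#'   `S - D + 1`.
#' @param require_divisible logical; if `TRUE`, additionally require that
#'   `S` divides `N` and `D` divides both `S` and `N` (needed by the
#'   constructor and capacity modules).
#'
#' @return An object of class `network_params`: a list with elements
#'   `N`, `S`, `D`, `T`.
#' @examples
#' network_params(12, 4)
#' network_params(8, 4, D = 2)
#' @export
network_params <- function(N, S, D = 1L, T = NULL,
                           require_divisible = FALSE) {
  N <- as_count(N, "N")
  S <- as_count(S, "S")
  D <- as_count(D, "D")
  if (S > N) stop("S must satisfy 1 <= S <= N", call. = FALSE)
  if (D > S) stop("D must satisfy 1 <= D <= S", call. = FALSE)
  if (is.null(T)) T <- S - D + 1L
  T <- as.integer(T)
  if (T < 1L) stop("threshold T must be >= 1", call. = FALSE)
  if (require_divisible) check_divisible(N, S, D)
  structure(list(N = N, S = S, D = D, T = T), class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "Binary associative network: N = %d units, S = %d active/pattern, D = %d, T = %d (fire iff sum >= T)\n",
    x$N, x$S, x$D, x$T))
  invisible(x)
}

#' Canonical firing threshold
#'
#' `T = S - D + 1` under the "fire iff sum >= T" convention, so that the
#' saturated state pins every non-member output sum at `T - 1`.
#'
#' @param S pattern sparsity.
#' @param D minimum active-cell difference.
#' @return integer threshold.
#' @export
canonical_threshold <- function(S, D = 1L) {
  as.integer(S) - as.integer(D) + 1L
}

# -- internal validation helpers ---------------------------------------------

as_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("%s must be a single positive integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

check_divisible <- function(N, S, D = 1L) {
  if (N %% S != 0L) {
    stop(sprintf("S (%d) must divide N (%d)", S, N), call. = FALSE)
  }
  if (S %% D != 0L) {
    stop(sprintf("D (%d) must divide S (%d)", D, S), call. = FALSE)
  }
  if (N %% D != 0L) {
    stop(sprintf("D (%d) must divide N (%d)", D, N), call. = FALSE)
  }
  invisible(TRUE)
}

check_pattern <- function(p, N, S = NULL) {
  p <- as.integer(p)
  if (anyNA(p) || any(p < 1L) || any(p > N)) {
    stop("pattern indices must lie in [1, N]", call. = FALSE)
  }
  if (anyDuplicated(p)) stop("pattern indices must be distinct", call. = FALSE)
  if (!is.null(S) && length(p) != S) {
    stop(sprintf("pattern must have exactly S = %d active units", S),
         call. = FALSE)
  }
  sort(p)
}
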