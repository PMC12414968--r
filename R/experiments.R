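#' Capacity sweep over network size at fixed relative sparsity
#'
#' Evaluates the closed-form capacity for a list of network sizes holding
#' the relative sparsity `S/N` constant. Capacity grows log-linearly:
#' `log10 C = S * log10(N/S)`. Sizes for which `ratio * N` is not an
#' integer dividing `N` are skipped with a message rather than floored.
#'
#' @param ratio relative sparsity `S/N` (e.g. `1/3`).
#' @param N_values integer vector of network sizes.
#' @return data.frame with columns `N`, `S`, `capacity` (`NA` when not
#'   exactly representable), `log10_capacity`.
#' @examples
#' sweep_capacity_vs_N(1/3, c(6, 9, 12))
#' @export
sweep_capacity_vs_N <- function(ratio, N_values) {
  rows <- lapply(as.integer(N_values), function(N) {
    S <- ratio * N
    if (abs(S - round(S)) > 1e-9 || round(S) < 1 || N %% round(S) != 0) {
      message(sprintf("skipping N = %d: S = ratio * N is not an admissible sparsity", N))
      return(NULL)
    }
    S <- as.integer(round(S))
    l10 <- capacity_log10(N, S)
    cap <- if (l10 <= 53 * log10(2)) capacity_closed_form(N, S) else NA_real_
    data.frame(N = N, S = S, capacity = cap, log10_capacity = l10)
  })
  do.call(rbind, rows)
}

#' Capacity sweep over sparsity and differentiability at fixed size
#'
#' Evaluates `(N/S)^(S/D)` over admissible `(S, D)` combinations
#' (divisibility-respecting; inadmissible combinations are skipped with a
#' message, never floored) and reports the capacity-maximizing sparsity
#' for each `D`. The optimum sits near `S = N/3`, and capacity is
#' non-increasing in `D`.
#'
#' @param N network size.
#' @param D_values differentiability values to sweep.
#' @param S_values sparsities to sweep; defaults to all divisors of `N`.
#' @return data.frame with columns `S`, `D`, `B`, `capacity`; attribute
#'   `optima` is a data.frame of the per-`D` argmax (smallest-`S`
#'   tie-break).
#' @examples
#' sweep_capacity_vs_S(12, D_values = c(1, 2))
#' @export
sweep_capacity_vs_S <- function(N, D_values = 1L, S_values = NULL) {
  N <- as_count(N, "N")
  if (is.null(S_values)) S_values <- divisors_of(N)
  rows <- list()
  for (D in sort(as.integer(D_values))) {
    for (S in sort(as.integer(S_values))) {
      ok <- tryCatch({ check_divisible(N, S, D); TRUE },
                     error = function(e) FALSE)
      if (!ok || S < D) {
        message(sprintf("skipping (S = %d, D = %d): divisibility constraints not met", S, D))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        S = S, D = D, B = N %/% S, capacity = capacity_general(N, S, D))
    }
  }
  out <- do.call(rbind, rows)
  optima <- do.call(rbind, lapply(split(out, out$D), function(df) {
    best <- df[which.max(df$capacity), , drop = FALSE]  # smallest S on ties
    data.frame(D = best$D, S_opt = best$S, capacity = best$capacity)
  }))
  rownames(optima) <- NULL
  attr(out, "optima") <- optima
  out
}

#' Compare constructive and random pattern-generation strategies
#'
#' For each network size, reports the fraction of the theoretical maximum
#' capacity achieved by (a) deterministic sub-sampling from the
#' constructed saturated matrix (always 100%) and (b) random sequential
#' storage over a set of seeds (mean/min/max envelope).
#'
#' @param S pattern sparsity.
#' @param N_values network sizes (multiples of `S`).
#' @param seeds integer vector of seeds for the random trials.
#' @param D differentiability.
#' @return data.frame with columns `N`, `S`, `D`, `capacity`,
#'   `constructive_pct`, `random_mean_pct`, `random_min_pct`,
#'   `random_max_pct`, `n_seeds`.
#' @examples
#' \donttest{
#' compare_strategies(4, c(12, 16), seeds = 1:5)
#' }
#' @export
compare_strategies <- function(S, N_values, seeds = 1:50, D = 1L) {
  rows <- lapply(as.integer(N_values), function(N) {
    params <- network_params(N, S, D, require_divisible = TRUE)
    cap <- capacity_general(N, S, D)
    W <- build_saturated_matrix(grid_spec(params))
    achieved <- count_valid_patterns(W, S)
    fr <- vapply(seeds, function(s) {
      random_fill(params, seed = s)$fraction_pct
    }, numeric(1))
    data.frame(N = N, S = S, D = D, capacity = cap,
               constructive_pct = 100 * achieved / cap,
               random_mean_pct = mean(fr), random_min_pct = min(fr),
               random_max_pct = max(fr), n_seeds = length(seeds))
  })
  do.call(rbind, rows)
}

#' Reorganization experiment: suboptimal random sets vs the optimal set
#'
#' Initializes networks with random pattern sets that fall below the
#' theoretical maximum (seeds whose random fill happens to reach the
#' maximum are skipped, with a resampling budget), generates the optimal
#' set by enumeration from the constructed saturated matrix, and computes
#' the per-seed [work_curve()] of converting the random set into the
#' optimal one.
#'
#' @param params a [network_params()] satisfying the divisibility
#'   invariants.
#' @param seeds integer vector of seeds.
#' @param resample_budget extra seeds tried (per requested seed) to find a
#'   suboptimal random set before giving up on that seed.
#' @return list with `curves` (named list of `work_curve`s) and `summary`
#'   (data.frame: `seed`, `stored`, `capacity`, `min_work_bits`,
#'   `argmin_k`); seeds for which no suboptimal set was found are reported
#'   in `summary` with `NA` work and a message, not an error.
#' @export
run_reorganization_experiment <- function(params, seeds = 1:10,
                                          resample_budget = 20L) {
  stopifnot(inherits(params, "network_params"))
  check_divisible(params$N, params$S, params$D)
  cap <- capacity_general(params$N, params$S, params$D)
  W_opt <- build_saturated_matrix(grid_spec(params))
  O <- enumerate_valid_patterns(W_opt, params$S)
  curves <- list()
  rows <- lapply(as.integer(seeds), function(s) {
    fill <- NULL
    for (off in 0:resample_budget) {
      cand <- random_fill(params, seed = s + off * 100003L)
      if (cand$capacity_achieved < cap) { fill <- cand; break }
    }
    if (is.null(fill)) {
      message(sprintf(
        "seed %d: no suboptimal random set within the resampling budget", s))
      return(data.frame(seed = s, stored = NA_integer_, capacity = cap,
                        min_work_bits = NA_real_, argmin_k = NA_integer_))
    }
    wc <- work_curve(fill$patterns, O, params$S)
    curves[[as.character(s)]] <<- wc
    data.frame(seed = s, stored = fill$capacity_achieved, capacity = cap,
               min_work_bits = attr(wc, "min_work_bits"),
               argmin_k = attr(wc, "argmin_k"))
  })
  list(curves = curves, summary = do.call(rbind, rows))
}
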