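optimal_set_4 <- function() {
  enumerate_valid_patterns(build_saturated_matrix(canonical_spec4()), 2)
}

test_that("best-match assignment minimizes total bitwise Hamming distance", {
  O <- optimal_set_4()
  m <- match_patterns(O, O)
  expect_equal(m$total_distance, 0)
  expect_equal(m$assignment, seq_along(O))

  # the two excluded 2-subsets each sit at distance 2 from their best partner
  R <- list(c(1, 4), c(2, 3))
  m <- match_patterns(R, O)
  expect_equal(m$total_distance, 4)
  expect_equal(sort(m$distances), c(2, 2))

  m1 <- match_patterns(list(c(1, 2)), O)
  expect_equal(m1$total_distance, 0)

  expect_error(match_patterns(c(O, O), O), "must not exceed")
})

test_that("optimal assignment never exceeds greedy, and equals exhaustive search on tiny cases", {
  set.seed(61)
  O <- optimal_set_4()
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  for (i in 1:10) {
    R <- replicate(sample(1:3, 1), sort(sample.int(4, 2)), simplify = FALSE)
    R <- R[!duplicated(vapply(R, pattern_key, character(1)))]
    opt <- match_patterns(R, O, method = "optimal")
    greedy <- match_patterns(R, O, method = "greedy")
    expect_lte(opt$total_distance, greedy$total_distance)
    # exhaustive minimum over every injective assignment R -> O
    injections <- unlist(lapply(
      utils::combn(length(O), length(R), simplify = FALSE), all_perms),
      recursive = FALSE)
    best <- min(vapply(injections, function(a) {
      sum(vapply(seq_along(R), function(r) {
        2 * active_difference(R[[r]], O[[a[r]]])
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(opt$total_distance, best)
  }
})

test_that("the work curve prices conversions and deletions correctly", {
  O <- optimal_set_4()
  wc <- work_curve(list(c(1, 4), c(2, 3)), O, S = 2)
  expect_equal(wc$total_bits, c(4, 4, 4))
  expect_equal(attr(wc, "min_work_bits"), 4)

  # R a subset of O: zero work at k = |R|
  wc0 <- work_curve(O[1:2], O, S = 2)
  expect_equal(attr(wc0, "min_work_bits"), 0)
  expect_equal(wc0$total_bits[wc0$k == 2], 0)

  # deleting everything always costs S * |R|
  set.seed(71)
  for (i in 1:5) {
    R <- replicate(3, sort(sample.int(6, 2)), simplify = FALSE)
    R <- R[!duplicated(vapply(R, pattern_key, character(1)))]
    O6 <- enumerate_valid_patterns(
      build_saturated_matrix(grid_spec(network_params(6, 2))), 2)
    wc <- work_curve(R, O6, S = 2)
    expect_equal(wc$total_bits[wc$k == 0], 2 * length(R))
    expect_lte(attr(wc, "min_work_bits"), 2 * length(R))
    # increments follow sorted conversion costs: total(k) - total(k-1) = d_k - S
    d <- sort(attr(wc, "assignment")$distances)
    expect_equal(diff(wc$total_bits), d - 2)
  }
})

test_that("executing the argmin reorganization reaches the closed-form capacity", {
  params <- network_params(6, 2)
  O <- enumerate_valid_patterns(
    build_saturated_matrix(grid_spec(params)), 2)
  r <- random_fill(params, seed = 4)
  wc <- work_curve(r$patterns, O, S = 2)
  m <- attr(wc, "assignment")
  k_star <- attr(wc, "argmin_k")
  # convert the k* cheapest pairs, delete the rest, then add every optimal
  # pattern not already present: the result is the full optimal set
  ord <- order(m$distances)
  converted <- lapply(ord[seq_len(k_star)], function(i) O[[m$assignment[i]]])
  missing <- O[!vapply(O, function(p) {
    any(vapply(converted, function(q) setequal(p, q), logical(1)))
  }, logical(1))]
  final <- c(converted, missing)
  expect_true(same_pattern_set(final, O))
  expect_length(final, capacity_closed_form(6, 2))
  expect_true(family_mutually_recalls(final, params))
  expect_lte(attr(wc, "min_work_bits"), 2 * length(r$patterns))
})
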