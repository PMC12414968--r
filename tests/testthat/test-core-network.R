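test_that("clipped storage writes the outer-product block and is idempotent", {
  W <- store_pattern(empty_connectivity(4), c(1, 2))
  expected <- empty_connectivity(4)
  expected[1:2, 1:2] <- 1L
  expect_identical(W, expected)
  expect_identical(store_pattern(W, c(1, 2)), W)

  W2 <- store_pattern(W, c(3, 4))
  expect_equal(sum(W2), 8)
  expect_true(all(W2[1:2, 3:4] == 0L))

  expect_error(store_pattern(empty_connectivity(4), c(1, 5)), "indices")
  expect_error(store_pattern(empty_connectivity(4), c(2, 2)), "distinct")
})

test_that("thresholded recall reproduces the worked 4-unit examples", {
  r <- recall(canonical_W4, c(1, 2), T = 2)
  expect_identical(r$active, c(1L, 2L))
  expect_true(is_exact_recall(canonical_W4, c(1, 2), 2))

  r <- recall(canonical_W4, c(1, 4), T = 2)
  expect_identical(r$sums, c(1L, 2L, 2L, 1L))
  expect_identical(r$active, c(2L, 3L))
  expect_false(is_exact_recall(canonical_W4, c(1, 4), 2))

  ones <- matrix(1L, 5, 5)
  expect_identical(recall(ones, c(2, 4), T = 2)$active, 1:5)

  # lone stored pattern always self-recalls at T = S
  W <- store_pattern(empty_connectivity(6), c(2, 3, 5))
  expect_true(is_exact_recall(W, c(2, 3, 5), T = 3))
})

test_that("recall agrees with full binary-vector multiplication", {
  set.seed(11)
  for (i in 1:20) {
    N <- sample(4:10, 1)
    W <- store_patterns(empty_connectivity(N),
                        replicate(3, sort(sample.int(N, 3)), simplify = FALSE))
    p <- sort(sample.int(N, 3))
    T <- sample(1:3, 1)
    expect_identical(recall(W, p, T)$active, recall_via_vector(W, p, T))
  }
})

test_that("strict-inequality firing matches the canonical rule shifted by one", {
  for (T in 1:2) {
    r_strict <- recall(canonical_W4, c(1, 2), T = T, strict = TRUE)
    r_canon <- recall(canonical_W4, c(1, 2), T = T + 1L)
    expect_identical(r_strict$active, r_canon$active)
  }
})

test_that("cross-pattern activation counts non-member interference only", {
  pats <- list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
  W <- store_patterns(empty_connectivity(4), pats)
  expect_identical(W, canonical_W4)
  expect_equal(cross_pattern_activation(W, pats), 8)

  expect_equal(cross_pattern_activation(empty_connectivity(4), pats), 0)
  W1 <- store_pattern(empty_connectivity(4), c(1, 2))
  expect_equal(cross_pattern_activation(W1, list(c(1, 2))), 0)
})

test_that("the saturated-state test pins non-member sums at T - 1", {
  pats <- list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
  expect_true(is_saturated_state(canonical_W4, pats, T = 2))

  W <- canonical_W4
  W[1, 2] <- 0L  # drop one connection: some non-member sum falls to 0
  expect_false(is_saturated_state(W, pats, T = 2))

  expect_true(is_saturated_state(empty_connectivity(3), list(), T = 2))
})

test_that("storage is monotone in every entry and every pre-threshold sum", {
  set.seed(21)
  N <- 8
  W <- empty_connectivity(N)
  probe <- sort(sample.int(N, 3))
  prev_sums <- recall(W, probe, T = 1)$sums
  for (i in 1:10) {
    W2 <- store_pattern(W, sort(sample.int(N, 3)))
    expect_true(all(W2 >= W))
    sums <- recall(W2, probe, T = 1)$sums
    expect_true(all(sums >= prev_sums))
    W <- W2
    prev_sums <- sums
  }
})

test_that("exact recall is threshold-monotone", {
  set.seed(31)
  for (i in 1:15) {
    N <- 8
    pats <- replicate(4, sort(sample.int(N, 3)), simplify = FALSE)
    W <- store_patterns(empty_connectivity(N), pats)
    p <- pats[[1]]
    for (T in 1:3) {
      if (is_exact_recall(W, p, T)) {
        expect_true(all(recall(W, p, T)$sums[p] >= T))
        # raising the threshold can only silence outputs
        expect_true(all(recall(W, p, T + 1L)$active %in%
                          recall(W, p, T)$active))
      }
    }
  }
})

test_that("parameter validation enforces the invariants", {
  expect_error(network_params(4, 5), "S must")
  expect_error(network_params(4, 2, 3), "D must")
  expect_error(network_params(6, 4, require_divisible = TRUE), "divide")
  expect_error(network_params(12, 6, 4, require_divisible = TRUE), "divide")
  p <- network_params(12, 4, 2)
  expect_equal(p$T, 3)
  expect_equal(canonical_threshold(4, 1), 4)
  # boundary sparsities are allowed
  expect_equal(network_params(5, 5)$T, 5)
  expect_equal(network_params(5, 1)$T, 1)
})
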