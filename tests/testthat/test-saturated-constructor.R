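test_that("the grid construction reproduces the worked 4-unit matrix", {
  W <- build_saturated_matrix(canonical_spec4())
  expect_identical(W, canonical_W4)
  expect_length(validate_saturated(W, canonical_spec4()), 0)
})

test_that("basis patterns tile the units into disjoint blocks", {
  expect_equal(basis_patterns(grid_spec(network_params(4, 2))),
               list(1:2, 3:4))
  expect_equal(basis_patterns(grid_spec(network_params(6, 2))),
               list(1:2, 3:4, 5:6))
  expect_equal(basis_patterns(grid_spec(network_params(8, 4, 2))),
               list(1:4, 5:8))
  # single block: all-ones matrix
  expect_identical(build_saturated_matrix(grid_spec(network_params(2, 2))),
                   matrix(1L, 2, 2))
})

test_that("off-diagonal sub-matrices carry exactly one zero per row and column", {
  for (cfg in list(c(6, 2), c(9, 3), c(12, 4))) {
    spec <- grid_spec(network_params(cfg[1], cfg[2]))
    W <- build_saturated_matrix(spec)
    expect_length(validate_saturated(W, spec), 0)
    S <- cfg[2]; B <- cfg[1] / S
    for (a in seq_len(B)) for (b in seq_len(B)) {
      M <- W[((a - 1) * S + 1):(a * S), ((b - 1) * S + 1):(b * S)]
      if (a == b) {
        expect_true(all(M == 1L))
      } else {
        expect_true(all(rowSums(M == 0L) == 1))
        expect_true(all(colSums(M == 0L) == 1))
      }
    }
  }
})

test_that("the validator reports structural violations with block coordinates", {
  spec <- grid_spec(network_params(4, 2))
  v <- validate_saturated(matrix(1L, 4, 4), spec)
  expect_true(any(grepl("one zero per row/column", v)))

  W <- build_saturated_matrix(spec)
  W[1, 4] <- 0L  # second zero in an off-diagonal row
  v <- validate_saturated(W, spec)
  expect_true(any(grepl("\\(1,2\\)", v)))

  W <- build_saturated_matrix(spec)
  W[1, 1] <- 0L
  expect_true(any(grepl("diagonal", validate_saturated(W, spec))))

  # inconsistent zero placement across three blocks
  spec9 <- grid_spec(network_params(9, 3))
  W9 <- build_saturated_matrix(spec9)
  blk23 <- W9[4:6, 7:9]
  W9[4:6, 7:9] <- blk23[c(2, 1, 3), ]  # still one zero/row+col, wrong family
  expect_true(any(grepl("inconsistent", validate_saturated(W9, spec9))))

  expect_error(validate_saturated(matrix(0L, 3, 3), spec), "matrix")
})

test_that("every permutation family member is saturated and capacity-invariant", {
  set.seed(41)
  for (cfg in list(c(6, 2, 1), c(9, 3, 1), c(12, 4, 1), c(8, 4, 2))) {
    params <- network_params(cfg[1], cfg[2], cfg[3])
    S_eq <- params$S %/% params$D
    B <- params$N %/% params$S
    for (rep in 1:3) {
      perms <- replicate(B, sample.int(S_eq), simplify = FALSE)
      spec <- grid_spec(params, perms = perms)
      W <- build_saturated_matrix(spec)
      expect_length(validate_saturated(W, spec), 0)

      pats <- enumerate_valid_patterns(W, params$S)
      expect_length(pats, capacity_general(params$N, params$S, params$D))

      # basis patterns recall exactly at the canonical threshold
      for (bp in basis_patterns(spec)) {
        expect_true(is_exact_recall(W, bp, params$T))
      }
      # saturation fixed point: storing all valid patterns reproduces W
      expect_identical(store_patterns(empty_connectivity(params$N), pats), W)
      # ideal state: every non-member sum sits exactly at T - 1
      expect_true(is_saturated_state(W, pats, params$T))
    }
  }
})

test_that("D > 1 matrices are D x D expansions of the equivalent construction", {
  params <- network_params(8, 4, 2)
  W <- build_saturated_matrix(grid_spec(params))
  W_eq <- build_saturated_matrix(grid_spec(network_params(4, 2)))
  expanded <- W_eq %x% matrix(1L, 2, 2)
  storage.mode(expanded) <- "integer"
  expect_identical(W, expanded)
  expect_equal(count_valid_patterns(W, 4), 4)
})

test_that("grid specs reject malformed permutations", {
  expect_error(grid_spec(network_params(6, 2), perms = list(1:2)), "per block")
  expect_error(grid_spec(network_params(6, 2),
                         perms = list(1:2, 1:2, c(1, 1))), "permutation")
})
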