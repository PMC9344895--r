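turner_pairs <- lapply(
  list(c("C", "G", 89), c("G", "C", 89), c("C", "G", 99),
       c("G", "C", 99), c("C", "G", "04"), c("G", "C", "04")),
  function(x) derive_coefficients(nntm_turner(x[1], x[2], x[3])))

test_that("exact distribution reproduces hand-computed weights", {
  u <- exact_distribution(1, 0, 0)
  expect_equal(unname(u$prob), c(0.5, 0.5))

  d <- exact_distribution(1, 0, log(2))
  expect_equal(d$prob[d$states == "H"], 2 / 3, ignore_attr = TRUE)
  expect_equal(d$prob[d$states == "I"], 1 / 3, ignore_attr = TRUE)

  big <- exact_distribution(4, -2.8, -3.0)
  expect_equal(length(big$states), 42)
  expect_equal(sum(big$prob), 1, tolerance = 1e-12)
})

test_that("log-space weighting survives extreme coefficients", {
  d <- exact_distribution(6, -50, 40)
  expect_true(all(is.finite(d$prob)))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("transition matrix matches the two-state hand computation", {
  tm <- transition_matrix(1, 0, 0)
  expect_equal(tm$P["H", "I"], 1 / 16)
  expect_equal(tm$P["I", "H"], 1 / 16)
  expect_equal(diag(tm$P), c(H = 15 / 16, I = 15 / 16))
})

test_that("rows are stochastic and entries nonnegative", {
  for (m in 1:5) {
    tm <- transition_matrix(m, -0.9, -1.8)
    expect_true(all(tm$P >= 0))
    expect_equal(rowSums(tm$P), setNames(rep(1, length(tm$states)),
                                         tm$states), tolerance = 1e-12)
  }
})

test_that("detailed balance holds across published coefficient pairs", {
  for (co in c(turner_pairs, list(energy_coefficients(0, 0)))) {
    for (m in 1:4) {
      tm <- transition_matrix(m, co$alpha, co$beta)
      dist <- exact_distribution(m, co$alpha, co$beta)
      expect_lt(verify_detailed_balance(tm, dist), 1e-12)
    }
  }
})

test_that("the balance meter detects a corrupted matrix", {
  tm <- transition_matrix(2, 0, 0)
  dist <- exact_distribution(2, 0, 0)
  tm$P[1, 2] <- tm$P[1, 2] + 0.01
  expect_gt(verify_detailed_balance(tm, dist), 0.001)
  # symmetric matrix with uniform target balances exactly
  P <- matrix(1 / 3, 3, 3)
  expect_equal(verify_detailed_balance(P, rep(1 / 3, 3)), 0)
})

test_that("leading eigenvector recovers the Gibbs distribution", {
  tm <- transition_matrix(2, 0, 0)
  expect_equal(stationary_from_matrix(tm), rep(1 / 5, 5), tolerance = 1e-10)
  for (co in turner_pairs[c(1, 3, 6)]) {
    for (m in 2:5) {
      tm <- transition_matrix(m, co$alpha, co$beta)
      dist <- exact_distribution(m, co$alpha, co$beta)
      expect_lt(total_variation(stationary_from_matrix(tm), dist$prob),
                1e-10)
    }
  }
})

test_that("non-ergodic matrices are rejected", {
  expect_error(stationary_from_matrix(diag(3)), "strongly connected")
  expect_error(stationary_from_matrix(matrix(c(0.5, 0.2), 2, 2)),
               "row-stochastic")
})

test_that("total variation behaves as a metric on distributions", {
  expect_equal(total_variation(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(total_variation(c(1, 0), c(0, 1)), 1)
  expect_equal(total_variation(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(total_variation(c(1), c(0.5, 0.5)), "length")
})

test_that("spectral diagnostics report the known two-state gap", {
  dg <- spectral_diagnostics(transition_matrix(1, 0, 0))
  expect_equal(dg$spectral_gap, 1 / 8, tolerance = 1e-12)
  expect_true(dg$irreducible)
})

test_that("the spectral gap is positive across sizes and coefficients", {
  for (co in c(turner_pairs[c(2, 5)], list(energy_coefficients(0, 0)))) {
    for (m in 1:5) {
      dg <- spectral_diagnostics(transition_matrix(m, co$alpha, co$beta))
      expect_gt(dg$spectral_gap, 0)
      expect_lte(dg$spectral_gap, 1)
      expect_true(dg$irreducible)
      expect_lt(dg$detailed_balance_violation, 1e-12)
    }
  }
})
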