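test_that("runs are bit-reproducible given a seed", {
  a <- run_chain(5, -0.9, -1.8, steps = 5000, burn_in = 100, thinning = 5,
                 seed = 11)
  b <- run_chain(5, -0.9, -1.8, steps = 5000, burn_in = 100, thinning = 5,
                 seed = 11)
  expect_identical(a$paths, b$paths)
  expect_identical(a$tallies, b$tallies)
  c <- run_chain(5, -0.9, -1.8, steps = 5000, burn_in = 100, thinning = 5,
                 seed = 12)
  expect_false(identical(a$paths, c$paths))
})

test_that("kept count, validity and configuration contracts hold", {
  fit <- run_chain(4, 0, 0, steps = 1037, burn_in = 100, thinning = 7,
                   seed = 3)
  expect_equal(length(fit$paths), (1037 - 100) %/% 7)
  expect_true(all(vapply(fit$paths, validate_path, logical(1))))
  expect_true(all(nchar(fit$paths) == 4))
  expect_identical(fit$config$initial, "HHHH")
  expect_error(run_chain(4, 0, 0, steps = 10, burn_in = 20), "burn_in")
  expect_error(run_chain(4, 0, 0, steps = 100, initial = "UDUDH"),
               "length")
  expect_error(run_chain(4, 0, 0, steps = 100, initial = "DUDU"),
               "not a valid")
})

test_that("single steps at m=1 hit the hand-computed rate", {
  set.seed(5)
  steps <- vapply(1:20000, function(i) chain_step("H", 0, 0), character(1))
  phat <- mean(steps == "I")
  se <- sqrt((1 / 16) * (15 / 16) / 20000)
  expect_lt(abs(phat - 1 / 16), 4 * se)
})

test_that("empirical one-step kernel matches the exact matrix at m=2", {
  states <- enumerate_paths(2)
  tm <- transition_matrix(2, -0.9, -1.8)
  set.seed(17)
  trials <- 100000L
  for (s in seq_along(states)) {
    x0 <- match(strsplit(states[s], "")[[1]], c("U", "H", "I", "D"))
    out <- treegibbs:::cpp_single_steps(x0, -0.9, -1.8, trials)
    code <- out %*% 4^((2 - 1):0)
    scode <- vapply(states, function(st) {
      sum(match(strsplit(st, "")[[1]], c("U", "H", "I", "D")) * 4^(1:0))
    }, numeric(1))
    phat <- tabulate(match(code, scode), nbins = length(states)) / trials
    p <- tm$P[s, ]
    se <- sqrt(p * (1 - p) / trials)
    expect_true(all(abs(phat - p) <= 4 * se + 1e-12))
  }
})

test_that("a long fuzz run never leaves the valid state space", {
  expect_equal(fuzz_chain(12, -2.8, -2.2, steps = 1e6, seed = 23), 0)
  expect_equal(fuzz_chain(3, 2.3, 1.3, steps = 2e5, seed = 29), 0)
})

test_that("the chain converges to the enumerated Gibbs distribution", {
  fit <- run_chain(3, -0.9, -1.2, steps = 4e5, burn_in = 1e4, thinning = 5,
                   seed = 31)
  dist <- exact_distribution(3, -0.9, -1.2)
  expect_lt(total_variation(empirical_distribution(fit), dist$prob), 0.02)
})

test_that("sampled trees transport the path statistics", {
  st <- sample_trees(4, 0, 0, steps = 20000, burn_in = 1000, thinning = 10,
                     seed = 41)
  expect_equal(length(st$trees), length(st$sample$paths))
  for (k in seq_along(st$trees)) {
    ds <- degree_summary(st$trees[[k]])
    cnt <- path_counts(st$sample$paths[k])
    expect_equal(ds$n, 5)
    expect_equal(ds$d1, unname(cnt[["I"]]))
    expect_equal(ds$d0, unname(cnt[["U"]] + cnt[["H"]] + 1L))
  }
})

test_that("uniform coefficients give the uniform leaf-count law", {
  # under alpha = beta = 0 every one of the 14 trees with 4 edges is equally
  # likely; the leaf-count distribution follows by direct enumeration
  st <- sample_trees(3, 0, 0, steps = 2e5, burn_in = 1e4, thinning = 10,
                     seed = 43)
  d0 <- vapply(st$trees, function(t) degree_summary(t)$d0, integer(1))
  expected <- table(vapply(enumerate_trees(4),
                           function(t) degree_summary(t)$d0, integer(1))) / 14
  for (v in names(expected)) {
    p <- expected[[v]]
    phat <- mean(d0 == as.integer(v))
    se <- sqrt(p * (1 - p) / length(d0))
    # thinned samples retain some autocorrelation; allow a widened band
    expect_lt(abs(phat - p), 6 * se)
  }
})

test_that("summary and plot methods operate on sample objects", {
  fit <- run_chain(4, -0.9, -1.8, steps = 5000, burn_in = 500, thinning = 10,
                   seed = 47)
  s <- summary(fit)
  expect_s3_class(s, "dispersion_summary")
  expect_true("hairpins" %in% s$statistic)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), length(fit$paths))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
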