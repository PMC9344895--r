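test_that("coefficient reduction matches hand evaluation", {
  co <- derive_coefficients(nntm_params(4.6, 0.4, 0.1, -10.9, 3.8, 3.0, -1.6))
  expect_equal(co$alpha, -0.9)
  expect_equal(co$beta, -1.8)
  expect_equal(co$gamma, -1.7)

  z <- derive_coefficients(nntm_params(0, 0, 0, 0, 0, 0, 0))
  expect_equal(unlist(z[c("alpha", "beta", "gamma", "delta")]),
               c(alpha = 0, beta = 0, gamma = 0, delta = 0))

  u <- derive_coefficients(nntm_params(1, 1, 1, 1, 1, 1, 1))
  expect_equal(u$alpha, -6)
  expect_equal(u$beta, -12)
  expect_equal(u$gamma, -5)
  expect_equal(u$delta, 14)
})

test_that("non-finite NNTM inputs are rejected naming the field", {
  expect_error(nntm_params(NA, 0, 0, 0, 0, 0, 0), "'a'")
  expect_error(nntm_params(0, 0, 0, Inf, 0, 0, 0), "'h'")
})

test_that("built-in parameter sets return the published rows", {
  p <- nntm_turner("C", "G", 99)
  expect_equal(unlist(p[c("a", "b", "c", "h", "f", "i", "g")]),
               c(a = 3.4, b = 0, c = 0.4, h = -12.9, f = 4.5, i = 2.3,
                 g = -1.6))
  q <- nntm_turner("G", "C", "04")
  expect_equal(unlist(q[c("a", "b", "c", "h", "f", "i", "g")]),
               c(a = 9.3, b = 0, c = -0.9, h = -16.9, f = 4.1, i = 2.3,
                 g = -1.5))
  expect_error(nntm_turner("A", "U", 89), "valid options")
})

test_that("tree and path energies agree with direct counts", {
  co <- energy_coefficients(-0.9, -1.8)
  star4 <- parse_tree("()()()()")
  expect_equal(tree_energy(star4, co), 4 * -0.9)
  expect_equal(tree_energy(star4, energy_coefficients(0, 0)), 0)
  chain2 <- parse_tree("(())")
  expect_equal(tree_energy(chain2, energy_coefficients(1, 2)), 3)

  expect_equal(path_energy("UD", energy_coefficients(1, 0)), 2)
  expect_equal(path_energy("", energy_coefficients(5, 7)), 5)
  expect_equal(path_energy("UHID", energy_coefficients(0, 0)), 0)
})

test_that("root and size terms enter tree_energy only on request", {
  co <- energy_coefficients(1, 2, gamma = 10, delta = 100)
  star4 <- parse_tree("()()()()")  # d0=4, d1=0, r=4, n=4
  expect_equal(tree_energy(star4, co), 4)
  expect_equal(tree_energy(star4, co, include_root_term = TRUE), 4 + 40)
  expect_equal(tree_energy(star4, co, include_root_term = TRUE,
                           include_delta_term = TRUE), 4 + 40 + 400)
})

test_that("un-reduced NNTM energy equals the reduced-coefficient route", {
  # full enumeration of trees with n <= 6 under random parameter sets
  set.seed(42)
  trees <- unlist(lapply(1:6, enumerate_trees), recursive = FALSE)
  for (rep in 1:25) {
    params <- random_nntm_params()
    co <- derive_coefficients(params)
    for (t in trees) {
      ds <- degree_summary(t)
      e1 <- full_structure_energy(ds$d_counts, ds$r, ds$n, params)
      e2 <- tree_energy(t, co, include_root_term = TRUE,
                        include_delta_term = TRUE)
      expect_equal(e1, e2, tolerance = 1e-9)
    }
  }
})

test_that("full_structure_energy rejects broken degree identities", {
  p <- nntm_params(1, 1, 1, 1, 1, 1, 1)
  expect_error(full_structure_energy(c(2, 1), 1, 4, p), "sum\\(d_k\\)")
  expect_error(full_structure_energy(c(2, 2), 3, 4, p), "n - r")
  # star n=2: d0=2, r=2 with zero params
  expect_equal(full_structure_energy(c(2), 2, 2,
                                     nntm_params(0, 0, 0, 0, 0, 0, 0)), 0)
})

test_that("path energy transports tree energy through the bijection", {
  co <- energy_coefficients(0.7, -1.3)
  for (n in 1:6) {
    for (t in enumerate_trees(n)) {
      expect_identical(path_energy(tree_to_path(t), co), tree_energy(t, co))
    }
  }
})

test_that("parameter files round-trip through both text formats", {
  kv <- tempfile(fileext = ".txt")
  writeLines(c("# test set", "a=4.6", "b=0.4", "c=0.1", "h=-10.9",
               "f=3.8", "i=3.0", "g=-1.6"), kv)
  p <- read_nntm_params(kv)
  expect_equal(derive_coefficients(p)$alpha, -0.9)

  js <- tempfile(fileext = ".json")
  writeLines('{"a":3.4,"b":0,"c":0.4,"h":-12.9,"f":4.5,"i":2.3,"g":-1.6}', js)
  expect_equal(derive_coefficients(read_nntm_params(js))$alpha, 2.3)

  bad <- tempfile()
  writeLines(c("a=1", "b=2"), bad)
  expect_error(read_nntm_params(bad), "missing keys")
})
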