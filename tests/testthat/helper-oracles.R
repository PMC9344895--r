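# Independent brute-force oracles, deliberately naive so they share no code
# with the implementation under test.

# all valid 2-Motzkin paths of length m by filtering all 4^m strings
brute_force_paths <- function(m) {
  if (m == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(c("D", "H", "I", "U")), m),
                    stringsAsFactors = FALSE))
  cand <- do.call(paste0, rev(grid))
  ok <- vapply(cand, function(s) {
    sym <- strsplit(s, "")[[1]]
    h <- 0
    for (ch in sym) {
      if (ch == "U") h <- h + 1
      if (ch == "D") h <- h - 1
      if (h < 0) return(FALSE)
    }
    h == 0
  }, logical(1))
  sort(cand[ok])
}

# number of single-coloured Motzkin paths of length n by filtering 3^n strings
brute_force_motzkin_count <- function(n) {
  if (n == 0L) return(1L)
  grid <- do.call(expand.grid,
                  c(rep(list(c("U", "H", "D")), n), stringsAsFactors = FALSE))
  cand <- do.call(paste0, grid)
  sum(vapply(cand, function(s) {
    sym <- strsplit(s, "")[[1]]
    h <- 0
    for (ch in sym) {
      if (ch == "U") h <- h + 1
      if (ch == "D") h <- h - 1
      if (h < 0) return(FALSE)
    }
    h == 0
  }, logical(1)))
}

random_nntm_params <- function() {
  v <- round(runif(7, -20, 20), 2)
  nntm_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], label = "random")
}

# energy of a tree straight from the definition: count leaves and
# single-child non-root nodes by walking the parenthesis string
naive_tree_energy <- function(parens, alpha, beta) {
  sym <- strsplit(parens, "")[[1]]
  # depth-wise child counts: track number of children per open node
  stack <- 0L  # root's child count at position 1
  d0 <- 0L; d1 <- 0L
  counts <- integer(1)
  for (ch in sym) {
    if (ch == "(") {
      counts[length(counts)] <- counts[length(counts)] + 1L
      counts <- c(counts, 0L)
    } else {
      k <- counts[length(counts)]
      if (k == 0L) d0 <- d0 + 1L
      if (k == 1L) d1 <- d1 + 1L
      counts <- counts[-length(counts)]
    }
  }
  alpha * d0 + beta * d1
}
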