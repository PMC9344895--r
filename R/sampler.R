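# The production sampler: a seeded, reproducible Markov chain on 2-Motzkin
# paths targeting the Gibbs distribution with energy
# E(x) = alpha (|x|_U + |x|_H + 1) + beta |x|_I. The inner loop is compiled;
# randomness comes from R's RNG, so set.seed()/the `seed` argument gives
# bit-reproducible runs within one build of the package.

.sym_levels <- c("U", "H", "I", "D")

path_to_codes <- function(path) {
  if (!nzchar(path)) return(integer(0))
  match(strsplit(path, "", fixed = TRUE)[[1L]], .sym_levels)
}

codes_to_paths <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  cols <- lapply(seq_len(ncol(mat)), function(j) .sym_levels[mat[, j]])
  if (!length(cols)) return(rep("", nrow(mat)))
  do.call(paste0, cols)
}

resolve_coefficients <- function(alpha, beta) {
  if (inherits(alpha, "energy_coefficients")) {
    if (!missing(beta) && !is.null(beta)) {
      stop("supply either an energy_coefficients object or alpha and beta, ",
           "not both", call. = FALSE)
    }
    list(alpha = alpha$alpha, beta = alpha$beta)
  } else {
    if (is.null(beta)) {
      stop("supply beta alongside alpha, or pass an energy_coefficients ",
           "object", call. = FALSE)
    }
    stopifnot(is.numeric(alpha), is.numeric(beta),
              is.finite(alpha), is.finite(beta))
    list(alpha = as.numeric(alpha), beta = as.numeric(beta))
  }
}

#' One step of the sampling chain
#'
#' Advances a 2-Motzkin path by exactly one step of the four-move chain:
#' a move type is drawn uniformly from \{1, 2, 3, 4\}, then (1) an adjacent
#' pair is toggled between `UD` and `HH` with the Gibbs-balanced Bernoulli
#' probabilities, (2) a single position is toggled between `H` and `I`, (3)
#' two positions holding `U`/`D` symbols are swapped with probability 1/2 and
#' reverted if the result is invalid, or (4) an adjacent `U`/`D`-vs-`H`/`I`
#' pair is reversed with probability 1/2. The output is always a valid path.
#' Uses (and advances) R's global RNG stream; draw order is move type, then
#' index(es), then one Bernoulli uniform.
#'
#' @param path A valid 2-Motzkin path string.
#' @param alpha,beta Energy coefficients, or an [energy_coefficients()]
#'   object as `alpha`.
#' @return The path after one step.
#' @export
chain_step <- function(path, alpha, beta = NULL) {
  assert_valid_path(path)
  cf <- resolve_coefficients(alpha, beta)
  if (!nzchar(path)) return(path)
  out <- cpp_single_steps(path_to_codes(path), cf$alpha, cf$beta, 1L)
  codes_to_paths(out)
}

#' Run the branching-sampler Markov chain
#'
#' Runs the four-move chain (see [chain_step()]) on 2-Motzkin paths of length
#' `m` for `steps` steps from the all-`H` path (the hub of the chain's
#' irreducibility argument) or a supplied initial state, discarding a burn-in
#' prefix and keeping every `thinning`-th state thereafter. The stationary
#' distribution is the Gibbs distribution with energy
#' `alpha (|x|_U + |x|_H + 1) + beta |x|_I`, i.e. the branching Gibbs
#' distribution over plane trees with `m + 1` edges pushed through the
#' bijection. The exterior-loop coefficient gamma does not enter the sampled
#' distribution.
#'
#' @param m Path length (trees have `m + 1` edges).
#' @param alpha,beta Energy coefficients (kcal/mol), or an
#'   [energy_coefficients()] object as `alpha` (its gamma/delta are ignored).
#' @param steps Total number of chain steps (>= 1).
#' @param burn_in Steps discarded before collection (0 <= burn_in <= steps).
#' @param thinning Keep every `thinning`-th post-burn-in state.
#' @param seed Optional integer seed (calls `set.seed`); if `NULL` the
#'   current RNG state is used.
#' @param initial Starting path; defaults to `strrep("H", m)`.
#' @return An object of class `tree_gibbs`: kept paths, the configuration,
#'   per-move-type attempt/acceptance tallies, and the final state. The kept
#'   count is `floor((steps - burn_in) / thinning)`.
#' @examples
#' fit <- run_chain(4, alpha = -0.9, beta = -1.8, steps = 2000, seed = 1)
#' fit
#' @export
run_chain <- function(m, alpha, beta = NULL, steps, burn_in = 0,
                      thinning = 1, seed = NULL, initial = NULL) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  cf <- resolve_coefficients(alpha, beta)
  steps <- as.numeric(steps); burn_in <- as.numeric(burn_in)
  thinning <- as.numeric(thinning)
  if (steps < 1 || burn_in < 0 || burn_in > steps || thinning < 1) {
    stop("need steps >= 1, 0 <= burn_in <= steps, thinning >= 1",
         call. = FALSE)
  }
  if (is.null(initial)) initial <- strrep("H", m)
  assert_valid_path(initial)
  if (nchar(initial) != m) {
    stop("initial path has length ", nchar(initial), ", expected m = ", m,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- cpp_run_chain(path_to_codes(initial), cf$alpha, cf$beta,
                       steps, burn_in, thinning)
  tallies <- data.frame(
    move = c("UD/HH toggle", "H/I toggle", "U-D swap", "colour swap"),
    attempts = res$attempts,
    accepted = res$accepted
  )
  structure(list(
    paths = codes_to_paths(res$kept),
    final = codes_to_paths(matrix(res$final, nrow = 1L)),
    tallies = tallies,
    config = list(m = m, alpha = cf$alpha, beta = cf$beta, steps = steps,
                  burn_in = burn_in, thinning = thinning, seed = seed,
                  initial = initial)
  ), class = "tree_gibbs")
}

#' Sample plane trees from the branching Gibbs distribution
#'
#' Convenience wrapper: [run_chain()] followed by [path_to_tree()] on every
#' kept state.
#'
#' @inheritParams run_chain
#' @return List with `trees` (a list of [plane_tree] objects) and `sample`
#'   (the underlying `tree_gibbs` object).
#' @export
sample_trees <- function(m, alpha, beta = NULL, steps, burn_in = 0,
                         thinning = 1, seed = NULL, initial = NULL) {
  fit <- run_chain(m, alpha, beta, steps, burn_in, thinning, seed, initial)
  list(trees = lapply(fit$paths, path_to_tree), sample = fit)
}

#' @export
print.tree_gibbs <- function(x, ...) {
  cfg <- x$config
  cat("Gibbs branching sample (2-Motzkin chain)\n")
  cat("  m = ", cfg$m, " (trees with ", cfg$m + 1L, " edges), alpha = ",
      cfg$alpha, ", beta = ", cfg$beta, "\n", sep = "")
  cat("  steps = ", format(cfg$steps, scientific = FALSE), ", burn-in = ",
      format(cfg$burn_in, scientific = FALSE), ", thinning = ", cfg$thinning,
      if (!is.null(cfg$seed)) paste0(", seed = ", cfg$seed), "\n", sep = "")
  cat("  kept states:", length(x$paths), "\n")
  acc <- ifelse(x$tallies$attempts > 0,
                x$tallies$accepted / x$tallies$attempts, NA)
  cat("  move acceptance:",
      paste(sprintf("%s %.3f", x$tallies$move, acc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tree_gibbs <- function(x, ...) {
  cnt <- path_counts_matrix(x$paths)
  data.frame(index = seq_along(x$paths),
             path = x$paths,
             hairpins = cnt[, "U"] + cnt[, "H"] + 1L,
             internal_nodes = cnt[, "I"],
             stringsAsFactors = FALSE)
}

# symbol counts for many paths at once
path_counts_matrix <- function(paths) {
  cbind(U = nchar(gsub("[^U]", "", paths)),
        H = nchar(gsub("[^H]", "", paths)),
        I = nchar(gsub("[^I]", "", paths)),
        D = nchar(gsub("[^D]", "", paths)))
}

#' @export
summary.tree_gibbs <- function(object, ...) {
  trees <- lapply(object$paths, path_to_tree)
  records <- do.call(rbind, lapply(trees, function(t) {
    as.data.frame(tree_statistics(t))
  }))
  summarize_dispersion(records)
}

#' @export
plot.tree_gibbs <- function(x, statistic = c("hairpins", "internal_nodes"),
                            ...) {
  statistic <- match.arg(statistic)
  df <- as.data.frame(x)
  v <- df[[statistic]]
  graphics::barplot(table(v), xlab = statistic, ylab = "kept samples",
                    main = sprintf("m = %d, alpha = %g, beta = %g",
                                   x$config$m, x$config$alpha,
                                   x$config$beta), ...)
  invisible(x)
}

#' Empirical distribution of a sample over the enumerated state space
#'
#' Tabulates the kept paths of a [run_chain()] result against the full
#' enumeration of 2-Motzkin paths of the same length, for comparison with
#' [exact_distribution()] via [total_variation()].
#'
#' @param fit A `tree_gibbs` object (or a character vector of paths).
#' @param m Path length; taken from the object when omitted.
#' @param cap Enumeration guard.
#' @return Probability vector aligned with `enumerate_paths(m)`.
#' @export
empirical_distribution <- function(fit, m = NULL, cap = 10L) {
  paths <- if (inherits(fit, "tree_gibbs")) fit$paths else fit
  if (is.null(m)) {
    m <- if (inherits(fit, "tree_gibbs")) fit$config$m else nchar(paths[1L])
  }
  states <- enumerate_paths(m, cap = cap)
  idx <- match(paths, states)
  if (anyNA(idx)) stop("sample contains a path outside the state space",
                       call. = FALSE)
  tabulate(idx, nbins = length(states)) / length(paths)
}

#' Long-run validity fuzz of the chain
#'
#' Runs the chain for `steps` steps checking the 2-Motzkin validity
#' invariant after every step without storing states; returns the number of
#' invariant violations (zero for a correct kernel).
#'
#' @inheritParams run_chain
#' @return Number of invalid states encountered.
#' @export
fuzz_chain <- function(m, alpha, beta = NULL, steps, seed = NULL,
                       initial = NULL) {
  m <- as.integer(m)
  cf <- resolve_coefficients(alpha, beta)
  if (is.null(initial)) initial <- strrep("H", m)
  assert_valid_path(initial)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cpp_fuzz_chain(path_to_codes(initial), cf$alpha, cf$beta,
                 as.numeric(steps))
}
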