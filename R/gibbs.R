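# Exact small-instance machinery: the Gibbs distribution by enumeration, the
# full one-step transition matrix of the four-move chain, and the
# detailed-balance / stationarity / spectral diagnostics used to certify the
# sampler on sizes where complete enumeration is feasible.

# Move probabilities of the chain in numerically stable logistic form:
#   UD -> HH with e^(-a) / (2 (1 + e^(-a))) = 1/2 * plogis(-a), etc.
# Stable for arbitrary user-supplied coefficients (exp overflow saturates to
# the correct limit 0).
move_probs <- function(alpha, beta) {
  list(
    ud_hh = 0.5 / (1 + exp(alpha)),
    hh_ud = 0.5 / (1 + exp(-alpha)),
    i_h   = 0.5 / (1 + exp(alpha - beta)),
    h_i   = 0.5 / (1 + exp(beta - alpha))
  )
}

#' Exact Gibbs distribution over 2-Motzkin paths
#'
#' Enumerates every 2-Motzkin path of length m and assigns each the Gibbs
#' weight exp(-E(x)) / Z with E(x) = alpha (|x|_U + |x|_H + 1) + beta |x|_I.
#' Weights are computed in log space with a max shift before normalisation,
#' so large |alpha|, |beta| or m cannot overflow. With alpha = beta = 0 the
#' distribution is uniform over the catalan(m + 1) paths.
#'
#' @param m Path length.
#' @param alpha,beta Energy coefficients (kcal/mol).
#' @param cap Enumeration guard (default 10).
#' @return An object of class `gibbs_exact`: list with `states`, `prob`,
#'   `logZ`, `m`, `alpha`, `beta`.
#' @examples
#' exact_distribution(1, 0, log(2))$prob  # H: 2/3, I: 1/3
#' @export
exact_distribution <- function(m, alpha, beta, cap = 10L) {
  states <- enumerate_paths(m, cap = cap)
  cnt <- t(vapply(states, path_counts, integer(4)))
  logw <- -(alpha * (cnt[, "U"] + cnt[, "H"] + 1) + beta * cnt[, "I"])
  shift <- max(logw)
  w <- exp(logw - shift)
  list(states = states, prob = w / sum(w),
       logZ = shift + log(sum(w)),
       m = as.integer(m), alpha = alpha, beta = beta) |>
    structure(class = "gibbs_exact")
}

#' @export
print.gibbs_exact <- function(x, ...) {
  cat("exact Gibbs distribution over 2-Motzkin paths\n")
  cat("  m = ", x$m, " (", length(x$states), " states), alpha = ", x$alpha,
      ", beta = ", x$beta, ", logZ = ", format(x$logZ), "\n", sep = "")
  invisible(x)
}

#' Exact one-step transition matrix of the sampling chain
#'
#' Builds the full transition matrix of the four-move chain over all
#' 2-Motzkin paths of length m, summing each off-diagonal entry over move
#' types (each chosen with probability 1/4), index choices (1/(m-1) for the
#' adjacent-pair moves, 1/m or 1/m^2 for the others) and the move-specific
#' Bernoulli acceptance; the diagonal absorbs the remainder. For m = 1 the
#' adjacent-pair moves have an empty index range and are automatic no-ops.
#'
#' @inheritParams exact_distribution
#' @param cap Enumeration guard (default 8: the matrix is
#'   catalan(m+1) x catalan(m+1)).
#' @return An object of class `chain_matrix`: list with `states`, `P`, `m`,
#'   `alpha`, `beta`. Rows of `P` sum to one.
#' @export
transition_matrix <- function(m, alpha, beta, cap = 8L) {
  m <- as.integer(m)
  states <- enumerate_paths(m, cap = cap)
  N <- length(states)
  P <- matrix(0, N, N, dimnames = list(states, states))
  pr <- move_probs(alpha, beta)
  syms <- strsplit(states, "", fixed = TRUE)
  lookup <- setNames(seq_len(N), states)
  add <- function(row, ysym, p) {
    y <- paste(ysym, collapse = "")
    P[row, lookup[[y]]] <<- P[row, lookup[[y]]] + p
  }
  for (s in seq_len(N)) {
    x <- syms[[s]]
    if (m >= 2L) {
      w14 <- 0.25 / (m - 1)  # move types 1 and 4: adjacent pair choice
      for (i in seq_len(m - 1L)) {
        a <- x[i]; b <- x[i + 1L]
        if (a == "U" && b == "D") {
          y <- x; y[i] <- "H"; y[i + 1L] <- "H"
          add(s, y, w14 * pr$ud_hh)
        } else if (a == "H" && b == "H") {
          y <- x; y[i] <- "U"; y[i + 1L] <- "D"
          add(s, y, w14 * pr$hh_ud)
        }
        aud <- a %in% c("U", "D"); bud <- b %in% c("U", "D")
        if (xor(aud, bud)) {
          y <- x; y[i] <- b; y[i + 1L] <- a
          add(s, y, w14 * 0.5)  # swaps across colours always stay valid
        }
      }
    }
    w2 <- 0.25 / m
    for (i in seq_len(m)) {
      if (x[i] == "I") {
        y <- x; y[i] <- "H"; add(s, y, w2 * pr$i_h)
      } else if (x[i] == "H") {
        y <- x; y[i] <- "I"; add(s, y, w2 * pr$h_i)
      }
    }
    w3 <- 0.25 / m^2
    for (i in seq_len(m)) {
      if (!x[i] %in% c("U", "D")) next
      for (j in seq_len(m)) {
        if (j == i || !x[j] %in% c("U", "D") || x[j] == x[i]) next
        y <- x; y[i] <- x[j]; y[j] <- x[i]
        yp <- paste(y, collapse = "")
        if (validate_path(yp)) P[s, lookup[[yp]]] <- P[s, lookup[[yp]]] + w3 * 0.5
      }
    }
  }
  diag(P) <- 0
  diag(P) <- 1 - rowSums(P)
  structure(list(states = states, P = P, m = m, alpha = alpha, beta = beta),
            class = "chain_matrix")
}

#' @export
print.chain_matrix <- function(x, ...) {
  cat("one-step transition matrix: m = ", x$m, ", ", length(x$states),
      " states, alpha = ", x$alpha, ", beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Maximum detailed-balance violation
#'
#' Returns `max |pi(x) P(x,y) - pi(y) P(y,x)|` over all state pairs: zero (to
#' rounding) certifies that the chain is reversible with respect to `pi`.
#'
#' @param tm A [transition_matrix()] result (or a bare stochastic matrix).
#' @param pi A [exact_distribution()] result (or a bare probability vector in
#'   the same state order).
#' @return Nonnegative scalar.
#' @export
verify_detailed_balance <- function(tm, pi) {
  P <- if (inherits(tm, "chain_matrix")) tm$P else tm
  p <- if (inherits(pi, "gibbs_exact")) pi$prob else pi
  if (length(p) != nrow(P)) stop("state ordering mismatch", call. = FALSE)
  if (inherits(tm, "chain_matrix") && inherits(pi, "gibbs_exact") &&
      !identical(tm$states, pi$states)) {
    stop("state ordering mismatch", call. = FALSE)
  }
  flow <- p * P
  max(abs(flow - t(flow)))
}

#' Stationary distribution from the transition matrix
#'
#' The leading left eigenvector of an ergodic transition matrix, normalised
#' to a probability vector. Ergodicity is checked first: the transition
#' graph must be strongly connected and aperiodic (the chain's built-in
#' laziness guarantees self-loops).
#'
#' @param tm A [transition_matrix()] result or bare stochastic matrix.
#' @return Probability vector in the matrix's state order.
#' @export
stationary_from_matrix <- function(tm) {
  P <- if (inherits(tm, "chain_matrix")) tm$P else tm
  if (nrow(P) != ncol(P)) stop("matrix must be square", call. = FALSE)
  if (any(P < -1e-12) || max(abs(rowSums(P) - 1)) > 1e-9) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  if (!is_strongly_connected(P > 0)) {
    stop("transition matrix is not ergodic: graph not strongly connected",
         call. = FALSE)
  }
  if (all(diag(P) == 0)) {
    stop("transition matrix has no self-loops; aperiodicity not established",
         call. = FALSE)
  }
  e <- eigen(t(P))
  i <- which.min(Mod(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("leading eigenvector is not nonnegative",
                            call. = FALSE)
  pmax(v, 0) / sum(pmax(v, 0))
}

# strong connectivity: every state reachable from state 1 and state 1
# reachable from every state
is_strongly_connected <- function(adj) {
  reach <- function(A) {
    seen <- logical(nrow(A))
    frontier <- 1L
    seen[1L] <- TRUE
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

#' Total variation distance
#'
#' One half the L1 distance between two probability vectors over the same
#' ordered support; the convergence metric in the mixing-time definition.
#'
#' @param p,q Probability vectors of equal length.
#' @return Number in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  0.5 * sum(abs(p - q))
}

#' Spectral and reversibility diagnostics of the chain
#'
#' Summarises the chain at a fully enumerable size: the second-largest
#' eigenvalue modulus |lambda_1| and spectral gap 1 - |lambda_1| (its inverse
#' is the relaxation time), the maximum detailed-balance violation against
#' the enumerated Gibbs distribution, the total-variation distance between
#' the leading eigenvector and the Gibbs distribution, and an irreducibility
#' verdict.
#'
#' @param tm A [transition_matrix()] result.
#' @param target Optional [exact_distribution()] at the same (m, alpha,
#'   beta); computed when omitted.
#' @return An object of class `chain_diagnostics`.
#' @export
spectral_diagnostics <- function(tm, target = NULL) {
  stopifnot(inherits(tm, "chain_matrix"))
  if (is.null(target)) {
    target <- exact_distribution(tm$m, tm$alpha, tm$beta,
                                 cap = max(10L, tm$m))
  }
  stopifnot(identical(target$states, tm$states))
  ev <- sort(Mod(eigen(tm$P, only.values = TRUE)$values), decreasing = TRUE)
  lambda1 <- if (length(ev) >= 2L) ev[2L] else 0
  irr <- is_strongly_connected(tm$P > 0)
  stat <- if (irr) stationary_from_matrix(tm) else NULL
  structure(list(
    m = tm$m, alpha = tm$alpha, beta = tm$beta,
    n_states = length(tm$states),
    detailed_balance_violation = verify_detailed_balance(tm, target),
    tv_to_target = if (irr) total_variation(stat, target$prob) else NA_real_,
    lambda1 = lambda1,
    spectral_gap = 1 - lambda1,
    irreducible = irr
  ), class = "chain_diagnostics")
}

#' @export
print.chain_diagnostics <- function(x, ...) {
  cat("chain diagnostics (m = ", x$m, ", ", x$n_states, " states, alpha = ",
      x$alpha, ", beta = ", x$beta, ")\n", sep = "")
  cat("  max detailed-balance violation:", format(x$detailed_balance_violation),
      "\n")
  cat("  TV(eigenvector, Gibbs):       ", format(x$tv_to_target), "\n")
  cat("  |lambda_1|:                   ", format(x$lambda1), "\n")
  cat("  spectral gap:                 ", format(x$spectral_gap), "\n")
  cat("  irreducible:                  ", x$irreducible, "\n")
  invisible(x)
}
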