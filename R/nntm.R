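#' NNTM thermodynamic parameter set
#'
#' Bundles the seven aggregate Nearest Neighbor Thermodynamic Model (NNTM)
#' quantities that determine the branching energy of a secondary structure:
#' the multiloop penalty `a`, the penalty `b` per single-stranded nucleotide
#' in a multiloop, the penalty `c` per helix branching from a multiloop, the
#' helix energy `h`, the hairpin energy `f`, the interior-loop energy `i`,
#' and the dangling-end contribution `g`. All values are in kcal/mol.
#'
#' @param a Multiloop penalty (kcal/mol).
#' @param b Penalty per single-stranded nucleotide in a multiloop (kcal/mol).
#' @param c Penalty per branching helix in a multiloop (kcal/mol).
#' @param h Helix energy (kcal/mol).
#' @param f Hairpin energy (kcal/mol).
#' @param i Interior-loop energy (kcal/mol).
#' @param g Dangling-end energy (kcal/mol).
#' @param label Free-text provenance tag.
#' @return An object of class `nntm_params`: a named list with the seven
#'   values and the label.
#' @seealso [nntm_turner()] for the built-in published parameter sets,
#'   [derive_coefficients()] for the reduction to tree-energy coefficients.
#' @examples
#' p <- nntm_params(a = 4.6, b = 0.4, c = 0.1, h = -10.9,
#'                  f = 3.8, i = 3.0, g = -1.6, label = "CG-Turner89")
#' derive_coefficients(p)
#' @export
nntm_params <- function(a, b, c, h, f, i, g, label = "user") {
  vals <- list(a = a, b = b, c = c, h = h, f = f, i = i, g = g)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("NNTM parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  structure(c(lapply(vals, as.numeric), list(label = as.character(label)[1L])),
            class = "nntm_params")
}

#' @export
print.nntm_params <- function(x, ...) {
  cat("NNTM parameter set [", x$label, "] (kcal/mol)\n", sep = "")
  v <- unlist(x[c("a", "b", "c", "h", "f", "i", "g")])
  print(v)
  invisible(x)
}

# Published multiloop/helix/loop aggregates for the two combinatorial
# sequences A^4(Y^5 Z A^4 Y Z^5 A^4)^n with (Y,Z) in {(C,G),(G,C)}, under the
# Turner 1989/1999/2004 rule sets.
.turner_table <- list(
  "CG89" = c(a = 4.6, b = 0.4, c = 0.1,  h = -10.9, f = 3.8, i = 3.0, g = -1.6),
  "GC89" = c(a = 4.6, b = 0.4, c = 0.1,  h = -16.5, f = 3.5, i = 3.0, g = -1.9),
  "CG99" = c(a = 3.4, b = 0.0, c = 0.4,  h = -12.9, f = 4.5, i = 2.3, g = -1.6),
  "GC99" = c(a = 3.4, b = 0.0, c = 0.4,  h = -16.9, f = 4.1, i = 2.3, g = -1.9),
  "CG04" = c(a = 9.3, b = 0.0, c = -0.9, h = -12.9, f = 4.5, i = 2.3, g = -1.1),
  "GC04" = c(a = 9.3, b = 0.0, c = -0.9, h = -16.9, f = 4.1, i = 2.3, g = -1.5)
)

#' Built-in published NNTM parameter sets
#'
#' Returns one of the six built-in NNTM parameter sets for the combinatorial
#' sequences with (Y, Z) = (C, G) or (G, C), under the Turner 1989, 1999 or
#' 2004 thermodynamic rules.
#'
#' @param y,z Bases of the combinatorial sequence, each `"C"` or `"G"`;
#'   only the pairs (C, G) and (G, C) exist.
#' @param turner Turner revision: one of `89`, `99`, `4` or `2004`-style
#'   values `04`/`4`/`2004` (also accepted as strings).
#' @return An [nntm_params()] object.
#' @examples
#' nntm_turner("C", "G", 99)
#' @export
nntm_turner <- function(y, z, turner) {
  y <- toupper(as.character(y)[1L]); z <- toupper(as.character(z)[1L])
  tn <- as.character(turner)[1L]
  tn <- switch(tn, "89" = "89", "1989" = "89", "99" = "99", "1999" = "99",
               "04" = "04", "4" = "04", "2004" = "04", tn)
  key <- paste0(y, z, tn)
  if (!key %in% names(.turner_table)) {
    stop("no built-in NNTM parameter set for (Y=", y, ", Z=", z,
         ", Turner=", tn, "); valid options: (C,G) or (G,C) with Turner ",
         "89, 99 or 04", call. = FALSE)
  }
  v <- .turner_table[[key]]
  nntm_params(v["a"], v["b"], v["c"], v["h"], v["f"], v["i"], v["g"],
              label = paste0(y, z, "-Turner", tn))
}

#' Tree-energy coefficients
#'
#' Container for the reduced coefficients of the plane-tree energy
#' E(t) = alpha d0 + beta d1 + gamma r + delta n, where d0 is the number of
#' leaves (hairpins), d1 the number of internal nodes (interior loops), r the
#' root degree (exterior-loop branching) and n the edge (helix) count.
#'
#' @param alpha Coefficient of the leaf count d0 (kcal/mol).
#' @param beta Coefficient of the internal-node count d1 (kcal/mol).
#' @param gamma Coefficient of the root degree r (kcal/mol).
#' @param delta Per-edge constant (kcal/mol); irrelevant at fixed size.
#' @param label Provenance tag.
#' @return An object of class `energy_coefficients`.
#' @export
energy_coefficients <- function(alpha, beta, gamma = 0, delta = 0,
                                label = "user") {
  vals <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("coefficient '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  structure(c(lapply(vals, as.numeric), list(label = as.character(label)[1L])),
            class = "energy_coefficients")
}

#' @export
print.energy_coefficients <- function(x, ...) {
  cat("Tree energy coefficients [", x$label, "] (kcal/mol)\n", sep = "")
  print(unlist(x[c("alpha", "beta", "gamma", "delta")]))
  invisible(x)
}

#' Reduce NNTM parameters to tree-energy coefficients
#'
#' Collapses the seven NNTM quantities into the four coefficients of the
#' linear tree energy: alpha = f - a - 4b - c - g, beta = i - a - 8b - 2c - 2g,
#' gamma = -4b - c, delta = a + 8b + 2c + h + 2g. Values are carried at full
#' floating precision; published tables round alpha, beta, gamma to one
#' decimal for display only.
#'
#' @param params An [nntm_params()] object.
#' @return An [energy_coefficients()] object.
#' @examples
#' derive_coefficients(nntm_turner("C", "G", 89))  # alpha=-0.9 beta=-1.8
#' @export
derive_coefficients <- function(params) {
  stopifnot(inherits(params, "nntm_params"))
  with(params, energy_coefficients(
    alpha = f - a - 4 * b - c - g,
    beta  = i - a - 8 * b - 2 * c - 2 * g,
    gamma = -4 * b - c,
    delta = a + 8 * b + 2 * c + h + 2 * g,
    label = params$label
  ))
}

#' Read an NNTM parameter set from a text or JSON file
#'
#' Accepts either a JSON object or a plain `key=value` block with the keys
#' `a, b, c, h, f, i, g` (one per line; `#` comments and blank lines are
#' ignored).
#'
#' @param path File path.
#' @param label Provenance tag; defaults to the file name.
#' @return An [nntm_params()] object.
#' @export
read_nntm_params <- function(path, label = basename(path)) {
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  vals <- if (grepl("^\\s*\\{", joined)) {
    as.list(jsonlite::fromJSON(joined))
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed key=value line: '", lines[which(bad)[1L]], "'",
           call. = FALSE)
    }
    setNames(lapply(kv, function(p) as.numeric(trimws(p[2L]))),
             vapply(kv, function(p) trimws(p[1L]), ""))
  }
  need <- c("a", "b", "c", "h", "f", "i", "g")
  miss <- setdiff(need, names(vals))
  if (length(miss)) {
    stop("parameter file is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nntm_params(vals$a, vals$b, vals$c, vals$h, vals$f, vals$i, vals$g,
              label = label)
}

#' Energy of a plane tree
#'
#' Evaluates the branching energy alpha*d0 + beta*d1, optionally adding the
#' exterior-loop term gamma*r and the size term delta*n. With both optional
#' terms off this is the energy the sampler targets: at fixed size the delta
#' term is constant and the exterior-loop contribution is disregarded as
#' small relative to the total.
#'
#' @param tree A [plane_tree] object.
#' @param coeffs An [energy_coefficients()] object.
#' @param include_root_term Add gamma times the root degree.
#' @param include_delta_term Add delta times the edge count.
#' @return Energy in kcal/mol.
#' @export
tree_energy <- function(tree, coeffs, include_root_term = FALSE,
                        include_delta_term = FALSE) {
  stopifnot(inherits(coeffs, "energy_coefficients"))
  ds <- degree_summary(tree)
  e <- coeffs$alpha * ds$d0 + coeffs$beta * ds$d1
  if (include_root_term) e <- e + coeffs$gamma * ds$r
  if (include_delta_term) e <- e + coeffs$delta * ds$n
  e
}

#' Full NNTM structure energy from a down-degree sequence
#'
#' Direct evaluation of the un-reduced NNTM branching energy
#' d0*f + d1*i + sum_{j>=2} d_j (a + 4b(j+1) + c(j+1) + g(j+1)) + n*h + g*r.
#' This is the quantity the coefficient reduction linearises; the two routes
#' agree exactly for every plane tree.
#'
#' @param down_degree_counts Numeric vector: element `j+1` is the number of
#'   non-root nodes with down degree `j` (d0, d1, d2, ...).
#' @param root_degree Root child count r.
#' @param n Edge count.
#' @param params An [nntm_params()] object.
#' @return Energy in kcal/mol.
#' @export
full_structure_energy <- function(down_degree_counts, root_degree, n, params) {
  stopifnot(inherits(params, "nntm_params"))
  d <- as.numeric(down_degree_counts)
  r <- as.numeric(root_degree)
  n <- as.numeric(n)
  if (any(d < 0) || any(d != round(d))) {
    stop("down-degree counts must be nonnegative integers", call. = FALSE)
  }
  j <- seq_along(d) - 1
  if (!isTRUE(all.equal(sum(d), n))) {
    stop("degree identity violated: sum(d_k) must equal n (edge count)",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(sum(j * d), n - r))) {
    stop("degree identity violated: sum(k * d_k) must equal n - r",
         call. = FALSE)
  }
  d0 <- if (length(d) >= 1) d[1L] else 0
  d1 <- if (length(d) >= 2) d[2L] else 0
  multi <- 0
  if (length(d) >= 3) {
    jj <- j[-(1:2)]
    dj <- d[-(1:2)]
    multi <- sum(dj * (params$a + 4 * params$b * (jj + 1) +
                         params$c * (jj + 1) + params$g * (jj + 1)))
  }
  d0 * params$f + d1 * params$i + multi + n * params$h + params$g * r
}

#' Energy of a 2-Motzkin path
#'
#' Evaluates the path form of the branching energy,
#' E(x) = alpha (|x|_U + |x|_H + 1) + beta |x|_I. Under the tree/path
#' bijection the up and uncoloured-horizontal steps plus one count the
#' hairpins and the coloured-horizontal steps count the interior loops, so
#' this agrees exactly with [tree_energy()] (both optional terms off) on the
#' corresponding tree.
#'
#' @param path A 2-Motzkin path string over `U`, `H`, `I`, `D` (the empty
#'   string is the length-0 path).
#' @param coeffs An [energy_coefficients()] object.
#' @return Energy in kcal/mol.
#' @export
path_energy <- function(path, coeffs) {
  stopifnot(inherits(coeffs, "energy_coefficients"))
  assert_valid_path(path)
  cnt <- path_counts(path)
  coeffs$alpha * (cnt[["U"]] + cnt[["H"]] + 1) + coeffs$beta * cnt[["I"]]
}
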