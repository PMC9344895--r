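#' Validate a 2-Motzkin path string
#'
#' A 2-Motzkin path of length m is a string over the alphabet `U` (up), `H`
#' and `I` (the two colours of horizontal step) and `D` (down) in which the
#' number of `D`s never exceeds the number of `U`s in any prefix and the
#' total counts of `U` and `D` agree — a lattice path from (0,0) to (m,0)
#' that never dips below the axis. The empty string is the (single) valid
#' path of length 0.
#'
#' @param path A single string over `U`, `H`, `I`, `D`.
#' @return `TRUE` or `FALSE`. Characters outside the alphabet are an error
#'   (the message names the first offending position).
#' @examples
#' validate_path("UHID")  # TRUE
#' validate_path("DU")    # FALSE: prefix dips below the axis
#' @export
validate_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, !is.na(path))
  if (!nzchar(path)) return(TRUE)
  sym <- strsplit(path, "", fixed = TRUE)[[1L]]
  foreign <- which(!sym %in% c("U", "H", "I", "D"))
  if (length(foreign)) {
    stop("invalid symbol '", sym[foreign[1L]], "' at position ", foreign[1L],
         ": alphabet is {U, H, I, D}", call. = FALSE)
  }
  h <- cumsum((sym == "U") - (sym == "D"))
  all(h >= 0L) && h[length(h)] == 0L
}

assert_valid_path <- function(path) {
  if (!validate_path(path)) {
    stop("'", path, "' is not a valid 2-Motzkin path (a prefix has more Ds ",
         "than Us, or total U and D counts differ)", call. = FALSE)
  }
  invisible(path)
}

#' Symbol counts of a path
#'
#' @param path A path string (not validated here beyond the alphabet).
#' @return Named integer vector with counts of `U`, `H`, `I`, `D`.
#' @export
path_counts <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  sym <- strsplit(path, "", fixed = TRUE)[[1L]]
  c(U = sum(sym == "U"), H = sum(sym == "H"),
    I = sum(sym == "I"), D = sum(sym == "D"))
}

#' Skeleton of a 2-Motzkin path
#'
#' The Dyck path of `U` and `D` steps left after deleting every horizontal
#' step. Always a valid Dyck path; the identity on Dyck-path inputs.
#'
#' @param path A valid 2-Motzkin path string.
#' @return A string over `U`, `D` (possibly empty).
#' @examples
#' skeleton("UHIDH")  # "UD"
#' @export
skeleton <- function(path) {
  assert_valid_path(path)
  gsub("[HI]", "", path)
}

#' Enumerate all 2-Motzkin paths of a given length
#'
#' Exhaustive, duplicate-free generation by depth-first extension with prefix
#' pruning (a partial string is extended only while its height stays
#' nonnegative and can still return to zero). The result is in lexicographic
#' order (D < H < I < U) and has exactly `catalan(m + 1)` elements, the
#' number of plane trees with m + 1 edges.
#'
#' @param m Path length (nonnegative integer).
#' @param cap Guard on m; enumeration is exponential in m.
#' @return Character vector of all valid paths of length `m`.
#' @examples
#' enumerate_paths(2)  # "HH" "HI" "IH" "II" "UD"
#' @export
enumerate_paths <- function(m, cap = 10L) {
  m <- as.integer(m)
  stopifnot(length(m) == 1L, m >= 0L)
  if (m > cap) {
    stop("enumeration of length-", m, " paths exceeds the cap (", cap,
         "); raise `cap` explicitly if you really want catalan(", m + 1,
         ") strings", call. = FALSE)
  }
  if (m == 0L) return("")
  out <- character(0)
  # iterative DFS over (prefix, height); alphabet in lexicographic order
  recurse <- function(prefix, height, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    if (height > 0L && height <= left) recurse(paste0(prefix, "D"), height - 1L, left - 1L)
    if (height <= left - 1L) {
      recurse(paste0(prefix, "H"), height, left - 1L)
      recurse(paste0(prefix, "I"), height, left - 1L)
    }
    if (height + 1L <= left - 1L) recurse(paste0(prefix, "U"), height + 1L, left - 1L)
    invisible(NULL)
  }
  recurse("", 0L, m)
  out
}

# Largest n for which catalan(n) is still an exact double (< 2^53).
.catalan_cap <- 30L

#' Catalan and Motzkin numbers
#'
#' `catalan_number(n)` is the number of plane trees with n edges (equally,
#' Dyck paths of length 2n), computed by the convolution recurrence
#' C_0 = 1, C_{j} = sum_i C_i C_{j-1-i}, in which every intermediate is an
#' integer, so the arithmetic is exact. `motzkin_number(n)` counts
#' single-coloured Motzkin paths of length n via the binomial sum
#' M_n = sum_k choose(n, 2k) C_k. Both are exact; n is capped where the
#' values would exceed the exact-integer range of a double (2^53).
#'
#' @param n Nonnegative integer.
#' @return Exact count as a numeric scalar.
#' @examples
#' catalan_number(4)  # 14
#' motzkin_number(3)  # 4
#' @export
catalan_number <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L)
  if (n < 0L) stop("n must be nonnegative", call. = FALSE)
  if (n > .catalan_cap) {
    stop("catalan_number is exact only for n <= ", .catalan_cap, call. = FALSE)
  }
  cc <- numeric(n + 1L)
  cc[1L] <- 1
  if (n >= 1L) {
    for (j in 1:n) cc[j + 1L] <- sum(cc[1:j] * cc[j:1])
  }
  cc[n + 1L]
}

#' @rdname catalan_number
#' @export
motzkin_number <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L)
  if (n < 0L) stop("n must be nonnegative", call. = FALSE)
  if (n > .catalan_cap) {
    stop("motzkin_number is exact only for n <= ", .catalan_cap, call. = FALSE)
  }
  k <- 0:(n %/% 2)
  sum(choose(n, 2 * k) * vapply(k, catalan_number, numeric(1)))
}
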