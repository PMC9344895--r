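#' Plane trees
#'
#' A plane tree is a rooted tree in which each node's children are ordered.
#' Here it abstracts the branching pattern of an RNA secondary structure:
#' edges are helices, leaves are hairpins, non-root nodes with one child are
#' interior loops, nodes with two or more children are multiloops, and the
#' root is the exterior loop.
#'
#' Internally a tree is a list of child-id vectors indexed by node id, with
#' node 1 as the root. Trees serialise to balanced-parenthesis strings (the
#' child subtrees concatenated left-to-right inside the parent's
#' parentheses, with the root's own parentheses omitted), one pair per edge.
#'
#' @param children List of integer vectors; `children[[i]]` are the child
#'   node ids of node `i` in left-to-right order. Node 1 is the root.
#' @return An object of class `plane_tree`.
#' @seealso [parse_tree()], [tree_to_path()], [path_to_tree()],
#'   [degree_summary()]
#' @export
plane_tree <- function(children) {
  stopifnot(is.list(children), length(children) >= 2L)
  nn <- length(children)
  kids <- unlist(lapply(children, as.integer), use.names = FALSE)
  if (length(kids) != nn - 1L || anyDuplicated(kids) ||
      any(kids < 2L) || any(kids > nn) || 1L %in% kids) {
    stop("malformed plane tree: every node except the root (node 1) must ",
         "appear exactly once as a child", call. = FALSE)
  }
  tree <- structure(list(children = lapply(children, as.integer)),
                    class = "plane_tree")
  # reachability from the root rules out detached cycles
  if (length(preorder_nodes(tree)) != nn) {
    stop("malformed plane tree: not all nodes reachable from the root",
         call. = FALSE)
  }
  tree
}

# Node ids in preorder (root first, children left-to-right), iteratively so
# deep chains cannot exhaust the call stack.
preorder_nodes <- function(tree) {
  children <- tree$children
  order <- integer(0)
  st <- 1L
  while (length(st)) {
    v <- st[length(st)]
    st <- st[-length(st)]
    order <- c(order, v)
    kids <- children[[v]]
    if (length(kids)) st <- c(st, rev(kids))
  }
  order
}

#' @export
format.plane_tree <- function(x, ...) {
  children <- x$children
  buf <- character(0)
  st <- rev(children[[1L]])
  while (length(st)) {
    top <- st[length(st)]
    st <- st[-length(st)]
    if (top == 0L) {
      buf <- c(buf, ")")
    } else {
      buf <- c(buf, "(")
      st <- c(st, 0L, rev(children[[top]]))
    }
  }
  paste(buf, collapse = "")
}

#' @export
print.plane_tree <- function(x, ...) {
  ds <- degree_summary(x)
  cat("plane tree: ", ds$n, " edges, ", ds$d0, " leaves, ", ds$d1,
      " internal nodes, root degree ", ds$r, "\n", sep = "")
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.plane_tree <- function(x, ...) format(x)

#' Parse a balanced-parenthesis tree string
#'
#' Inverse of `format()` on [plane_tree] objects: each `(`...`)` pair is an
#' edge, subtrees are concatenated left-to-right, and the root's parentheses
#' are omitted (so a tree with n edges is a string of n balanced pairs).
#'
#' @param s String of balanced parentheses; must contain at least one pair.
#' @return A [plane_tree].
#' @examples
#' parse_tree("(()())")  # root -> v, v -> two leaves
#' @export
parse_tree <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  sym <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!length(sym)) stop("empty tree string: a plane tree has >= 1 edge",
                         call. = FALSE)
  bad <- which(!sym %in% c("(", ")"))
  if (length(bad)) {
    stop("unexpected character '", sym[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  children <- list(integer(0))
  stack <- 1L
  for (ch in sym) {
    if (ch == "(") {
      id <- length(children) + 1L
      children[[id]] <- integer(0)
      parent <- stack[length(stack)]
      children[[parent]] <- c(children[[parent]], id)
      stack <- c(stack, id)
    } else {
      if (length(stack) == 1L) {
        stop("unbalanced parentheses: unexpected ')'", call. = FALSE)
      }
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) != 1L) {
    stop("unbalanced parentheses: ", length(stack) - 1L, " unclosed '('",
         call. = FALSE)
  }
  plane_tree(children)
}

#' Degree summary of a plane tree
#'
#' Single-traversal branching census: edge count n, leaf (hairpin) count d0,
#' internal-node (interior-loop) count d1, root degree r, the full
#' down-degree counts d_j over non-root nodes, and the maximum non-root down
#' degree. Satisfies the identities sum_k d_k = n and sum_k k d_k = n - r.
#'
#' @param tree A [plane_tree].
#' @return List with elements `n`, `d0`, `d1`, `r`, `d_counts` (vector of
#'   d_0..d_max) and `max_down_degree`.
#' @export
degree_summary <- function(tree) {
  stopifnot(inherits(tree, "plane_tree"))
  deg <- lengths(tree$children)
  nonroot <- deg[-1L]
  maxd <- if (length(nonroot)) max(nonroot) else 0L
  d_counts <- tabulate(nonroot + 1L, nbins = maxd + 1L)
  names(d_counts) <- paste0("d", 0:maxd)
  list(n = length(deg) - 1L,
       d0 = sum(nonroot == 0L),
       d1 = sum(nonroot == 1L),
       r = deg[1L],
       d_counts = d_counts,
       max_down_degree = maxd)
}

#' Plane tree to 2-Motzkin path (the Deutsch bijection)
#'
#' Labels each edge by the rules: the leftmost edge off a non-root node of
#' down degree >= 2 gets `U`, the rightmost gets `D`; the only edge off a
#' non-root node of down degree 1 gets `I`; every other edge (edges off the
#' root, and middle edges) gets `H`. Reading the labels in preorder always
#' starts with `H`; that initial `H` is dropped, giving a 2-Motzkin path of
#' length n - 1. The path transports the branching statistics:
#' `|x|_I = d1(t)` and `|x|_U + |x|_H + 1 = d0(t)`.
#'
#' @param tree A [plane_tree] with n >= 1 edges.
#' @return A valid 2-Motzkin path string of length n - 1 (empty for the
#'   single-edge tree).
#' @examples
#' tree_to_path(parse_tree("(()())"))  # "UD"
#' @export
tree_to_path <- function(tree) {
  stopifnot(inherits(tree, "plane_tree"))
  children <- tree$children
  nn <- length(children)
  lab <- character(nn)
  for (p in seq_len(nn)) {
    kids <- children[[p]]
    k <- length(kids)
    if (k == 0L) next
    if (p == 1L) {
      lab[kids] <- "H"
    } else if (k == 1L) {
      lab[kids] <- "I"
    } else {
      lab[kids] <- "H"
      lab[kids[1L]] <- "U"
      lab[kids[k]] <- "D"
    }
  }
  ord <- preorder_nodes(tree)[-1L]  # non-root nodes in preorder
  seq <- lab[ord]
  if (seq[1L] != "H") stop("internal error: preorder labels must start with H")
  paste(seq[-1L], collapse = "")
}

#' 2-Motzkin path to plane tree (inverse bijection)
#'
#' Rebuilds the plane tree from its path: walking the path left to right, a
#' pointer `u` marks where `H`/`D` attach a node, `v` is the last node added,
#' and a stack restores `u` when a `D` closes the branch a `U` opened. The
#' root's first child is pre-seeded, so the empty path maps to the
#' single-edge tree and a length-m path to a tree with m + 1 edges.
#'
#' @param path A valid 2-Motzkin path string.
#' @return A [plane_tree] with `nchar(path) + 1` edges.
#' @examples
#' format(path_to_tree("UD"))  # "(()())"
#' @export
path_to_tree <- function(path) {
  assert_valid_path(path)
  m <- nchar(path)
  sym <- if (m) strsplit(path, "", fixed = TRUE)[[1L]] else character(0)
  children <- rep(list(integer(0)), m + 2L)
  u <- 1L            # attachment point for H and D
  v <- 2L            # last node added
  children[[1L]] <- 2L
  stack <- integer(0)
  for (i in seq_len(m)) {
    node <- i + 2L
    s <- sym[i]
    if (s == "U") {
      children[[v]] <- c(children[[v]], node)
      stack <- c(stack, u)
      u <- v
    } else if (s == "I") {
      children[[v]] <- c(children[[v]], node)
    } else if (s == "H") {
      children[[u]] <- c(children[[u]], node)
    } else {  # D
      children[[u]] <- c(children[[u]], node)
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
    v <- node
  }
  plane_tree(children)
}

#' Enumerate all plane trees with n edges
#'
#' All `catalan(n)` plane trees, obtained by enumerating 2-Motzkin paths of
#' length n - 1 and inverting the bijection.
#'
#' @param n Edge count (>= 1).
#' @param cap Passed to [enumerate_paths()].
#' @return List of [plane_tree] objects.
#' @export
enumerate_trees <- function(n, cap = 10L) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  lapply(enumerate_paths(n - 1L, cap = cap - 1L), path_to_tree)
}

#' Newick export
#'
#' Serialises a plane tree as an unlabelled Newick string for use with
#' standard tree viewers and packages such as ape. Child order is preserved.
#'
#' @param tree A [plane_tree].
#' @return A Newick string terminated by `;`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "plane_tree"))
  children <- tree$children
  # assemble bottom-up over reverse preorder so chains cannot overflow a stack
  ord <- preorder_nodes(tree)
  repr <- character(length(children))
  for (v in rev(ord)) {
    kids <- children[[v]]
    repr[v] <- if (length(kids)) {
      paste0("(", paste(repr[kids], collapse = ","), ")")
    } else {
      ""
    }
  }
  paste0(repr[1L], ";")
}
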