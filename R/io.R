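# Plain-text interchange: one 2-Motzkin path string per line for path files,
# one balanced-parenthesis string per line for tree files.

#' Read and write path and tree files
#'
#' Path files hold one `{U,H,I,D}` string per line; tree files hold one
#' balanced-parenthesis plane-tree string per line. Readers validate every
#' line and report the first offending line number.
#'
#' @param path File path.
#' @param paths Character vector of valid 2-Motzkin path strings.
#' @param trees List of [plane_tree] objects.
#' @param newick If `TRUE`, `write_trees` writes Newick strings instead of
#'   parenthesis strings.
#' @return Readers return a character vector of paths or a list of trees;
#'   writers return the file path invisibly.
#' @name path_tree_io
NULL

#' @rdname path_tree_io
#' @export
read_paths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    ok <- tryCatch(validate_path(lines[k]), error = function(e) FALSE)
    if (!isTRUE(ok)) {
      stop("invalid 2-Motzkin path on line ", k, " of '", path, "': '",
           lines[k], "'", call. = FALSE)
    }
  }
  lines
}

#' @rdname path_tree_io
#' @export
write_paths <- function(paths, path) {
  writeLines(paths, path)
  invisible(path)
}

#' @rdname path_tree_io
#' @export
read_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    out[[k]] <- tryCatch(parse_tree(lines[k]), error = function(e) {
      stop("invalid tree on line ", k, " of '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  out
}

#' @rdname path_tree_io
#' @export
write_trees <- function(trees, path, newick = FALSE) {
  lines <- vapply(trees,
                  if (newick) as_newick else function(t) format(t),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
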