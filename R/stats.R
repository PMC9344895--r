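#' Branching statistics of a plane tree
#'
#' Computes the branching properties of interest for an RNA secondary
#' structure abstracted as a plane tree: the number of hairpins (leaves,
#' d0), the number of interior loops (internal nodes, d1), the exterior-loop
#' branching (root degree r), the maximum multiloop branching (maximum down
#' degree over non-root nodes), the number of multiloops (non-root nodes
#' with down degree >= 2), the height (maximum root-to-leaf edge count) and
#' the diameter (longest path between any two nodes, in edges; with each
#' edge a helix this is the tree-level analogue of a maximum ladder
#' distance). The root is excluded from the multiloop counts because it
#' models the exterior loop, not a multiloop. Always
#' `hairpins + internal_nodes + multiloop_count == n` (the non-root nodes).
#'
#' @param tree A [plane_tree].
#' @return Named list with `n`, `hairpins`, `internal_nodes`, `root_degree`,
#'   `max_down_degree`, `multiloop_count`, `height`, `diameter`.
#' @examples
#' tree_statistics(parse_tree("()()()()"))  # star: 4 hairpins, height 1
#' @export
tree_statistics <- function(tree) {
  stopifnot(inherits(tree, "plane_tree"))
  children <- tree$children
  deg <- lengths(children)
  nonroot <- deg[-1L]
  ord <- preorder_nodes(tree)
  # subtree heights bottom-up: in reverse preorder every child precedes its
  # parent
  ht <- integer(length(children))
  diam <- 0L
  for (v in rev(ord)) {
    kids <- children[[v]]
    if (length(kids)) {
      reach <- ht[kids] + 1L  # deepest descent through each child
      top <- sort(reach, decreasing = TRUE)
      ht[v] <- top[1L]
      through <- if (length(top) >= 2L) top[1L] + top[2L] else top[1L]
      if (through > diam) diam <- through
    }
  }
  list(n = length(deg) - 1L,
       hairpins = sum(nonroot == 0L),
       internal_nodes = sum(nonroot == 1L),
       root_degree = deg[[1L]],
       max_down_degree = if (length(nonroot)) max(nonroot) else 0L,
       multiloop_count = sum(nonroot >= 2L),
       height = ht[1L],
       diameter = diam)
}

#' Dispersion summary of branching statistics
#'
#' Per-statistic mean, unbiased variance, standard deviation and
#' nearest-rank quantiles (2.5, 25, 50, 75, 97.5 percent) over a set of
#' sampled trees. Nearest-rank quantiles avoid interpolation ambiguity on
#' integer statistics.
#'
#' @param records A data frame of statistic values (one row per tree, e.g.
#'   rows of [tree_statistics()] output), or a list of such records.
#' @return An object of class `dispersion_summary`: a data frame with one
#'   row per statistic and columns `mean`, `variance`, `sd`, `q2.5`, `q25`,
#'   `median`, `q75`, `q97.5`, plus attribute `n_samples`.
#' @export
summarize_dispersion <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) {
    stop("need at least 2 samples to summarise dispersion", call. = FALSE)
  }
  num <- records[vapply(records, is.numeric, TRUE)]
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  rows <- lapply(names(num), function(nm) {
    v <- num[[nm]]
    srt <- sort(v)
    ranks <- pmax(1L, ceiling(qs * length(v)))
    data.frame(statistic = nm, mean = mean(v), variance = var(v),
               sd = sd(v),
               q2.5 = srt[ranks[1L]], q25 = srt[ranks[2L]],
               median = srt[ranks[3L]], q75 = srt[ranks[4L]],
               q97.5 = srt[ranks[5L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_samples") <- nrow(records)
  class(out) <- c("dispersion_summary", "data.frame")
  out
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat("branching-statistic dispersion over", attr(x, "n_samples"),
      "samples\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Place an observed statistic within a sampled dispersion
#'
#' Reports where an observed branching-statistic value falls within the
#' sampled null dispersion: the percentile rank (fraction of samples at or
#' below the observation, with the midpoint convention for ties) and the
#' z-score (observed minus sample mean, over sample standard deviation).
#' This is the decision quantity for asking whether a predicted structure's
#' branching is within the expected dispersion of the energy model — e.g.
#' whether its hairpin count is more than 2-3 standard deviations from the
#' model mean.
#'
#' @param observed Observed value (single number).
#' @param samples Numeric vector of sampled values (length >= 2).
#' @return An object of class `placement`: list with `observed`,
#'   `percentile`, `z` (`NA` with a note when the sample variance is zero),
#'   `mean`, `sd`, `n`.
#' @export
placement <- function(observed, samples) {
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.numeric(samples))
  if (length(samples) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  n <- length(samples)
  pct <- (sum(samples < observed) + 0.5 * sum(samples == observed)) / n
  s <- sd(samples)
  z <- if (s > 0) (observed - mean(samples)) / s else NA_real_
  structure(list(observed = observed, percentile = pct, z = z,
                 mean = mean(samples), sd = s, n = n,
                 note = if (s == 0) "zero-variance sample: z undefined"),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf(
    "observed %g: percentile %.4f, z = %s (sample mean %.4g, sd %.4g, n = %d)\n",
    x$observed, x$percentile,
    if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z),
    x$mean, x$sd, x$n))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
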