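#' Threshold the affinity bipartite graph
#'
#' Keeps the complex-cluster pairs whose neighborhood affinity is at
#' least `theta` and which share at least one protein (pairs with
#' `t[i,j] == 0` are never edges, even at `theta = 0`, so the low end
#' of a threshold sweep is not inflated by vacuous matches).
#'
#' @param table an [build_overlap()] table.
#' @param theta affinity threshold in \[0, 1\].
#' @return an object of class `threshold_graph`: list with `theta` and
#'   `edges`, a data.frame of columns `i` (complex index), `j` (cluster
#'   index) and `weight` (the affinity).
#' @export
threshold_graph <- function(table, theta = 0.25) {
  stopifnot(inherits(table, "overlap_table"))
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must be a single value in [0, 1]")
  keep <- which(table$na >= theta & table$t > 0, arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2],
                      weight = table$na[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(theta = theta, edges = edges), class = "threshold_graph")
}

# internal: run igraph bipartite matching on an edge frame.
# weights = NULL -> maximum cardinality; otherwise maximum total weight
# over *all* matchings (edge weights here are positive, so the optimum
# is automatically a maximal matching).
bipartite_match <- function(edges, n, m, weights = NULL) {
  if (nrow(edges) == 0L)
    return(list(pairs = cbind(i = integer(0), j = integer(0)), weight = 0))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(rbind(edges$i, n + edges$j))
  )
  res <- igraph::max_bipartite_match(g, weights = weights)
  mi <- res$matching[seq_len(n)]
  matched <- which(!is.na(mi))
  pairs <- cbind(i = matched, j = as.integer(mi[matched]) - n)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  list(pairs = pairs, weight = res$matching_weight)
}

#' Maximal matching ratio (MMR)
#'
#' Builds the affinity-thresholded bipartite graph, finds a
#' maximum-weight matching between complexes and clusters, and
#' normalises the matched weight by the number of reference complexes:
#' a one-to-one quality score in \[0, 1\]. The value is deterministic
#' even when several optimal pairings exist.
#'
#' @inheritParams threshold_graph
#' @return a scalar in \[0, 1\].
#' @examples
#' gs <- gold_standard(list(c("a","b","c","d"), c("d","e","f")))
#' cs <- cluster_set(list(c("a","b","c"), c("e","f","g"), c("x","y")))
#' mmr(build_overlap(gs, cs), theta = 0.25)  # (0.75 + 4/9) / 2
#' @export
mmr <- function(table, theta = 0.25) {
  tg <- threshold_graph(table, theta)
  if (nrow(tg$edges) == 0L) return(0)
  bm <- bipartite_match(tg$edges, nrow(table$t), ncol(table$t),
                        weights = tg$edges$weight)
  bm$weight / nrow(table$t)
}

#' Threshold Precision, Recall and F-measure
#'
#' Counts the complexes that have at least one cluster with affinity
#' `>= theta` (N_p) and the clusters with at least one such complex
#' (N_c); Precision = N_p / n, Recall = N_c / m. The naming follows
#' the convention of this literature, where "Precision" is a fraction
#' of *complexes* and "Recall" a fraction of *clusters* — swapped
#' relative to common machine-learning usage.
#'
#' @inheritParams threshold_graph
#' @return named numeric vector `c(precision=, recall=, f=)`.
#' @export
pr_metrics <- function(table, theta = 0.25) {
  tg <- threshold_graph(table, theta)
  prec <- length(unique(tg$edges$i)) / nrow(table$t)
  rec <- length(unique(tg$edges$j)) / ncol(table$t)
  c(precision = prec, recall = rec, f = harmonic_mean(prec, rec))
}

#' One-to-one matching between complexes and clusters
#'
#' Maximum-cardinality matching on the unweighted thresholded graph.
#' The cardinality is unique; among maximum-cardinality matchings the
#' reported pairing is the one of maximum total affinity, so the pair
#' list is reproducible for downstream inspection.
#'
#' @inheritParams threshold_graph
#' @return an object of class `match_result`: list with `pairs` (two
#'   column matrix of complex/cluster indices, sorted by complex),
#'   `cardinality`, `total_weight` (summed affinity of the pairs),
#'   `n_p_plus` and `n_c_plus` (both equal to the cardinality).
#' @export
match_set <- function(table, theta = 0.25) {
  tg <- threshold_graph(table, theta)
  n <- nrow(table$t); m <- ncol(table$t)
  if (nrow(tg$edges) == 0L) {
    bm <- list(pairs = cbind(i = integer(0), j = integer(0)))
  } else {
    # cardinality dominates: any extra edge outweighs any affinity sum
    big <- min(n, m) + 1
    bm <- bipartite_match(tg$edges, n, m, weights = big + tg$edges$weight)
  }
  w <- if (nrow(bm$pairs)) {
    sum(table$na[bm$pairs])
  } else 0
  structure(
    list(pairs = bm$pairs, cardinality = nrow(bm$pairs), total_weight = w,
         n_p_plus = nrow(bm$pairs), n_c_plus = nrow(bm$pairs),
         theta = tg$theta),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<one-to-one match at theta = %g: %d pairs, total affinity %.4f>\n",
              x$theta, x$cardinality, x$total_weight))
  invisible(x)
}

#' Matching-based Precision+, Recall+ and F-measure+
#'
#' The one-to-one refinement of the threshold Precision/Recall family:
#' a complex (cluster) only counts if it participates in a
#' maximum-cardinality matching, so redundant near-copies of a cluster
#' cannot all be validated by the same complex. Precision+ = |Match|/n,
#' Recall+ = |Match|/m, F-measure+ their harmonic mean.
#'
#' @inheritParams threshold_graph
#' @return named numeric vector `c(precision_plus=, recall_plus=, f_plus=)`.
#' @export
plus_metrics <- function(table, theta = 0.25) {
  ms <- match_set(table, theta)
  prec <- ms$n_p_plus / nrow(table$t)
  rec <- ms$n_c_plus / ncol(table$t)
  c(precision_plus = prec, recall_plus = rec,
    f_plus = harmonic_mean(prec, rec))
}

#' Composite MMR + F-measure+ criterion
#'
#' The sum of the maximal matching ratio and F-measure+, combining a
#' qualitative (matched affinity) and a quantitative (matched counts)
#' view of the one-to-one correspondence between detected clusters and
#' reference complexes. Ranges over \[0, 2\] and attains 2 exactly when
#' the detected clusters coincide with a gold standard whose complexes
#' all pass the threshold against themselves.
#'
#' @inheritParams threshold_graph
#' @return a scalar in \[0, 2\].
#' @export
composite_mmr_fplus <- function(table, theta = 0.25) {
  unname(mmr(table, theta) + plus_metrics(table, theta)["f_plus"])
}
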