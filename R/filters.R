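#' Filter clusters by size
#'
#' Keeps the clusters with `min_size <= |C| <= max_size`, preserving
#' order. Mirrors the minimum/maximum cluster-size option of complex
#' evaluation servers.
#'
#' @param clusters a [cluster_set()].
#' @param min_size minimum cluster size (>= 1).
#' @param max_size maximum cluster size (may be `Inf`).
#' @return a [cluster_set()] (possibly with zero clusters).
#' @export
filter_size <- function(clusters, min_size = 1L, max_size = Inf) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (min_size < 1L || min_size > max_size)
    stop("need 1 <= min_size <= max_size")
  keep <- lengths(clusters$clusters) >= min_size &
    lengths(clusters$clusters) <= max_size
  res <- clusters
  res$clusters <- clusters$clusters[keep]
  res$m <- sum(keep)
  if (inherits(res, "gold_standard")) res$n <- res$m
  res
}

#' Find the clusters of each method containing a query protein
#'
#' Exact string match on the protein ID; a protein absent everywhere
#' yields empty lists, not an error.
#'
#' @param cluster_sets list of [cluster_set()] objects (one per method).
#' @param protein the protein ID to look up.
#' @return named list (one entry per method, named by its label) of
#'   lists of clusters containing the protein, in original order.
#' @export
filter_protein <- function(cluster_sets, protein) {
  stopifnot(is.list(cluster_sets), is.character(protein),
            length(protein) == 1L)
  res <- lapply(cluster_sets, function(cs) {
    stopifnot(inherits(cs, "cluster_set"))
    Filter(function(cl) protein %in% cl, cs$clusters)
  })
  names(res) <- vapply(cluster_sets, `[[`, character(1), "name")
  res
}

#' Filter a method's clusters by cross-method reliability
#'
#' Keeps a cluster of `target` when at least `beta` methods — the
#' target itself plus the panel — contain a similar cluster, similarity
#' meaning Jaccard index strictly above `phi`. The target method always
#' counts for its own clusters (a cluster matches itself whenever
#' `phi < 1`), so `beta = 1` is the identity filter.
#'
#' @param target the [cluster_set()] to filter.
#' @param panel list of [cluster_set()] objects from other methods.
#' @param beta minimum number of supporting methods (>= 1).
#' @param phi Jaccard similarity threshold; default 0.5.
#' @return a [cluster_set()] with the supported clusters, in order.
#'   `beta` larger than the number of available methods yields an empty
#'   result with a warning.
#' @export
filter_reliability <- function(target, panel, beta = 2L, phi = 0.5) {
  stopifnot(inherits(target, "cluster_set"), is.list(panel), beta >= 1L,
            phi >= 0, phi <= 1)
  methods <- c(list(target), panel)
  if (beta > length(methods)) {
    warning(sprintf(
      "beta = %d exceeds the %d available methods; no cluster can qualify",
      beta, length(methods)))
    res <- target
    res$clusters <- list()
    res$m <- 0L
    return(res)
  }
  supported <- vapply(target$clusters, function(cl) {
    votes <- vapply(methods, function(ms) {
      any(vapply(ms$clusters, function(other) jcc_score(cl, other) > phi,
                 logical(1)))
    }, logical(1))
    sum(votes) >= beta
  }, logical(1))
  res <- target
  res$clusters <- target$clusters[supported]
  res$m <- sum(supported)
  res
}
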