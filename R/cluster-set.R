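#' Construct a set of detected clusters
#'
#' A `cluster_set` is the canonical container for the output of one
#' complex-detection method: an ordered list of protein-ID sets, each
#' attributed to the method named by `name`. Protein IDs are opaque,
#' case-sensitive strings; duplicate IDs inside one cluster are collapsed.
#'
#' @param clusters list of character vectors, one per cluster; every
#'   cluster must contain at least one protein ID.
#' @param name label of the method that produced the clusters.
#' @return an object of class `cluster_set` with elements `name`,
#'   `clusters` (list of character vectors) and `m` (cluster count).
#' @examples
#' cs <- cluster_set(list(c("A", "B", "C"), c("D", "E")), name = "mcl")
#' length(cs)
#' @export
cluster_set <- function(clusters, name = "clusters") {
  stopifnot(is.list(clusters), is.character(name), length(name) == 1L)
  clusters <- lapply(clusters, function(x) {
    x <- unique(as.character(x))
    if (length(x) == 0L || anyNA(x) || any(!nzchar(x)))
      stop("every cluster must be a non-empty set of protein IDs")
    x
  })
  structure(
    list(name = name, clusters = clusters, m = length(clusters)),
    class = "cluster_set"
  )
}

#' Construct a gold standard of reference complexes
#'
#' A `gold_standard` holds the curated reference complexes a method is
#' scored against. Complexes may overlap: sharing proteins across
#' reference complexes is an intrinsic property of real catalogues and
#' is permitted here.
#'
#' @param complexes list of character vectors, one per reference complex.
#' @param name label of the catalogue (e.g. `"CYC2008"`).
#' @return an object of classes `gold_standard` and `cluster_set`;
#'   element `n` is the number of complexes.
#' @examples
#' gs <- gold_standard(list(c("A", "B", "C", "D"), c("D", "E", "F")))
#' gs$n
#' @export
gold_standard <- function(complexes, name = "gold") {
  gs <- cluster_set(complexes, name = name)
  gs$n <- gs$m
  class(gs) <- c("gold_standard", "cluster_set")
  gs
}

#' @export
length.cluster_set <- function(x) length(x$clusters)

#' @export
print.cluster_set <- function(x, ...) {
  kind <- if (inherits(x, "gold_standard")) "gold standard" else "cluster set"
  sizes <- lengths(x$clusters)
  cat(sprintf("<%s '%s': %d %s, %d distinct proteins>\n",
              kind, x$name, length(sizes),
              if (inherits(x, "gold_standard")) "complexes" else "clusters",
              length(unique(unlist(x$clusters)))))
  if (length(sizes))
    cat(sprintf("  sizes: min %d / median %s / max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
  invisible(x)
}

# shared sanity check used by the metric layer
assert_nonempty_pair <- function(gold, clusters) {
  if (!inherits(gold, "cluster_set") || !inherits(clusters, "cluster_set"))
    stop("expected cluster_set / gold_standard objects")
  if (length(gold) == 0L || length(clusters) == 0L)
    stop("empty evaluation: need at least one complex and one cluster")
  invisible(TRUE)
}
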