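#' Build the k-partite cluster-similarity graph
#'
#' One part per method; every node represents one detected cluster.
#' Two nodes from *different* parts are joined when the Jaccard index
#' of their clusters strictly exceeds `phi`, with the convention that
#' identical clusters (Jaccard 1) always qualify — so `phi = 1` links
#' exactly the identical clusters. No intra-part edges exist, hence every clique
#' has at most one node per method and clique size is at most k.
#'
#' @param cluster_sets list of at least two [cluster_set()] objects.
#' @param phi overlap threshold in \[0, 1\]; default 0.5.
#' @return an object of class `kpartite_graph`: list with `graph`
#'   (an igraph object whose vertices carry `method` and `cluster`
#'   indices), `nodes` (data.frame of the same), and `cluster_sets`.
#' @export
build_kpartite <- function(cluster_sets, phi = 0.5) {
  if (!is.list(cluster_sets) || length(cluster_sets) < 2L)
    stop("integration needs >= 2 methods")
  stopifnot(all(vapply(cluster_sets, inherits, logical(1), "cluster_set")),
            phi >= 0, phi <= 1)
  k <- length(cluster_sets)
  nodes <- data.frame(
    method = rep(seq_len(k), vapply(cluster_sets, length, integer(1))),
    cluster = unlist(lapply(cluster_sets, function(s) seq_along(s$clusters)))
  )
  all_clusters <- unlist(lapply(cluster_sets, `[[`, "clusters"),
                         recursive = FALSE)
  nv <- nrow(nodes)
  from <- to <- integer(0)
  for (u in seq_len(nv)) {
    for (v in seq_len(nv)) {
      if (v <= u || nodes$method[u] == nodes$method[v]) next
      jc <- jcc_score(all_clusters[[u]], all_clusters[[v]])
      if (jc > phi || jc == 1) {  # identical clusters always link, so phi = 1 works
        from <- c(from, u); to <- c(to, v)
      }
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$method <- nodes$method
  igraph::V(g)$cluster <- nodes$cluster
  structure(list(graph = g, nodes = nodes, cluster_sets = cluster_sets,
                 phi = phi),
            class = "kpartite_graph")
}

#' Enumerate consensus cliques
#'
#' All maximal cliques of the k-partite similarity graph whose size
#' strictly exceeds `psi`. Because the graph has no intra-part edges, a
#' clique of size s corresponds to s distinct methods agreeing (up to
#' the overlap threshold) on one cluster.
#'
#' @param kgraph a [build_kpartite()] graph.
#' @param psi strict size cutoff (cliques of size `<= psi` are
#'   discarded); default k/2.
#' @return list of integer vectors of node indices into
#'   `kgraph$nodes`, each sorted, the list ordered lexicographically.
#' @export
consensus_cliques <- function(kgraph, psi = length(kgraph$cluster_sets) / 2) {
  stopifnot(inherits(kgraph, "kpartite_graph"), psi >= 0)
  min_size <- floor(psi) + 1L  # smallest integer strictly greater than psi
  cl <- igraph::max_cliques(kgraph$graph, min = min_size)
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  key <- vapply(cl, function(x) paste(sprintf("%09d", x), collapse = ","),
                character(1))
  cl[order(key)]
}

#' Integrate the results of several methods
#'
#' Cross-method consensus: builds the k-partite similarity graph at
#' overlap threshold `phi`, keeps the maximal cliques larger than
#' `psi`, and emits per clique either the union or the intersection of
#' its member clusters. Exact duplicates among the integrated clusters
#' are collapsed to one, and empty intersections are dropped. With
#' `phi = 1` only identical clusters are linked, so union and
#' intersection coincide.
#'
#' @inheritParams build_kpartite
#' @param psi strict clique-size cutoff; default k/2.
#' @param mode `"union"` or `"intersection"`.
#' @param name label for the integrated set.
#' @return a [cluster_set()] of consensus clusters, with attribute
#'   `"provenance"`: a list (one entry per emitted cluster) of
#'   data.frames naming the method/cluster indices of the clique.
#' @export
integrate_methods <- function(cluster_sets, phi = 0.5,
                              psi = length(cluster_sets) / 2,
                              mode = c("union", "intersection"),
                              name = "integration") {
  mode <- match.arg(mode)
  kg <- build_kpartite(cluster_sets, phi)
  cliques <- consensus_cliques(kg, psi)
  all_clusters <- unlist(lapply(cluster_sets, `[[`, "clusters"),
                         recursive = FALSE)
  out <- list(); prov <- list(); seen <- character(0)
  for (cq in cliques) {
    members <- all_clusters[cq]
    merged <- sort(unique(
      if (mode == "union") unlist(members) else Reduce(intersect, members)
    ))
    if (length(merged) == 0L) next
    key <- paste(merged, collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- merged
    prov[[length(prov) + 1L]] <- kg$nodes[cq, , drop = FALSE]
  }
  if (length(out) == 0L)
    stop("no consensus clusters: every clique was below the size cutoff or empty")
  res <- cluster_set(out, name = name)
  attr(res, "provenance") <- prov
  res
}
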