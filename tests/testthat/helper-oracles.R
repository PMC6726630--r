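# Independent brute-force oracles used to pin the matching and clique
# code, plus small random-instance generators. Everything here works by
# exhaustive enumeration and never calls the package's graph backends.

# All matchings of a bipartite edge list, by take/skip recursion.
# Returns list(max_weight, max_cardinality).
brute_matching <- function(edges) {
  if (nrow(edges) == 0L) return(list(max_weight = 0, max_cardinality = 0L))
  best_w <- 0
  best_c <- 0L
  rec <- function(k, used_i, used_j, w, card) {
    if (w > best_w) best_w <<- w
    if (card > best_c) best_c <<- card
    if (k > nrow(edges)) return()
    # skip edge k
    rec(k + 1L, used_i, used_j, w, card)
    # take edge k if both endpoints free
    i <- edges$i[k]; j <- edges$j[k]
    if (!(i %in% used_i) && !(j %in% used_j))
      rec(k + 1L, c(used_i, i), c(used_j, j), w + edges$weight[k], card + 1L)
  }
  rec(1L, integer(0), integer(0), 0, 0L)
  list(max_weight = best_w, max_cardinality = best_c)
}

# Maximal cliques of an undirected graph given as adjacency matrix,
# by checking every vertex subset (n <= 15 or so).
brute_maximal_cliques <- function(adj, min_size = 1L) {
  n <- nrow(adj)
  is_clique <- function(v) {
    if (length(v) < 2L) return(TRUE)
    all(adj[v, v][upper.tri(matrix(0, length(v), length(v)))] == 1)
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    v <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!is_clique(v)) next
    # maximal: no outside vertex adjacent to all of v
    outside <- setdiff(seq_len(n), v)
    extendable <- any(vapply(outside, function(u) all(adj[u, v] == 1),
                             logical(1)))
    if (!extendable && length(v) >= min_size)
      cliques[[length(cliques) + 1L]] <- v
  }
  key <- vapply(cliques, function(x) paste(sprintf("%09d", x), collapse = ","),
                character(1))
  cliques[order(key)]
}

# Random small gold/cluster pair over a shared protein universe, so
# overlaps (and hence threshold-graph edges) actually occur.
random_instance <- function(n_max = 6L, m_max = 6L, universe = 10L) {
  prot <- sprintf("u%02d", seq_len(universe))
  n <- sample.int(n_max, 1L)
  m <- sample.int(m_max, 1L)
  gs <- gold_standard(lapply(seq_len(n), function(i)
    sample(prot, sample(2:5, 1L))), name = "rand_gold")
  cs <- cluster_set(lapply(seq_len(m), function(j)
    sample(prot, sample(2:5, 1L))), name = "rand_clusters")
  list(gold = gs, clusters = cs, table = build_overlap(gs, cs))
}

# W1: the worked instance used across the metric tests.
w1_gold <- function() gold_standard(
  list(c("a", "b", "c", "d"), c("d", "e", "f")), name = "w1_gold")
w1_clusters <- function() cluster_set(
  list(c("a", "b", "c"), c("e", "f", "g"), c("x", "y")), name = "w1_method")
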