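#' Neighborhood affinity between a complex and a cluster
#'
#' The neighborhood affinity score
#' \deqn{NA(P, C) = \frac{|P \cap C|^2}{|P|\,|C|}}
#' measures how well a reference complex P is reproduced by a detected
#' cluster C, rewarding both coverage and purity. It is symmetric, lies
#' in \[0, 1\], is 0 exactly when the sets are disjoint and 1 exactly
#' when they are equal.
#'
#' @param p,c non-empty character vectors of protein IDs (duplicates
#'   ignored).
#' @return a scalar in \[0, 1\].
#' @examples
#' na_score(c("a", "b", "c", "d"), c("a", "b", "c"))  # 9/12
#' @export
na_score <- function(p, c) {
  p <- unique(p); c <- unique(c)
  if (length(p) == 0L || length(c) == 0L)
    stop("neighborhood affinity is undefined for empty sets")
  length(intersect(p, c))^2 / (length(p) * length(c))
}

#' Jaccard index between two protein sets
#'
#' \deqn{JCC(P, C) = \frac{|P \cap C|}{|P \cup C|}}
#'
#' @inheritParams na_score
#' @return a scalar in \[0, 1\].
#' @export
jcc_score <- function(p, c) {
  p <- unique(p); c <- unique(c)
  if (length(p) == 0L || length(c) == 0L)
    stop("Jaccard index is undefined for empty sets")
  i <- length(intersect(p, c))
  i / (length(p) + length(c) - i)
}

#' Build the bipartite complex-cluster overlap table
#'
#' Models the relation between a gold standard and one method's output
#' as a weighted bipartite graph: entry `t[i, j]` counts the proteins
#' shared by reference complex i and detected cluster j. The
#' neighborhood-affinity and Jaccard matrices are precomputed alongside
#' the counts because different criteria consume different scores.
#'
#' @param gold a [gold_standard()].
#' @param clusters a [cluster_set()].
#' @return an object of class `overlap_table`: a list with integer
#'   matrix `t` (n x m), numeric matrices `na` and `jcc` of the same
#'   shape, complex sizes `n_i`, cluster sizes `m_j`, and the two
#'   labels `gold_name`, `method_name`.
#' @examples
#' gs <- gold_standard(list(c("a","b","c","d"), c("d","e","f")))
#' cs <- cluster_set(list(c("a","b","c"), c("e","f","g"), c("x","y")))
#' ov <- build_overlap(gs, cs)
#' ov$t
#' @export
build_overlap <- function(gold, clusters) {
  assert_nonempty_pair(gold, clusters)
  P <- gold$clusters
  C <- clusters$clusters
  n <- length(P); m <- length(C)
  n_i <- lengths(P); m_j <- lengths(C)

  # inverted index protein -> clusters containing it; t_i. in O(overlap)
  idx <- split(rep(seq_len(m), m_j), unlist(C))
  tmat <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    hits <- unlist(idx[P[[i]]], use.names = FALSE)
    if (length(hits)) tmat[i, ] <- tabulate(hits, nbins = m)
  }

  na <- tmat^2 / outer(n_i, m_j)
  jcc <- tmat / (outer(n_i, m_j, `+`) - tmat)
  structure(
    list(t = tmat, na = na, jcc = jcc, n_i = n_i, m_j = m_j,
         gold_name = gold$name, method_name = clusters$name),
    class = "overlap_table"
  )
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("<overlap table: %d complexes ('%s') x %d clusters ('%s'), %d overlapping pairs>\n",
              nrow(x$t), x$gold_name, ncol(x$t), x$method_name, sum(x$t > 0)))
  invisible(x)
}
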