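make_methods <- function(...) {
  sets <- list(...)
  lapply(seq_along(sets), function(i)
    cluster_set(sets[[i]], name = paste0("m", i)))
}

test_that("k-partite edges follow the strict overlap rule", {
  ms <- make_methods(list(c("a", "b", "c")), list(c("a", "b", "c")))
  kg <- build_kpartite(ms, phi = 1)
  expect_equal(igraph::ecount(kg$graph), 1L)  # identical clusters always link
  # near-identical is not enough at phi = 1
  ms0 <- make_methods(list(c("a", "b", "c")), list(c("a", "b", "c", "d")))
  expect_equal(igraph::ecount(build_kpartite(ms0, phi = 1)$graph), 0L)

  # JCC exactly phi must not create an edge
  ms3 <- make_methods(list(c("a", "b", "c")), list(c("a", "b", "d")))
  expect_equal(igraph::ecount(build_kpartite(ms3, phi = 0.5)$graph), 0L)
  ms4 <- make_methods(list(c("a", "b", "c")), list(c("a", "b")))
  expect_equal(igraph::ecount(build_kpartite(ms4, phi = 0.5)$graph), 1L)

  # no intra-part edges even for identical clusters within one method
  ms5 <- make_methods(list(c("a", "b"), c("a", "b")), list(c("a", "b")))
  kg5 <- build_kpartite(ms5, phi = 0.4)
  ends <- igraph::as_edgelist(kg5$graph)
  expect_true(all(kg5$nodes$method[ends[, 1]] != kg5$nodes$method[ends[, 2]]))

  expect_error(build_kpartite(ms[1], 0.5), ">= 2 methods")
})

test_that("consensus cliques respect the strict size cutoff", {
  # triangle across three parts
  ms <- make_methods(list(c("a", "b", "c")), list(c("a", "b", "c")),
                     list(c("a", "b", "c")))
  kg <- build_kpartite(ms, phi = 0.5)
  cl <- consensus_cliques(kg, psi = 1)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]], 1:3)
  # isolated nodes form maximal cliques of size 1, excluded at psi = 1
  ms2 <- make_methods(list(c("a", "b")), list(c("x", "y")))
  expect_equal(length(consensus_cliques(build_kpartite(ms2, 0.5), psi = 1)), 0L)
})

test_that("clique enumeration agrees with brute-force subset search", {
  set.seed(23)
  prot <- sprintf("q%02d", 1:12)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    ms <- lapply(seq_len(k), function(i) {
      nc <- sample(1:3, 1)
      cluster_set(lapply(seq_len(nc), function(j)
        sample(prot, sample(2:5, 1))), name = paste0("m", i))
    })
    phi <- sample(c(0.2, 0.4, 0.6), 1)
    kg <- build_kpartite(ms, phi)
    nv <- nrow(kg$nodes)
    adj <- matrix(0L, nv, nv)
    el <- igraph::as_edgelist(kg$graph)
    adj[el] <- 1L; adj[el[, 2:1, drop = FALSE]] <- 1L
    for (psi in 0:2) {
      got <- consensus_cliques(kg, psi)
      want <- brute_maximal_cliques(adj, min_size = psi + 1L)
      expect_equal(got, want, info = sprintf("rep %d psi %d", rep, psi))
    }
  }
})

test_that("integration unions and intersects clique members", {
  ms <- make_methods(list(c("a", "b", "c")), list(c("a", "b", "d")))
  un <- integrate_methods(ms, phi = 0.4, psi = 1, mode = "union")
  expect_equal(un$clusters, list(c("a", "b", "c", "d")))
  is <- integrate_methods(ms, phi = 0.4, psi = 1, mode = "intersection")
  expect_equal(is$clusters, list(c("a", "b")))
  # provenance names the clique
  expect_equal(nrow(attr(un, "provenance")[[1]]), 2L)
})

test_that("phi = 1 makes union and intersection identical", {
  set.seed(37)
  for (rep in 1:10) {
    gs <- make_gold(n_complexes = 4, size_range = c(3, 5), seed = rep)
    # three methods reporting overlapping subsets of the same catalogue
    ms <- lapply(1:3, function(i) {
      keep <- sort(sample(gs$n, 3))
      cluster_set(gs$clusters[keep], name = paste0("m", i))
    })
    un <- try(integrate_methods(ms, phi = 1, psi = 1, mode = "union"),
              silent = TRUE)
    is <- try(integrate_methods(ms, phi = 1, psi = 1, mode = "intersection"),
              silent = TRUE)
    if (inherits(un, "try-error")) {
      expect_true(inherits(is, "try-error"))  # no clique passed in either mode
    } else {
      expect_equal(un$clusters, is$clusters)
    }
  }
})

test_that("integrated clusters bound their clique members", {
  set.seed(41)
  gs <- make_gold(n_complexes = 5, size_range = c(4, 6), seed = 2)
  ms <- lapply(1:3, function(i)
    perturb_clusters(gs, drop_protein_rate = 0.2, seed = i,
                     name = paste0("m", i)))
  for (mode in c("union", "intersection")) {
    res <- integrate_methods(ms, phi = 0.3, psi = 1, mode = mode)
    all_clusters <- unlist(lapply(ms, `[[`, "clusters"), recursive = FALSE)
    prov <- attr(res, "provenance")
    offsets <- cumsum(c(0, head(vapply(ms, length, integer(1)), -1)))
    for (ci in seq_along(res$clusters)) {
      members <- all_clusters[offsets[prov[[ci]]$method] + prov[[ci]]$cluster]
      for (mem in members) {
        if (mode == "union") expect_true(all(mem %in% res$clusters[[ci]]))
        else expect_true(all(res$clusters[[ci]] %in% mem))
      }
    }
  }
})

test_that("size filter keeps the requested band and is idempotent", {
  cs <- cluster_set(list("a", c("a", "b"), c("a", "b", "c")))
  expect_equal(filter_size(cs, 2, 2)$clusters, list(c("a", "b")))
  expect_equal(filter_size(cs, 1, Inf)$clusters, cs$clusters)
  expect_equal(filter_size(cluster_set(list(c("a","b"), c("c","d","e"))), 3, 10)$clusters,
               list(c("c", "d", "e")))
  once <- filter_size(cs, 2, 3)
  expect_equal(filter_size(once, 2, 3)$clusters, once$clusters)
  expect_error(filter_size(cs, 3, 2), "min_size")
})

test_that("protein filter returns per-method hits by exact match", {
  ms <- make_methods(list(c("a", "b"), c("b", "c")), list(c("x", "y")))
  hits <- filter_protein(ms, "b")
  expect_equal(hits$m1, list(c("a", "b"), c("b", "c")))
  expect_equal(hits$m2, list())
  none <- filter_protein(ms, "absent")
  expect_true(all(lengths(none) == 0))
  # case-sensitive, no partial matching
  expect_equal(length(filter_protein(ms, "B")$m1), 0L)
})

test_that("reliability filter counts supporting methods including the target", {
  target <- cluster_set(list(c("a", "b", "c"), c("x", "y", "z")), name = "t")
  # beta = 1: identity
  expect_equal(filter_reliability(target, list(), beta = 1)$clusters,
               target$clusters)
  # panel holding an exact copy of the first cluster only
  panel <- list(cluster_set(list(c("a", "b", "c")), name = "p1"))
  res <- filter_reliability(target, panel, beta = 2)
  expect_equal(res$clusters, list(c("a", "b", "c")))
  # beta beyond the available methods: warning + empty
  expect_warning(res2 <- filter_reliability(target, panel, beta = 3),
                 "exceeds")
  expect_equal(length(res2), 0L)
})
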