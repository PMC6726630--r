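test_that("gold generation is seeded, sized and overlap-constrained", {
  g1 <- make_gold(n_complexes = 3, size_range = c(4, 4), overlap_fraction = 0,
                  seed = 7)
  g2 <- make_gold(n_complexes = 3, size_range = c(4, 4), overlap_fraction = 0,
                  seed = 7)
  expect_identical(g1$clusters, g2$clusters)
  expect_equal(lengths(g1$clusters), rep(4L, 3))
  expect_equal(length(unique(unlist(g1$clusters))), 12L)  # disjoint

  gov <- make_gold(n_complexes = 2, size_range = c(4, 4), overlap_fraction = 1,
                   shared_count = 2, seed = 7)
  expect_equal(length(intersect(gov$clusters[[1]], gov$clusters[[2]])), 2L)

  expect_error(make_gold(size_range = c(3, 5), overlap_fraction = 0.5,
                         shared_count = 3), "shared_count")
})

test_that("the identity perturbation returns the gold clusters unchanged", {
  gs <- make_gold(n_complexes = 4, seed = 5)
  cs <- perturb_clusters(gs, seed = 9)
  expect_equal(cs$clusters, gs$clusters)
})

test_that("each pathology knob produces its advertised signature", {
  gs <- make_gold(n_complexes = 3, size_range = c(4, 6),
                  overlap_fraction = 0, seed = 15)
  # giant component: one extra cluster equal to the protein union, SN = 1
  giant <- perturb_clusters(gs, giant_component = TRUE, seed = 1)
  expect_equal(length(giant), gs$n + 1L)
  expect_setequal(giant$clusters[[gs$n + 1L]], unlist(gs$clusters))
  lost <- perturb_clusters(gs, drop_protein_rate = 0.4, seed = 2)
  with_giant <- cluster_set(c(lost$clusters, giant$clusters[gs$n + 1L]))
  expect_equal(unname(sn_ppv_acc(build_overlap(gs, with_giant))["SN"]), 1)

  # duplicates are exact copies of existing clusters
  dup <- perturb_clusters(gs, duplicate_clusters = 3, seed = 3)
  expect_equal(length(dup), gs$n + 3L)
  for (extra in dup$clusters[(gs$n + 1):(gs$n + 3)])
    expect_true(any(vapply(gs$clusters, setequal, logical(1), extra)))

  # spurious pairs live inside single complexes
  sp <- perturb_clusters(gs, spurious_pairs = 5, seed = 4)
  for (pair in sp$clusters[(gs$n + 1):(gs$n + 5)]) {
    expect_equal(length(pair), 2L)
    expect_true(any(vapply(gs$clusters, function(cl) all(pair %in% cl),
                           logical(1))))
  }

  # noise proteins come from the disjoint N-namespace
  noisy <- perturb_clusters(gs, add_noise_protein_rate = 0.5, seed = 6)
  contaminants <- setdiff(unlist(noisy$clusters), unlist(gs$clusters))
  expect_true(length(contaminants) > 0)
  expect_true(all(startsWith(contaminants, "N")))

  # dropped clusters shrink the set (and dropping everything is an error)
  big <- make_gold(n_complexes = 12, size_range = c(3, 6), seed = 16)
  dropped <- perturb_clusters(big, drop_cluster_rate = 0.5, seed = 8)
  expect_lt(length(dropped), big$n)
  expect_gt(length(dropped), 0L)
  expect_error(perturb_clusters(big, drop_cluster_rate = 1, seed = 8),
               "dropped every cluster")
})

test_that("planted networks are denser inside complexes than between them", {
  gs <- make_gold(n_complexes = 4, size_range = c(4, 6),
                  overlap_fraction = 0, seed = 20)
  # limit case: complete cliques, no background
  full <- make_ppin(gs, p_in = 1, p_out = 0, seed = 1)
  expect_equal(nrow(full$edges),
               sum(choose(lengths(gs$clusters), 2)))
  # determinism
  n1 <- make_ppin(gs, p_in = 0.9, p_out = 0.05, seed = 2)
  n2 <- make_ppin(gs, p_in = 0.9, p_out = 0.05, seed = 2)
  expect_identical(n1$edges, n2$edges)
  expect_error(make_ppin(gs, p_in = 0.1, p_out = 0.5), "p_in > p_out")

  # empirical density gap over 20 seeds
  intra_pairs <- sum(choose(lengths(gs$clusters), 2))
  total_pairs <- choose(length(unique(unlist(gs$clusters))), 2)
  dens_in <- dens_out <- numeric(20)
  for (s in 1:20) {
    net <- make_ppin(gs, p_in = 0.8, p_out = 0.1, seed = 100 + s)
    in_complex <- vapply(seq_len(nrow(net$edges)), function(e)
      any(vapply(gs$clusters, function(cl)
        all(c(net$edges$a[e], net$edges$b[e]) %in% cl), logical(1))),
      logical(1))
    dens_in[s] <- sum(in_complex) / intra_pairs
    dens_out[s] <- sum(!in_complex) / (total_pairs - intra_pairs)
  }
  expect_gt(mean(dens_in), mean(dens_out))
})

test_that("composite score degrades in expectation as perturbation grows", {
  gs <- make_gold(n_complexes = 6, size_range = c(4, 7),
                  overlap_fraction = 0, seed = 30)
  rates <- c(0, 0.15, 0.35)
  means <- vapply(rates, function(r) {
    mean(vapply(1:20, function(s) {
      cs <- perturb_clusters(gs, drop_protein_rate = r,
                             add_noise_protein_rate = r, seed = 1000 + s)
      composite_mmr_fplus(build_overlap(gs, cs), 0.25)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(means[1], 2)  # exact at zero perturbation
  expect_true(all(diff(means) <= 0))
})
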