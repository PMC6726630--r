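#' Generate a synthetic gold standard
#'
#' Builds a reproducible reference catalogue of protein complexes with
#' controllable overlap, emulating the shape of curated yeast
#' catalogues: complex sizes drawn uniformly from `size_range`, and a
#' chosen fraction of consecutive complex pairs sharing a fixed number
#' of proteins (catalogue complexes routinely overlap).
#'
#' Proteins are labelled `P000001, P000002, ...`; overlap is realised
#' by letting the later complex of a selected pair reuse the first
#' `shared_count` proteins of the earlier one.
#'
#' @param n_complexes number of reference complexes.
#' @param size_range length-2 integer vector `(min, max)` of complex
#'   sizes; minimum size must exceed `shared_count`.
#' @param overlap_fraction fraction of consecutive complex pairs that
#'   share proteins, in \[0, 1\].
#' @param shared_count proteins shared by each overlapping pair.
#' @param seed RNG seed; the same seed always yields the same catalogue.
#' @param name label for the catalogue.
#' @return a [gold_standard()].
#' @examples
#' make_gold(n_complexes = 3, size_range = c(4, 4), seed = 7)
#' @export
make_gold <- function(n_complexes = 10, size_range = c(3, 8),
                      overlap_fraction = 0, shared_count = 2,
                      seed = NULL, name = "synthetic_gold") {
  stopifnot(n_complexes >= 1, length(size_range) == 2L,
            size_range[1] >= 1, size_range[1] <= size_range[2],
            overlap_fraction >= 0, overlap_fraction <= 1, shared_count >= 0)
  if (overlap_fraction > 0 && shared_count >= size_range[1])
    stop("shared_count must be smaller than the minimum complex size")
  with_seed(seed, {
    sz <- seq(size_range[1], size_range[2])
    sizes <- sz[sample.int(length(sz), n_complexes, replace = TRUE)]
    next_id <- 1L
    fresh <- function(k) {
      ids <- sprintf("P%06d", seq(next_id, length.out = k))
      next_id <<- next_id + k
      ids
    }
    complexes <- vector("list", n_complexes)
    overlap_pair <- if (n_complexes > 1)
      stats::runif(n_complexes - 1) < overlap_fraction else logical(0)
    for (i in seq_len(n_complexes)) {
      if (i > 1 && overlap_pair[i - 1] && shared_count > 0) {
        shared <- complexes[[i - 1]][seq_len(shared_count)]
        complexes[[i]] <- c(shared, fresh(sizes[i] - shared_count))
      } else {
        complexes[[i]] <- fresh(sizes[i])
      }
    }
    gold_standard(complexes, name = name)
  })
}

#' Perturb a gold standard into a synthetic detected-cluster set
#'
#' Starts from clusters identical to the reference complexes and
#' applies, in a fixed order so a seed fully determines the output:
#'
#' 1. drop whole clusters with probability `drop_cluster_rate`
#'    (undetected complexes, i.e. false negatives);
#' 2. drop individual proteins with probability `drop_protein_rate`
#'    (at least one protein is always kept per cluster);
#' 3. add noise proteins: each cluster gains
#'    `Binomial(size, add_noise_protein_rate)` contaminants from a
#'    disjoint `N...` namespace, so contamination stays traceable;
#' 4. append `duplicate_clusters` exact copies of randomly chosen
#'    surviving clusters (the redundancy pathology);
#' 5. append `spurious_pairs` two-protein clusters drawn from within
#'    single complexes of size > 2 (spurious false positives that
#'    saturate set-overlap criteria);
#' 6. optionally append one giant cluster equal to the union of all
#'    reference proteins (the giant-component pathology that forces
#'    SN to 1).
#'
#' With an all-zero specification the output clusters are identical to
#' the gold standard.
#'
#' @param gold a [gold_standard()].
#' @param drop_cluster_rate,drop_protein_rate,add_noise_protein_rate
#'   rates in \[0, 1\].
#' @param duplicate_clusters number of exact copies to append.
#' @param spurious_pairs number of within-complex 2-protein clusters to
#'   append.
#' @param giant_component append the union-of-all-proteins cluster?
#' @param seed RNG seed.
#' @param name label for the resulting set.
#' @return a [cluster_set()].
#' @export
perturb_clusters <- function(gold, drop_cluster_rate = 0,
                             drop_protein_rate = 0,
                             add_noise_protein_rate = 0,
                             duplicate_clusters = 0L,
                             spurious_pairs = 0L,
                             giant_component = FALSE,
                             seed = NULL, name = NULL) {
  stopifnot(inherits(gold, "gold_standard"))
  rates <- c(drop_cluster_rate, drop_protein_rate, add_noise_protein_rate)
  stopifnot(all(rates >= 0 & rates <= 1), duplicate_clusters >= 0,
            spurious_pairs >= 0)
  if (is.null(name)) name <- paste0(gold$name, "_detected")
  with_seed(seed, {
    clusters <- gold$clusters
    # 1. undetected complexes
    if (drop_cluster_rate > 0) {
      keep <- stats::runif(length(clusters)) >= drop_cluster_rate
      clusters <- clusters[keep]
    }
    # 2. missing proteins (clusters never emptied)
    if (drop_protein_rate > 0 && length(clusters)) {
      clusters <- lapply(clusters, function(cl) {
        keep <- stats::runif(length(cl)) >= drop_protein_rate
        if (!any(keep)) keep[sample.int(length(cl), 1L)] <- TRUE
        cl[keep]
      })
    }
    # 3. contaminating proteins from the disjoint noise namespace
    if (add_noise_protein_rate > 0 && length(clusters)) {
      noise_next <- 1L
      clusters <- lapply(clusters, function(cl) {
        extra <- stats::rbinom(1L, length(cl), add_noise_protein_rate)
        if (extra > 0) {
          ids <- sprintf("N%06d", seq(noise_next, length.out = extra))
          noise_next <<- noise_next + extra
          cl <- c(cl, ids)
        }
        cl
      })
    }
    # 4. redundant exact copies
    if (duplicate_clusters > 0 && length(clusters)) {
      picks <- sample.int(length(clusters), duplicate_clusters, replace = TRUE)
      clusters <- c(clusters, clusters[picks])
    }
    # 5. spurious within-complex pairs
    if (spurious_pairs > 0) {
      eligible <- which(lengths(gold$clusters) > 2L)
      if (length(eligible) == 0L)
        stop("spurious pairs need at least one complex of size > 2")
      for (s in seq_len(spurious_pairs)) {
        ci <- eligible[sample.int(length(eligible), 1L)]
        clusters <- c(clusters, list(sample(gold$clusters[[ci]], 2L)))
      }
    }
    # 6. giant component
    if (isTRUE(giant_component))
      clusters <- c(clusters, list(sort(unique(unlist(gold$clusters)))))
    if (length(clusters) == 0L)
      stop("perturbation dropped every cluster; lower drop_cluster_rate")
    cluster_set(clusters, name = name)
  })
}

#' Generate a planted-complex weighted interaction network
#'
#' Emulates the premise that complexes are dense subgraphs of the
#' interaction network: every pair of proteins sharing a complex gets
#' an edge with probability `p_in` and a reliability weight uniform in
#' `weight_in`; every other pair with probability `p_out` and weight
#' uniform in `weight_out`. Requires `p_in > p_out`. Self-interactions
#' are never emitted and proteins left without any edge are pruned.
#'
#' @param gold a [gold_standard()] supplying the protein universe and
#'   the planted complexes.
#' @param p_in intra-complex edge probability.
#' @param p_out inter-complex edge probability (< `p_in`).
#' @param weight_in,weight_out length-2 ranges for the reliability
#'   weights (must be positive).
#' @param seed RNG seed.
#' @return a `ppin_network`.
#' @export
make_ppin <- function(gold, p_in = 0.85, p_out = 0.02,
                      weight_in = c(0.6, 1), weight_out = c(0.05, 0.4),
                      seed = NULL) {
  stopifnot(inherits(gold, "gold_standard"),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            length(weight_in) == 2L, length(weight_out) == 2L,
            all(weight_in > 0), all(weight_out > 0))
  if (p_in <= p_out)
    stop("planted complexes must be denser than the background: p_in > p_out")
  proteins <- sort(unique(unlist(gold$clusters)))
  np <- length(proteins)
  if (np < 2L) stop("need at least two proteins to build a network")
  # pairs sharing at least one complex
  intra_key <- unique(unlist(lapply(gold$clusters, function(cl) {
    if (length(cl) < 2L) return(character(0))
    cmb <- utils::combn(sort(cl), 2L)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })))
  with_seed(seed, {
    cmb <- utils::combn(proteins, 2L)
    key <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    is_in <- key %in% intra_key
    p <- ifelse(is_in, p_in, p_out)
    hit <- stats::runif(length(p)) < p
    w <- numeric(sum(hit))
    ih <- is_in[hit]
    w[ih] <- stats::runif(sum(ih), weight_in[1], weight_in[2])
    w[!ih] <- stats::runif(sum(!ih), weight_out[1], weight_out[2])
    ppin_network(data.frame(a = cmb[1, hit], b = cmb[2, hit], weight = w,
                            stringsAsFactors = FALSE))
  })
}
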