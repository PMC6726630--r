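#' Evaluate one method against a gold standard
#'
#' Computes the full criterion family for one detected-cluster set.
#' With a fixed `theta`, every threshold-dependent criterion is
#' evaluated at that threshold and the composite MMR + F-measure+ is
#' included. With `theta = NULL` the evaluation switches to
#' area-under-curve mode: each threshold-dependent criterion is
#' reported as its trapezoidal area over `grid`, together with AUMF,
#' AUPR and AUPR+; SN/PPV/ACC are threshold-free and always reported
#' as absolute values.
#'
#' @param gold a [gold_standard()].
#' @param clusters a [cluster_set()].
#' @param theta affinity/Jaccard threshold in \[0, 1\], or `NULL` for
#'   area-under-curve mode.
#' @param grid threshold grid for area mode; ignored when `theta` is
#'   given.
#' @return a one-row `data.frame` ("metric report") with columns
#'   `method`, `gold`, `theta` (NA in area mode) and one column per
#'   criterion.
#' @examples
#' gs <- make_gold(n_complexes = 4, seed = 1)
#' cs <- perturb_clusters(gs, drop_protein_rate = 0.2, seed = 2)
#' evaluate_method(gs, cs, theta = 0.25)
#' @export
evaluate_method <- function(gold, clusters, theta = 0.25,
                            grid = default_grid()) {
  assert_nonempty_pair(gold, clusters)
  if (!any(unlist(clusters$clusters) %in% unlist(gold$clusters)))
    warning(sprintf(
      "method '%s' shares no protein with gold standard '%s'; all scores are 0",
      clusters$name, gold$name))
  tb <- build_overlap(gold, clusters)
  base <- data.frame(method = clusters$name, gold = gold$name,
                     theta = if (is.null(theta)) NA_real_ else theta,
                     stringsAsFactors = FALSE)
  spa <- sn_ppv_acc(tb)
  if (!is.null(theta)) {
    row <- cbind(base, as.data.frame(t(c(
      spa,
      mmr = mmr(tb, theta),
      pr_metrics(tb, theta),
      plus_metrics(tb, theta),
      n_metrics(tb, theta),
      mmr_fplus = composite_mmr_fplus(tb, theta)
    ))))
  } else {
    dep <- c("mmr", "precision", "recall", "f", "precision_plus",
             "recall_plus", "f_plus", "precision_n", "recall_n", "f_n")
    areas <- vapply(dep, function(mname) {
      curve_auc(sweep_criterion(tb, mname, grid))
    }, numeric(1))
    names(areas) <- paste0("auc_", dep)
    row <- cbind(base, as.data.frame(t(c(
      spa, areas,
      aumf = aumf(tb, grid),
      aupr = aupr(tb, grid, plus_variant = FALSE)$area,
      aupr_plus = aupr(tb, grid, plus_variant = TRUE)$area
    ))))
  }
  rownames(row) <- NULL
  row
}

#' Evaluate several methods against one gold standard
#'
#' @param gold a [gold_standard()].
#' @param cluster_sets list of [cluster_set()] objects.
#' @inheritParams evaluate_method
#' @return a `data.frame` with one row per method (see
#'   [evaluate_method()]).
#' @export
evaluate_methods <- function(gold, cluster_sets, theta = 0.25,
                             grid = default_grid()) {
  stopifnot(is.list(cluster_sets), length(cluster_sets) >= 1L)
  do.call(rbind, lapply(cluster_sets, function(cs)
    evaluate_method(gold, cs, theta = theta, grid = grid)))
}

#' Write a metric report as TSV with a JSON provenance sidecar
#'
#' The tabular criteria go to `<stem>.tsv`; configuration and
#' provenance (labels, threshold or grid, extra fields supplied via
#' `provenance`) go to `<stem>.json`.
#'
#' @param report a data.frame from [evaluate_method()] /
#'   [evaluate_methods()].
#' @param stem output path without extension.
#' @param provenance named list of extra fields to record (input file
#'   paths, seed, ...).
#' @return invisibly, the two paths written.
#' @export
write_report <- function(report, stem, provenance = list()) {
  tsv <- paste0(stem, ".tsv")
  json <- paste0(stem, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(list(
    methods = report$method,
    gold = unique(report$gold),
    theta = if (all(is.na(report$theta))) "area-under-curve" else
      unique(report$theta),
    criteria = setdiff(names(report), c("method", "gold", "theta"))
  ), provenance)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
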