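#' Default threshold grid
#'
#' The grid used by every area-under-curve criterion when none is
#' given: theta in \{0.01, 0.02, ..., 1.00\}. Zero is excluded because
#' with the `>= theta` edge rule it adds no information beyond the
#' smallest positive threshold, and the threshold axis of this
#' literature is read as (0, 1].
#'
#' @return numeric vector of 100 strictly increasing thresholds.
#' @export
default_grid <- function() seq(0.01, 1, by = 0.01)

# registry of threshold-dependent scalar criteria for sweeps
criterion_fun <- function(metric) {
  switch(metric,
    mmr            = function(tb, th) mmr(tb, th),
    precision      = function(tb, th) unname(pr_metrics(tb, th)["precision"]),
    recall         = function(tb, th) unname(pr_metrics(tb, th)["recall"]),
    f              = function(tb, th) unname(pr_metrics(tb, th)["f"]),
    precision_plus = function(tb, th) unname(plus_metrics(tb, th)["precision_plus"]),
    recall_plus    = function(tb, th) unname(plus_metrics(tb, th)["recall_plus"]),
    f_plus         = function(tb, th) unname(plus_metrics(tb, th)["f_plus"]),
    precision_n    = function(tb, th) unname(n_metrics(tb, th)["precision_n"]),
    recall_n       = function(tb, th) unname(n_metrics(tb, th)["recall_n"]),
    f_n            = function(tb, th) unname(n_metrics(tb, th)["f_n"]),
    composite      = function(tb, th) composite_mmr_fplus(tb, th),
    stop(sprintf("unknown criterion '%s'", metric))
  )
}

#' Sweep a threshold-dependent criterion over a grid
#'
#' Evaluates one criterion at every threshold of the grid. Supported
#' criteria: `"mmr"`, `"precision"`, `"recall"`, `"f"`,
#' `"precision_plus"`, `"recall_plus"`, `"f_plus"`, `"precision_n"`,
#' `"recall_n"`, `"f_n"` and `"composite"` (MMR + F-measure+).
#'
#' @param table an [build_overlap()] table.
#' @param metric criterion name (see above).
#' @param grid strictly increasing thresholds in \[0, 1\], at least two.
#' @return an object of class `threshold_curve`: list with `grid`,
#'   `values`, `metric` and `area` (trapezoidal area over the grid).
#' @export
sweep_criterion <- function(table, metric = "composite", grid = default_grid()) {
  stopifnot(inherits(table, "overlap_table"))
  if (length(grid) < 2L || any(diff(grid) <= 0) || any(grid < 0 | grid > 1))
    stop("grid must be >= 2 strictly increasing thresholds in [0, 1]")
  f <- criterion_fun(metric)
  vals <- vapply(grid, function(th) f(table, th), numeric(1))
  cv <- structure(list(grid = grid, values = vals, metric = metric),
                  class = "threshold_curve")
  cv$area <- curve_auc(cv)
  cv
}

#' Trapezoidal area under a threshold curve
#'
#' Integrates the sampled criterion over its grid by the trapezoidal
#' rule. The area is *not* re-normalised by grid width, so areas are
#' comparable only across identical grids; reports record the grid.
#'
#' @param curve a [sweep_criterion()] result.
#' @return the area (non-negative scalar).
#' @export
curve_auc <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  trapezoid(curve$grid, curve$values)
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Area under the (MMR + F-measure+) vs threshold curve (AUMF)
#'
#' The threshold-free form of the composite criterion: the trapezoidal
#' area of MMR + F-measure+ swept over the threshold grid. With the
#' default grid the maximum attainable value is 2 x 0.99 = 1.98.
#'
#' @param table an [build_overlap()] table.
#' @param grid thresholds; the default grid when not given.
#' @return a scalar in \[0, 2 x grid width\].
#' @export
aumf <- function(table, grid = default_grid()) {
  curve_auc(sweep_criterion(table, "composite", grid))
}

#' Precision-recall curve and area traced by the threshold
#'
#' Sweeps the threshold over the grid and plots precision against
#' recall (or their one-to-one `+` variants). Thresholds yielding the
#' same recall collapse to the maximum precision observed there, and
#' the area is the trapezoid over the observed recall range only — no
#' extrapolation toward recall 0 or 1, so a degenerate single-point
#' curve has area 0.
#'
#' @param table an [build_overlap()] table.
#' @param grid thresholds; the default grid when not given.
#' @param plus_variant if `TRUE`, use Precision+/Recall+ (AUPR+)
#'   instead of Precision/Recall (AUPR).
#' @return an object of class `pr_curve`: list with `points`
#'   (data.frame of `recall`, `precision`, increasing recall), `area`
#'   and `plus_variant`.
#' @export
aupr <- function(table, grid = default_grid(), plus_variant = FALSE) {
  stopifnot(inherits(table, "overlap_table"))
  if (length(grid) < 2L || any(diff(grid) <= 0) || any(grid < 0 | grid > 1))
    stop("grid must be >= 2 strictly increasing thresholds in [0, 1]")
  f <- if (plus_variant) plus_metrics else pr_metrics
  pr <- t(vapply(grid, function(th) unname(f(table, th)[1:2]), numeric(2)))
  rec <- pr[, 2]; prec <- pr[, 1]
  best <- tapply(prec, rec, max)
  pts <- data.frame(recall = as.numeric(names(best)),
                    precision = as.numeric(best))
  pts <- pts[order(pts$recall), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, area = trapezoid(pts$recall, pts$precision),
                 plus_variant = plus_variant),
            class = "pr_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold curve '%s': %d grid points on [%g, %g], area %.4f>\n",
              x$metric, length(x$grid), min(x$grid), max(x$grid), x$area))
  invisible(x)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<%s curve: %d points, area %.4f>\n",
              if (x$plus_variant) "precision+/recall+" else "precision/recall",
              nrow(x$points), x$area))
  invisible(x)
}

#' Write a curve to a tab-separated file
#'
#' Threshold curves get columns `theta`, `value`; precision-recall
#' curves get `recall`, `precision`.
#'
#' @param curve a `threshold_curve` or `pr_curve`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- if (inherits(curve, "pr_curve")) {
    curve$points
  } else {
    data.frame(theta = curve$grid, value = curve$values)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
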