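#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' The classical threshold-free trio:
#' \deqn{SN = \frac{\sum_i \max_j t_{ij}}{\sum_i n_i}, \qquad
#'       PPV = \frac{\sum_j \max_i t_{ij}}{\sum_i \sum_j t_{ij}}, \qquad
#'       ACC = \sqrt{SN \times PPV}}
#' where \eqn{t_{ij}} counts shared proteins, \eqn{n_i} is the size of
#' complex i. When no protein is shared at all (an all-zero table) PPV
#' and ACC are defined as 0: a method with no overlap gets the worst
#' score, not an error.
#'
#' @param table an [build_overlap()] table.
#' @return named numeric vector `c(SN=, PPV=, ACC=)`.
#' @export
sn_ppv_acc <- function(table) {
  stopifnot(inherits(table, "overlap_table"))
  sn <- sum(apply(table$t, 1, max)) / sum(table$n_i)
  tot <- sum(table$t)
  ppv <- if (tot == 0) 0 else sum(apply(table$t, 2, max)) / tot
  c(SN = sn, PPV = ppv, ACC = sqrt(sn * ppv))
}

#' Jaccard-thresholded PrecisionN, RecallN and F-measureN
#'
#' Per reference complex, the best overlap count over clusters whose
#' Jaccard index with it strictly exceeds `theta` (0 when none
#' qualifies), normalised by total complex size; RecallN mirrors the
#' construction per detected cluster. F-measureN is their harmonic
#' mean. Note the comparison is strict (`> theta`) for these
#' Jaccard-based criteria, unlike the `>= theta` convention of the
#' affinity-based family — both conventions are preserved as printed in
#' the original definitions.
#'
#' @param table an [build_overlap()] table.
#' @param theta Jaccard threshold in \[0, 1\].
#' @return named numeric vector `c(precision_n=, recall_n=, f_n=)`.
#' @export
n_metrics <- function(table, theta = 0.25) {
  stopifnot(inherits(table, "overlap_table"), theta >= 0, theta <= 1)
  pass <- table$jcc > theta
  tq <- table$t * pass
  k_i <- apply(tq, 1, max)   # best qualifying overlap per complex
  k_j <- apply(tq, 2, max)   # best qualifying overlap per cluster
  prec <- sum(k_i) / sum(table$n_i)
  rec <- sum(k_j) / sum(table$m_j)
  c(precision_n = prec, recall_n = rec, f_n = harmonic_mean(prec, rec))
}

# harmonic mean with the 0/0 -> 0 convention used by every F-type score
harmonic_mean <- function(a, b) {
  if (a + b == 0) 0 else 2 * a * b / (a + b)
}
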