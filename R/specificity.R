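# Cohort-specific circRNAs: CPM normalization, top-expressed ranking, and
# the tandem Mann-Whitney specificity test against two control cohorts.

#' Counts-per-million normalization of a back-splice count matrix
#'
#' CPM = count x 1e6 / (sum of all back-splice counts in that sample).
#' Optionally sums isoform-level CPMs to gene-level circ features.
#'
#' @param counts non-negative count matrix (feature x sample).
#' @param sum_by optional named vector mapping rownames of `counts` to a
#'   coarser feature (e.g. circ isoform to gene); CPMs are summed within
#'   each target feature after normalization.
#' @return CPM matrix.
#' @export
cpm_normalize <- function(counts, sum_by = NULL) {
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("cpm_normalize: zero-total sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  cpm <- sweep(counts, 2L, totals, "/") * 1e6
  if (!is.null(sum_by)) {
    grp <- sum_by[rownames(cpm)]
    if (anyNA(grp)) stop("cpm_normalize: sum_by misses some features")
    cpm <- rowsum(cpm, grp)
  }
  cpm
}

#' Rank features by mean CPM across samples
#'
#' Features are ranked by the mean across samples of their per-sample CPM;
#' ties are broken lexicographically by feature id, so the ranking is
#' stable across runs.
#'
#' @param cpm CPM matrix (feature x sample).
#' @param n number of top features to return.
#' @return data.frame: feature_id, mean_cpm, in rank order.
#' @export
select_top_expressed <- function(cpm, n = 500L) {
  mu <- rowMeans(cpm)
  o <- order(-mu, rownames(cpm))
  out <- data.frame(feature_id = rownames(cpm)[o], mean_cpm = mu[o],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Tandem Mann-Whitney specificity test against two control cohorts
#'
#' Features must show CPM of at least `min_cpm` in at least
#' `ceil(prevalence * n_cohort)` focal-cohort samples to enter testing.
#' Each remaining feature is tested one-sided (cohort greater) against each
#' control cohort; Benjamini-Hochberg adjustment is applied separately
#' within each of the two tests across features. A feature passes when both
#' adjusted values fall below `alpha`. The combined p-value is the sum of
#' the two unadjusted p-values (it may exceed 1 and is reported as-is).
#'
#' @param cohort,control1,control2 CPM matrices sharing a feature universe
#'   (features absent from a matrix are treated as all-zero).
#' @param prevalence focal-cohort prevalence fraction for the filter.
#' @param min_cpm CPM threshold of the prevalence filter.
#' @param alpha significance cutoff applied to the FDR-adjusted values.
#' @return data.frame: circ_id, p_vs_tumors, p_vs_normal, q_vs_tumors,
#'   q_vs_normal, combined_p, passed — one row per feature surviving the
#'   prevalence filter. The filtered-out features are in
#'   `attr(, "filtered")`.
#' @export
tandem_specificity_test <- function(cohort, control1, control2,
                                    prevalence = 0.30, min_cpm = 1,
                                    alpha = 0.001) {
  if (length(control1) == 0 || length(control2) == 0 ||
      is.null(ncol(control1)) || is.null(ncol(control2)) ||
      ncol(control1) == 0 || ncol(control2) == 0)
    stop("tandem_specificity_test: empty control cohort")
  features <- sort(unique(c(rownames(cohort), rownames(control1),
                            rownames(control2))))
  fill <- function(m) {
    out <- matrix(0, length(features), ncol(m),
                  dimnames = list(features, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  cohort <- fill(cohort); control1 <- fill(control1)
  control2 <- fill(control2)
  need <- ceiling(prevalence * ncol(cohort))
  tested <- rowSums(cohort >= min_cpm) >= need
  if (!any(tested)) {
    res <- data.frame(circ_id = character(0))
    attr(res, "filtered") <- features
    return(res)
  }
  idx <- which(tested)
  p1 <- p2 <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    p1[k] <- mw_test(cohort[i, ], control1[i, ],
                     alternative = "greater")$p.value
    p2[k] <- mw_test(cohort[i, ], control2[i, ],
                     alternative = "greater")$p.value
  }
  q1 <- stats::p.adjust(p1, method = "BH")
  q2 <- stats::p.adjust(p2, method = "BH")
  res <- data.frame(
    circ_id = features[idx],
    p_vs_tumors = p1, p_vs_normal = p2,
    q_vs_tumors = q1, q_vs_normal = q2,
    combined_p = p1 + p2,
    passed = q1 < alpha & q2 < alpha,
    stringsAsFactors = FALSE)
  attr(res, "filtered") <- features[!tested]
  res
}
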