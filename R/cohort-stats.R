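# Cohort-level statistics: proliferative index, clustering conventions,
# RBP-circRNA correlation clustering, gene-based size factors, and
# percentile-group differential comparisons.

#' Proliferative index per sample
#'
#' PI = median over the signature genes of log2(TPM + 1). Samples are
#' hierarchically clustered on the 1-D PI (Euclidean distance, complete
#' linkage) and the tree cut at two clusters, labeled high/low by mean PI.
#'
#' @param tpm TPM matrix (gene x sample).
#' @param signature character vector of signature gene ids; genes missing
#'   from the matrix are reported in `attr(, "missing")`.
#' @return data.frame: sample_id, pi, cluster ("high"/"low"); degenerate
#'   splits (all PIs identical) are flagged in `attr(, "degenerate")`.
#' @export
proliferative_index <- function(tpm, signature) {
  present <- intersect(signature, rownames(tpm))
  if (length(present) == 0)
    stop("proliferative_index: no signature gene present in the matrix")
  missing <- setdiff(signature, present)
  pi_val <- apply(log2(tpm[present, , drop = FALSE] + 1), 2, stats::median)
  degenerate <- length(unique(pi_val)) == 1L
  if (degenerate) {
    cluster <- rep("high", length(pi_val))
  } else {
    hc <- stats::hclust(stats::dist(pi_val), method = "complete")
    k2 <- stats::cutree(hc, k = 2)
    hi <- which.max(tapply(pi_val, k2, mean))
    cluster <- ifelse(k2 == as.integer(names(hi)), "high", "low")
  }
  out <- data.frame(sample_id = colnames(tpm), pi = as.numeric(pi_val),
                    cluster = cluster, stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  attr(out, "degenerate") <- degenerate
  out
}

#' Hierarchical clustering of samples by circRNA expression
#'
#' Read density is corrected per sample by dividing by the column sum;
#' z-scores are then computed per feature across samples (zero-variance
#' features are excluded and reported). Samples (columns) are clustered
#' with Manhattan distance and features (rows) with Canberra distance,
#' complete linkage.
#'
#' @param counts circRNA count matrix (feature x sample), >= 3 samples.
#' @param k optional number of sample clusters to cut.
#' @return list: `z` (z-score matrix), `sample_tree`, `feature_tree`,
#'   `clusters` (named cut labels if `k` given), `excluded` (zero-variance
#'   features).
#' @export
cluster_samples_by_circ <- function(counts, k = NULL) {
  if (ncol(counts) < 3L)
    stop("cluster_samples_by_circ: at least three samples required")
  prop <- sweep(counts, 2L, colSums(counts), "/")
  sds <- apply(prop, 1L, stats::sd)
  excluded <- rownames(prop)[sds == 0 | is.na(sds)]
  keep <- !(rownames(prop) %in% excluded)
  z <- t(scale(t(prop[keep, , drop = FALSE])))
  if (nrow(z) == 0) {
    # nothing left to cluster on (e.g. a single feature, constant after
    # proportion normalization): degenerate, not an error
    return(list(z = z, sample_tree = NULL, feature_tree = NULL,
                clusters = NULL, excluded = excluded))
  }
  sample_tree <- stats::hclust(stats::dist(t(z), method = "manhattan"),
                               method = "complete")
  feature_tree <- if (nrow(z) > 1L)
    stats::hclust(stats::dist(z, method = "canberra"), method = "complete")
  else NULL
  clusters <- if (!is.null(k)) stats::cutree(sample_tree, k = k) else NULL
  list(z = z, sample_tree = sample_tree, feature_tree = feature_tree,
       clusters = clusters, excluded = excluded)
}

#' RBP-circRNA correlation clustering
#'
#' Spearman correlations (average-rank ties) between each RBP's and each
#' circRNA's expression across shared samples, hierarchically clustered by
#' the Euclidean distance of the coefficient rows/columns (complete
#' linkage). For a requested cut, the number of strong correlations in each
#' (RBP cluster, circ cluster) block is normalized by the product of the
#' cluster sizes.
#'
#' @param rbp,circ expression matrices (feature x sample) sharing samples.
#' @param k_rbp,k_circ cluster counts for the block summary (optional).
#' @param rho_min correlation magnitude counted as strong.
#' @return list: `rho` (RBP x circ Spearman matrix), `rbp_tree`,
#'   `circ_tree`, `blocks` (normalized strong-correlation counts, when cuts
#'   requested), `excluded` (constant features).
#' @export
rbp_circ_cluster <- function(rbp, circ, k_rbp = NULL, k_circ = NULL,
                             rho_min = 0.3) {
  shared <- intersect(colnames(rbp), colnames(circ))
  stopifnot(length(shared) >= 3)
  rbp <- rbp[, shared, drop = FALSE]; circ <- circ[, shared, drop = FALSE]
  const_r <- apply(rbp, 1, function(x) stats::sd(x) == 0)
  const_c <- apply(circ, 1, function(x) stats::sd(x) == 0)
  excluded <- c(rownames(rbp)[const_r], rownames(circ)[const_c])
  rbp <- rbp[!const_r, , drop = FALSE]; circ <- circ[!const_c, , drop = FALSE]
  rho <- stats::cor(t(rbp), t(circ), method = "spearman")
  rbp_tree <- if (nrow(rho) > 1)
    stats::hclust(stats::dist(rho), method = "complete") else NULL
  circ_tree <- if (ncol(rho) > 1)
    stats::hclust(stats::dist(t(rho)), method = "complete") else NULL
  blocks <- NULL
  if (!is.null(k_rbp) && !is.null(k_circ) && !is.null(rbp_tree) &&
      !is.null(circ_tree)) {
    cr <- stats::cutree(rbp_tree, k = k_rbp)
    cc <- stats::cutree(circ_tree, k = k_circ)
    blocks <- matrix(0, k_rbp, k_circ)
    for (i in seq_len(k_rbp)) for (j in seq_len(k_circ)) {
      blk <- rho[cr == i, cc == j, drop = FALSE]
      blocks[i, j] <- sum(abs(blk) >= rho_min) / (sum(cr == i) * sum(cc == j))
    }
  }
  list(rho = rho, rbp_tree = rbp_tree, circ_tree = circ_tree,
       blocks = blocks, excluded = excluded)
}

#' Median-of-ratios size factors from gene counts
#'
#' Size factors for circRNA normalization are determined from gene counts,
#' not circRNA counts, so that global shifts in circRNA expression are not
#' normalized away. Reference = per-gene geometric mean over samples (genes
#' with any zero excluded); factor = per-sample median over genes of
#' count / reference.
#'
#' @param gene_counts gene count matrix (gene x sample).
#' @return named numeric vector of positive size factors.
#' @export
gene_size_factors <- function(gene_counts) {
  usable <- rowSums(gene_counts == 0) == 0
  if (!any(usable))
    stop("gene_size_factors: no gene with nonzero counts in every sample")
  m <- gene_counts[usable, , drop = FALSE]
  log_ref <- rowMeans(log(m))
  apply(m, 2, function(col) exp(stats::median(log(col) - log_ref)))
}

#' Divide a count matrix by per-sample size factors
#'
#' @param counts feature x sample matrix.
#' @param factors named factors from [gene_size_factors()].
#' @return normalized matrix.
#' @export
normalize_counts <- function(counts, factors) {
  stopifnot(all(colnames(counts) %in% names(factors)))
  sweep(counts, 2L, factors[colnames(counts)], "/")
}

#' Percentile-group differential comparison
#'
#' Samples strictly above the `hi`-th percentile of the expression vector
#' form the high group, samples strictly below the `lo`-th percentile the
#' low group (linear-interpolation percentiles). Features with fewer than
#' `min_total` summed reads are prefiltered. Each remaining feature is
#' compared between groups with a two-sided rank test on size-factor
#' normalized counts, BH-adjusted; counts of significantly up vs down
#' features are compared to a 50:50 null with a chi-squared test.
#'
#' @param expression named numeric vector (e.g. a driver gene's expression
#'   per sample).
#' @param counts feature x sample count matrix.
#' @param size_factors optional per-sample factors (default: gene-based
#'   factors must be supplied by the caller; `NULL` leaves counts as-is).
#' @param hi,lo percentile cutoffs (0-100), `hi > lo`.
#' @param fdr FDR cutoff for calling a feature differential.
#' @param min_total minimum summed raw reads per feature.
#' @return list: `table` (per-feature p, q, log2 fold change high/low,
#'   direction), `groups` (sample lists), `n_up`, `n_down`, `chisq_p`.
#' @export
percentile_group_compare <- function(expression, counts, size_factors = NULL,
                                     hi = 80, lo = 20, fdr = 0.05,
                                     min_total = 5L) {
  if (hi <= lo) stop("percentile_group_compare: hi must exceed lo")
  qs <- stats::quantile(expression, c(hi, lo) / 100, type = 7)
  high <- names(expression)[expression > qs[1]]
  low <- names(expression)[expression < qs[2]]
  if (length(high) == 0 || length(low) == 0)
    stop("percentile_group_compare: empty percentile group")
  keep <- rowSums(counts) >= min_total
  m <- counts[keep, , drop = FALSE]
  if (!is.null(size_factors)) m <- normalize_counts(m, size_factors)
  p <- lfc <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    xh <- m[i, high]; xl <- m[i, low]
    p[i] <- if (stats::sd(c(xh, xl)) == 0) 1 else
      mw_test(xh, xl, alternative = "two.sided")$p.value
    lfc[i] <- log2((mean(xh) + 0.5) / (mean(xl) + 0.5))
  }
  q <- stats::p.adjust(p, "BH")
  sig <- q < fdr
  direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  n_up <- sum(direction == "up"); n_down <- sum(direction == "down")
  chisq_p <- if (n_up + n_down > 0)
    suppressWarnings(stats::chisq.test(c(n_up, n_down),
                                       p = c(0.5, 0.5))$p.value)
  else NA_real_
  list(table = data.frame(feature_id = rownames(m), p.value = p, q.value = q,
                          log2fc = lfc, direction = direction,
                          stringsAsFactors = FALSE, row.names = NULL),
       groups = list(high = high, low = low),
       n_up = n_up, n_down = n_down, chisq_p = chisq_p)
}
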