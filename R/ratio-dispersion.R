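# Circular:linear expression ratios, group comparison of their pooled
# distributions, circRNA-productive gene calls, and Fano-factor dispersion.

#' Per-gene circ:linear expression ratios
#'
#' Circular and linear expression are averaged across a gene's circRNA
#' isoforms before the ratio is taken (avoiding isoform-specific biases).
#' Gene x sample records with zero linear expression get an absent (`NA`)
#' ratio and are reported separately by the callers.
#'
#' @param summary data.frame from [summarize_bsj_linear()].
#' @param linear which linear mean enters the ratio: the mean over all of
#'   the gene's linear junctions (default) or over external junctions only.
#' @return data.frame: gene_id, sample_id, circ_expr, linear_expr, ratio.
#' @export
circ_linear_ratio <- function(summary, linear = c("all", "external")) {
  linear <- match.arg(linear)
  lcol <- if (linear == "all") "linear_all_mean" else "linear_external_mean"
  key <- interaction(summary$gene_id, summary$sample_id, drop = TRUE)
  agg <- data.frame(
    gene_id = tapply(summary$gene_id, key, `[`, 1L),
    sample_id = tapply(summary$sample_id, key, `[`, 1L),
    circ_expr = as.numeric(tapply(summary$bsj, key, mean)),
    linear_expr = as.numeric(tapply(summary[[lcol]], key,
                                    function(x) mean(x, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  agg$linear_expr[is.nan(agg$linear_expr)] <- NA_real_
  agg$ratio <- ifelse(!is.na(agg$linear_expr) & agg$linear_expr > 0,
                      agg$circ_expr / agg$linear_expr, NA_real_)
  rownames(agg) <- NULL
  agg
}

#' Compare pooled circ:linear ratio distributions between two groups
#'
#' Pools the finite gene x sample ratios of each group and compares the two
#' distributions with a two-sided Mann-Whitney U test (exact enumeration
#' when both pooled sizes are at most 8, tie-corrected normal approximation
#' otherwise). ECDF curves are returned as (x, F) point pairs.
#'
#' @param ratios data.frame from [circ_linear_ratio()].
#' @param group_labels named character vector mapping sample_id to group;
#'   exactly two groups must be present.
#' @return list: `p.value`, `statistic` (U of the first group),
#'   `direction` (group with the lower median ratio), `medians`, `n`, and
#'   `ecdf` (named list of data.frames).
#' @export
compare_ratio_distributions <- function(ratios, group_labels) {
  grp <- group_labels[ratios$sample_id]
  if (anyNA(grp))
    stop("compare_ratio_distributions: samples without a group label")
  groups <- sort(unique(grp))
  if (length(groups) != 2L)
    stop("compare_ratio_distributions: exactly two groups required")
  pools <- lapply(groups, function(g) {
    x <- ratios$ratio[grp == g]
    x[is.finite(x)]
  })
  names(pools) <- groups
  if (any(lengths(pools) == 0))
    stop("compare_ratio_distributions: a group has zero ratios")
  tst <- mw_test(pools[[1]], pools[[2]], alternative = "two.sided")
  med <- vapply(pools, stats::median, numeric(1))
  list(p.value = tst$p.value, statistic = tst$statistic,
       direction = names(which.min(med)), medians = med,
       n = lengths(pools),
       ecdf = lapply(pools, ecdf_points))
}

#' Call circRNA-productive genes
#'
#' A gene is productive when its ratio of expressed circRNA isoforms to
#' expressed mRNA isoforms strictly exceeds `threshold`. Genes with zero
#' expressed mRNA isoforms are excluded from calling and reported.
#'
#' @param iso_counts data.frame with columns gene_id, circ_isoforms,
#'   mrna_isoforms (see [count_expressed_isoforms()]).
#' @param threshold productivity cutoff (strict >).
#' @return list: `genes` (gene_id, circ_isoforms, mrna_isoforms, ratio,
#'   productive) and `excluded` (genes with zero mRNA isoforms).
#' @export
call_productive_genes <- function(iso_counts, threshold = 1.2) {
  stopifnot(all(c("gene_id", "circ_isoforms", "mrna_isoforms") %in%
                  colnames(iso_counts)))
  excl <- iso_counts$mrna_isoforms == 0
  genes <- iso_counts[!excl, , drop = FALSE]
  genes$ratio <- genes$circ_isoforms / genes$mrna_isoforms
  genes$productive <- genes$ratio > threshold
  rownames(genes) <- NULL
  list(genes = genes, excluded = iso_counts[excl, , drop = FALSE])
}

#' Count expressed circRNA and mRNA isoforms per gene
#'
#' A circRNA isoform is expressed with at least one back-splice read in at
#' least one sample; an mRNA isoform with abundance of at least `min_tpm`
#' TPM in at least one sample.
#'
#' @param bsj back-splice count matrix (circ isoform x sample).
#' @param circ_gene named vector mapping circ isoform to gene_id.
#' @param tpm transcript TPM matrix (transcript x sample).
#' @param tx_gene named vector mapping transcript to gene_id.
#' @param min_tpm expression threshold for mRNA isoforms.
#' @return data.frame: gene_id, circ_isoforms, mrna_isoforms.
#' @export
count_expressed_isoforms <- function(bsj, circ_gene, tpm, tx_gene,
                                     min_tpm = 1) {
  circ_on <- rowSums(bsj >= 1) >= 1
  mrna_on <- rowSums(tpm >= min_tpm) >= 1
  genes <- sort(unique(c(circ_gene, tx_gene)))
  nc <- table(factor(circ_gene[rownames(bsj)][circ_on], levels = genes))
  nm <- table(factor(tx_gene[rownames(tpm)][mrna_on], levels = genes))
  data.frame(gene_id = genes, circ_isoforms = as.integer(nc),
             mrna_isoforms = as.integer(nm), stringsAsFactors = FALSE)
}

#' Fano-factor dispersion of count features
#'
#' Per isoform, the Fano factor is the sample variance (n - 1 denominator)
#' divided by the sample mean of its counts across samples; it is absent
#' when the mean is zero. Isoform factors are averaged per feature, and the
#' circular vs linear feature distributions are compared with a two-sided
#' rank test.
#'
#' @param counts count matrix (isoform x sample), at least two samples.
#' @param feature_map data.frame with columns isoform_id, feature_id, kind
#'   (`circ` or `linear`); isoforms must be rows of `counts`.
#' @return list: `records` (feature_id, kind, fano), `isoforms` (per-isoform
#'   factors), and `comparison` (rank-test p and medians, when both kinds
#'   are present).
#' @export
fano_factor <- function(counts, feature_map) {
  if (ncol(counts) < 2L)
    stop("fano_factor: at least two samples required")
  stopifnot(all(feature_map$isoform_id %in% rownames(counts)))
  m <- counts[feature_map$isoform_id, , drop = FALSE]
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  fan <- ifelse(mu > 0, v / mu, NA_real_)
  iso <- data.frame(isoform_id = feature_map$isoform_id,
                    feature_id = feature_map$feature_id,
                    kind = feature_map$kind, fano = fan,
                    stringsAsFactors = FALSE)
  ok <- !is.na(iso$fano)
  key <- paste(iso$feature_id, iso$kind, sep = "\r")[ok]
  agg <- tapply(iso$fano[ok], key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  records <- data.frame(
    feature_id = vapply(parts, `[[`, "", 1L),
    kind = vapply(parts, `[[`, "", 2L),
    fano = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  comparison <- NULL
  if (all(c("circ", "linear") %in% records$kind)) {
    fc <- records$fano[records$kind == "circ"]
    fl <- records$fano[records$kind == "linear"]
    tst <- mw_test(fc, fl, alternative = "two.sided")
    comparison <- list(p.value = tst$p.value,
                       median_circ = stats::median(fc),
                       median_linear = stats::median(fl))
  }
  list(records = records, isoforms = iso, comparison = comparison)
}
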