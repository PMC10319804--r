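# Confident circRNA catalog: CIRI2-style parsing, blacklist and expression
# filters, annotation matching with 1-bp boundary tolerance.

#' Read a CIRI2-style back-splice prediction table
#'
#' Expects a TSV with (at least) the columns `circRNA_ID`, `chr`,
#' `circRNA_start`, `circRNA_end`, `junction_reads`, `strand`,
#' `circRNA_type`; extra columns are ignored. Coordinates are 1-based
#' inclusive. Malformed rows (end < start, negative counts) are dropped and
#' reported with their line numbers.
#'
#' @param path TSV file path.
#' @param sample_id sample the junction read counts belong to; defaults to
#'   the file name stem.
#' @return a `circ_candidates` object: list with `table` (one row per
#'   candidate: circ_id, chrom, start, end, strand, circ_type) and `counts`
#'   (candidate x sample integer matrix). Rejected rows are in
#'   `attr(, "malformed")`.
#' @export
read_ciri2 <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(ciri2\\.)?tsv$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
            "junction_reads", "strand", "circRNA_type")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0)
    stop("read_ciri2: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df$circRNA_start <- suppressWarnings(as.integer(df$circRNA_start))
  df$circRNA_end <- suppressWarnings(as.integer(df$circRNA_end))
  df$junction_reads <- suppressWarnings(as.integer(df$junction_reads))
  bad <- is.na(df$circRNA_start) | is.na(df$circRNA_end) |
    is.na(df$junction_reads) | df$junction_reads < 0 |
    df$circRNA_end < df$circRNA_start |
    !df$strand %in% c("+", "-", ".")
  malformed <- data.frame(line = which(bad) + 1L,
                          circRNA_ID = df$circRNA_ID[bad],
                          stringsAsFactors = FALSE)
  if (nrow(malformed) > 0)
    warning("read_ciri2: dropped ", nrow(malformed), " malformed row(s) in ",
            basename(path), " (lines ",
            paste(utils::head(malformed$line, 5), collapse = ", "), ")")
  df <- df[!bad, , drop = FALSE]
  tab <- data.frame(
    circ_id = sprintf("%s:%d-%d:%s", df$chr, df$circRNA_start,
                      df$circRNA_end, df$strand),
    chrom = df$chr, start = df$circRNA_start, end = df$circRNA_end,
    strand = df$strand, circ_type = df$circRNA_type,
    stringsAsFactors = FALSE)
  counts <- matrix(df$junction_reads, ncol = 1,
                   dimnames = list(tab$circ_id, sample_id))
  structure(list(table = tab, counts = counts),
            class = "circ_candidates", malformed = malformed)
}

#' Merge per-sample candidate sets into one cohort set
#'
#' Candidates are keyed by (chrom, start, end, strand); a candidate absent
#' from a sample's table gets count 0 in that sample.
#'
#' @param cands list of `circ_candidates` (one per sample).
#' @return a single `circ_candidates` with a full candidate x sample count
#'   matrix.
#' @export
merge_candidates <- function(cands) {
  stopifnot(length(cands) > 0)
  tabs <- do.call(rbind, lapply(cands, `[[`, "table"))
  tab <- tabs[!duplicated(tabs$circ_id), , drop = FALSE]
  tab <- tab[order(tab$circ_id), , drop = FALSE]
  rownames(tab) <- NULL
  samples <- unlist(lapply(cands, function(x) colnames(x$counts)))
  if (anyDuplicated(samples))
    stop("merge_candidates: duplicated sample ids")
  counts <- matrix(0L, nrow(tab), length(samples),
                   dimnames = list(tab$circ_id, samples))
  for (x in cands)
    counts[rownames(x$counts), colnames(x$counts)] <- x$counts
  structure(list(table = tab, counts = counts), class = "circ_candidates")
}

subset_candidates <- function(cands, keep) {
  structure(list(table = cands$table[keep, , drop = FALSE],
                 counts = cands$counts[keep, , drop = FALSE]),
            class = "circ_candidates")
}

#' Remove candidates outside the primary chromosome set
#'
#' Drops predictions on chrM, chrY, and any contig not in the declared
#' primary-chromosome set (unplaced/alt contigs).
#'
#' @param cands a `circ_candidates`.
#' @param chroms character vector of allowed chromosome names; defaults to
#'   the GRCh38 primary autosomes plus chrX.
#' @return filtered `circ_candidates`.
#' @export
filter_blacklist <- function(cands,
                             chroms = paste0("chr", c(1:22, "X"))) {
  keep <- cands$table$chrom %in% setdiff(chroms, c("chrM", "chrY"))
  subset_candidates(cands, keep)
}

#' Expression filter for the confident set
#'
#' A candidate is kept iff it is expressed (count >= 1) in at least
#' `ceil(min_fraction * n_samples)` samples, OR its back-splice junction is
#' supported by at least `min_reads` reads in at least
#' `min_support_samples` samples.
#'
#' @param cands a `circ_candidates` with cohort-wide counts.
#' @param n_samples cohort size; defaults to the number of count columns.
#' @param min_fraction expression-prevalence branch fraction.
#' @param min_reads,min_support_samples read-support branch thresholds.
#' @return filtered `circ_candidates`.
#' @export
filter_expression <- function(cands, n_samples = ncol(cands$counts),
                              min_fraction = 0.25, min_reads = 20L,
                              min_support_samples = 3L) {
  if (n_samples == 0)
    stop("filter_expression: n_samples must be positive")
  expressed_in <- rowSums(cands$counts >= 1)
  supported_in <- rowSums(cands$counts >= min_reads)
  keep <- expressed_in >= ceiling(min_fraction * n_samples) |
    supported_in >= min_support_samples
  subset_candidates(cands, keep)
}

#' Match candidates to the gene annotation
#'
#' A candidate is accepted when a single gene has an exon boundary within
#' `tol` nt of each candidate end (acceptor 5' boundary and donor 3'
#' boundary in transcript orientation), both exons in that same gene.
#' Unstranded (".") candidates are matched against both strands; ties are
#' broken by smaller total boundary discrepancy, then lexicographic gene id.
#' Rejections carry a reason: `no-gene` (no exon boundary matches either
#' end), `cross-gene` (the two ends match exons of different genes only), or
#' `boundary` (a gene matches one end but not the other within `tol`).
#'
#' @param cands a `circ_candidates`.
#' @param annotation exon table (see [generate_annotation()] / [read_gtf()]).
#' @param tol boundary tolerance in nt.
#' @return list with `confident` (data.frame: circ_id, gene_id, coordinates,
#'   acceptor/donor exon numbers and intervals, per-end discrepancies,
#'   isoform_index), `rejected` (circ_id, reason), and `counts` (matrix for
#'   the confident rows).
#' @export
annotate_candidates <- function(cands, annotation, tol = 1L) {
  tab <- cands$table
  conf <- vector("list", nrow(tab))
  rej <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cand <- tab[i, ]
    strands <- if (cand$strand == ".") c("+", "-") else cand$strand
    ex <- annotation[annotation$chrom == cand$chrom &
                     annotation$strand %in% strands, , drop = FALSE]
    if (nrow(ex) == 0) { rej[i] <- "no-gene"; next }
    # genomic-left boundary matches exon starts, genomic-right matches ends
    d_start <- abs(ex$start - cand$start)
    d_end <- abs(ex$end - cand$end)
    left_ok <- d_start <= tol
    right_ok <- d_end <= tol
    if (!any(left_ok) && !any(right_ok)) { rej[i] <- "no-gene"; next }
    genes_left <- unique(ex$gene_id[left_ok])
    genes_right <- unique(ex$gene_id[right_ok])
    shared <- intersect(genes_left, genes_right)
    if (length(shared) == 0) {
      rej[i] <- if (length(genes_left) > 0 && length(genes_right) > 0)
        "cross-gene" else "boundary"
      next
    }
    # best exon pair per shared gene; ties by discrepancy then gene id
    best <- NULL
    for (g in sort(shared)) {
      gl <- which(left_ok & ex$gene_id == g)
      gr <- which(right_ok & ex$gene_id == g)
      li <- gl[which.min(d_start[gl])]
      ri <- gr[which.min(d_end[gr])]
      disc <- d_start[li] + d_end[ri]
      if (is.null(best) || disc < best$disc) {
        best <- list(g = g, li = li, ri = ri, disc = disc,
                     strand = ex$strand[li])
      }
    }
    left_ex <- ex[best$li, ]; right_ex <- ex[best$ri, ]
    plus <- best$strand == "+"
    conf[[i]] <- data.frame(
      circ_id = cand$circ_id, gene_id = best$g,
      chrom = cand$chrom, start = cand$start, end = cand$end,
      strand = best$strand,
      acceptor_exon = if (plus) left_ex$exon_number else right_ex$exon_number,
      donor_exon = if (plus) right_ex$exon_number else left_ex$exon_number,
      acceptor_start = if (plus) left_ex$start else right_ex$start,
      acceptor_end = if (plus) left_ex$end else right_ex$end,
      donor_start = if (plus) right_ex$start else left_ex$start,
      donor_end = if (plus) right_ex$end else left_ex$end,
      disc_start = cand$start - left_ex$start,
      disc_end = cand$end - right_ex$end,
      stringsAsFactors = FALSE)
  }
  ok <- !vapply(conf, is.null, logical(1))
  confident <- do.call(rbind, conf[ok])
  if (is.null(confident))
    confident <- data.frame(circ_id = character(0), gene_id = character(0))
  else {
    confident <- confident[order(confident$gene_id, confident$circ_id), ]
    confident$isoform_index <- stats::ave(
      seq_len(nrow(confident)), confident$gene_id, FUN = seq_along)
    rownames(confident) <- NULL
  }
  rejected <- data.frame(circ_id = tab$circ_id[!ok], reason = rej[!ok],
                         stringsAsFactors = FALSE)
  list(confident = confident, rejected = rejected,
       counts = cands$counts[ok, , drop = FALSE])
}

#' Catalog summary statistics
#'
#' Per-gene circRNA isoform counts, per-circRNA exon counts (annotated exons
#' between acceptor and donor inclusive, after overlap resolution), and
#' acceptor-exon region class tallies. The region class (CDS / 3'UTR /
#' noncoding) is taken from the annotation's `region` column when present,
#' else every circRNA is tallied noncoding.
#'
#' @param confident confident-set data.frame from [annotate_candidates()].
#' @param annotation exon table.
#' @return list with `isoforms_per_gene`, `exons_per_circ`, and
#'   `acceptor_region` data.frames.
#' @export
catalog_stats <- function(confident, annotation) {
  if (nrow(confident) == 0)
    return(list(isoforms_per_gene = data.frame(),
                exons_per_circ = data.frame(),
                acceptor_region = data.frame()))
  ipg <- as.data.frame(table(gene_id = confident$gene_id),
                       stringsAsFactors = FALSE)
  names(ipg)[2] <- "n_isoforms"
  n_ex <- integer(nrow(confident))
  region <- character(nrow(confident))
  has_region <- "region" %in% colnames(annotation)
  for (i in seq_len(nrow(confident))) {
    ch <- exons_in_span(annotation, confident$gene_id[i],
                        confident$start[i], confident$end[i])
    n_ex[i] <- nrow(ch)
    if (has_region) {
      plus <- confident$strand[i] == "+"
      acc <- annotation[annotation$gene_id == confident$gene_id[i] &
                        annotation$exon_number == confident$acceptor_exon[i], ]
      region[i] <- if (nrow(acc) > 0) acc$region[1] else "noncoding"
    } else region[i] <- "noncoding"
  }
  list(isoforms_per_gene = ipg,
       exons_per_circ = data.frame(circ_id = confident$circ_id,
                                   n_exons = n_ex,
                                   stringsAsFactors = FALSE),
       acceptor_region = as.data.frame(table(region = region),
                                       stringsAsFactors = FALSE))
}

#' Read an exon annotation from GTF
#'
#' Imports a GENCODE-dialect GTF and returns the package's exon table.
#' Exon numbers are taken from the `exon_number` attribute when present,
#' else assigned in transcript (5' to 3') order. When CDS / UTR features are
#' present, each exon gets a `region` class (CDS, 3UTR, or noncoding) from
#' the first transcript in annotation order.
#'
#' @param path GTF file path.
#' @return exon data.frame: gene_id, transcript_id, exon_number, chrom,
#'   start, end, strand (plus `region` when derivable).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  df <- data.frame(
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  if (!is.null(ex$exon_number)) {
    df$exon_number <- as.integer(as.character(ex$exon_number))
  }
  if (is.null(df$exon_number) || anyNA(df$exon_number)) {
    df$exon_number <- NA_integer_
    for (tx in split(seq_len(nrow(df)), df$transcript_id)) {
      o <- order(df$start[tx])
      if (df$strand[tx[1]] == "-") o <- rev(o)
      df$exon_number[tx[o]] <- seq_along(tx)
    }
  }
  cds <- gr[gr$type == "CDS"]
  utr3 <- gr[gr$type %in% c("three_prime_utr", "three_prime_UTR")]
  if (length(cds) > 0 || length(utr3) > 0) {
    exr <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start, df$end))
    df$region <- "noncoding"
    if (length(utr3) > 0)
      df$region[IRanges::overlapsAny(exr, utr3)] <- "3UTR"
    if (length(cds) > 0)
      df$region[IRanges::overlapsAny(exr, cds)] <- "CDS"
  }
  df[order(df$gene_id, df$transcript_id, df$exon_number), , drop = FALSE]
}
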