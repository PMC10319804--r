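# Putative circRNA sequences, length-matched control sequences, flanking
# and control intron selection, and Alu-overlap enrichment.

# annotated exons of a gene lying within a genomic span (1-bp tolerance for
# preserved boundary discrepancies), overlap-resolved by keeping the longest
# exon (ties: leftmost), clipped to the span, ordered by genomic position
exons_in_span <- function(annotation, gene_id, span_start, span_end) {
  ex <- annotation[annotation$gene_id == gene_id &
                     annotation$start >= span_start - 1L &
                     annotation$end <= span_end + 1L, , drop = FALSE]
  ex <- ex[!duplicated(ex[c("start", "end")]), , drop = FALSE]
  if (nrow(ex) == 0) return(ex)
  ex$start <- pmax(ex$start, span_start)
  ex$end <- pmin(ex$end, span_end)
  len <- ex$end - ex$start + 1L
  o <- order(-len, ex$start)
  kept <- logical(nrow(ex))
  for (i in o) {
    if (!any(kept & ex$start <= ex$end[i] & ex$end >= ex$start[i]))
      kept[i] <- TRUE
  }
  ex <- ex[kept, , drop = FALSE]
  ex[order(ex$start), , drop = FALSE]
}

# splice a set of exon rows into a strand-oriented sequence
splice_exons <- function(ex, genome) {
  if (nrow(ex) == 0) return("")
  pieces <- mapply(function(s, e) seq_range(genome, ex$chrom[1], s, e, "+"),
                   ex$start, ex$end)
  seqs <- paste(pieces, collapse = "")
  if (ex$strand[1] == "-")
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs)))
  seqs
}

#' Putative circRNA sequence
#'
#' Splices together all annotated exons of the matched gene lying between
#' the back-splice junction (acceptor and donor exons included). Overlapping
#' exon variants are resolved by keeping the longest (ties: leftmost).
#' Boundary discrepancies of the candidate (up to 1 bp) are preserved: the
#' span boundaries are the candidate's coordinates, not the annotation's.
#'
#' @param circ one confident-set row.
#' @param annotation exon table.
#' @param genome `Biostrings::DNAStringSet`.
#' @return list: `sequence` (5' to 3' in transcript orientation) and
#'   `exon_chain` (exon rows in genomic order).
#' @export
build_circ_sequence <- function(circ, annotation, genome) {
  ch <- exons_in_span(annotation, circ$gene_id, circ$start, circ$end)
  if (nrow(ch) == 0)
    stop("build_circ_sequence: no annotated exons in span of ", circ$circ_id)
  list(sequence = splice_exons(ch, genome), exon_chain = ch)
}

#' Length-matched control sequence for a circRNA
#'
#' Splices all gene exons strictly upstream of the acceptor and, separately,
#' all strictly downstream of the donor (transcript orientation); the longer
#' spliced product is the control. If longer than the circRNA sequence it is
#' symmetrically trimmed (`floor(excess/2)` from the start, `ceil(excess/2)`
#' from the end); if both sides are shorter, the longer one is returned
#' unpadded and flagged length-mismatched.
#'
#' @param circ one confident-set row.
#' @param annotation exon table.
#' @param genome `Biostrings::DNAStringSet`.
#' @param circ_len length of the circRNA sequence to match.
#' @return list: `sequence` (or `NA` when the gene has no exons outside the
#'   span), `side` (upstream/downstream), `length_matched` (logical).
#' @export
build_control_sequence <- function(circ, annotation, genome, circ_len) {
  gx <- annotation[annotation$gene_id == circ$gene_id, , drop = FALSE]
  plus <- circ$strand == "+"
  left <- gx[gx$end < circ$start, , drop = FALSE]   # genomic left of span
  right <- gx[gx$start > circ$end, , drop = FALSE]  # genomic right of span
  up <- if (plus) left else right    # transcript-upstream of acceptor
  dn <- if (plus) right else left    # transcript-downstream of donor
  splice_side <- function(side) {
    if (nrow(side) == 0) return("")
    side <- side[!duplicated(side[c("start", "end")]), , drop = FALSE]
    len <- side$end - side$start + 1L
    o <- order(-len, side$start)
    kept <- logical(nrow(side))
    for (i in o) {
      if (!any(kept & side$start <= side$end[i] & side$end >= side$start[i]))
        kept[i] <- TRUE
    }
    splice_exons(side[kept, , drop = FALSE][order(side$start[kept]), ,
                                            drop = FALSE], genome)
  }
  up_seq <- splice_side(up); dn_seq <- splice_side(dn)
  if (nchar(up_seq) == 0 && nchar(dn_seq) == 0)
    return(list(sequence = NA_character_, side = NA_character_,
                length_matched = FALSE))
  side <- if (nchar(up_seq) >= nchar(dn_seq)) "upstream" else "downstream"
  s <- if (side == "upstream") up_seq else dn_seq
  if (nchar(s) > circ_len) {
    excess <- nchar(s) - circ_len
    s <- substring(s, floor(excess / 2) + 1L,
                   nchar(s) - ceiling(excess / 2))
    matched <- TRUE
  } else matched <- nchar(s) == circ_len
  list(sequence = s, side = side, length_matched = matched)
}

#' Flanking and control introns of a circRNA
#'
#' The flanks are the longest intron upstream of the acceptor exon and the
#' longest downstream of the donor (transcript orientation; length >= 15 nt;
#' absent when none exists). Control introns are the gene's introns sorted
#' by decreasing length and greedily added while non-overlapping with the
#' circRNA span, the flanks, and previously chosen controls, until their
#' cumulative length reaches the flanks' cumulative length. No intron
#' splicing is performed: each control remains an independent interval.
#'
#' @param circ one confident-set row.
#' @param introns intron table from [annotation_introns()].
#' @param min_len minimum intron length (nt).
#' @return list of class `flank_set`: `circ_id`, `upstream`, `downstream`
#'   (single intron rows or `NULL`), `controls` (data.frame), `flank_cum`,
#'   `control_cum`.
#' @export
select_flanking_and_control_introns <- function(circ, introns,
                                                min_len = 15L) {
  gi <- introns[introns$gene_id == circ$gene_id &
                  introns$length >= min_len, , drop = FALSE]
  plus <- circ$strand == "+"
  left <- gi[gi$end < circ$start, , drop = FALSE]
  right <- gi[gi$start > circ$end, , drop = FALSE]
  up <- if (plus) left else right
  dn <- if (plus) right else left
  pick_longest <- function(x)
    if (nrow(x) == 0) NULL else x[which.max(x$length), , drop = FALSE]
  up_f <- pick_longest(up); dn_f <- pick_longest(dn)
  flank_cum <- sum(c(up_f$length, dn_f$length))

  taken <- rbind(
    data.frame(start = circ$start, end = circ$end),
    if (!is.null(up_f)) up_f[c("start", "end")],
    if (!is.null(dn_f)) dn_f[c("start", "end")])
  cand <- gi[order(-gi$length, gi$start), , drop = FALSE]
  controls <- cand[0, , drop = FALSE]
  cum <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cum >= flank_cum) break
    ci <- cand[i, ]
    if (any(taken$start <= ci$end & taken$end >= ci$start)) next
    controls <- rbind(controls, ci)
    taken <- rbind(taken, ci[c("start", "end")])
    cum <- cum + ci$length
  }
  structure(list(circ_id = circ$circ_id, upstream = up_f, downstream = dn_f,
                 controls = controls, flank_cum = flank_cum,
                 control_cum = cum), class = "flank_set")
}

flanks_to_granges <- function(flank_sets, what = c("upstream", "downstream",
                                                   "controls")) {
  rows <- do.call(rbind, lapply(flank_sets, function(fs) {
    part <- do.call(rbind, lapply(what, function(w) {
      x <- fs[[w]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      data.frame(chrom = x$chrom, start = x$start, end = x$end,
                 stringsAsFactors = FALSE)
    }))
    part
  }))
  if (is.null(rows)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end))
}

#' Alu-overlap enrichment of flanking vs control introns
#'
#' Per stratum (upstream flanks, downstream flanks, combined), counts the
#' introns intersecting at least one Alu interval (>= 1 bp overlap) against
#' the pooled control introns and computes a two-sided Fisher exact test on
#' the 2x2 table.
#'
#' @param flank_sets list of `flank_set` objects.
#' @param repeats `GenomicRanges::GRanges` of repeat intervals.
#' @return data.frame, one row per stratum: flank_alu, flank_total,
#'   control_alu, control_total, odds_ratio, p.value (`NA` for an empty
#'   stratum).
#' @export
alu_enrichment <- function(flank_sets, repeats) {
  ctrl <- flanks_to_granges(flank_sets, "controls")
  ctrl_alu <- if (length(ctrl) > 0)
    sum(IRanges::overlapsAny(ctrl, repeats, ignore.strand = TRUE)) else 0L
  strata <- list(upstream = "upstream", downstream = "downstream",
                 combined = c("upstream", "downstream"))
  rows <- lapply(names(strata), function(nm) {
    fl <- flanks_to_granges(flank_sets, strata[[nm]])
    fa <- if (length(fl) > 0)
      sum(IRanges::overlapsAny(fl, repeats, ignore.strand = TRUE)) else 0L
    tab <- matrix(c(fa, length(fl) - fa,
                    ctrl_alu, length(ctrl) - ctrl_alu), nrow = 2,
                  byrow = TRUE)
    p <- if (length(fl) == 0 || length(ctrl) == 0) NA_real_ else
      stats::fisher.test(tab)$p.value
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    data.frame(stratum = nm, flank_alu = fa, flank_total = length(fl),
               control_alu = ctrl_alu, control_total = length(ctrl),
               odds_ratio = or, p.value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare flanking-intron lengths against control-intron lengths
#'
#' @param flank_sets list of `flank_set` objects.
#' @return list: mean_flank, mean_control, p.value (two-sided rank test),
#'   and the two length vectors.
#' @export
intron_length_compare <- function(flank_sets) {
  fl <- unlist(lapply(flank_sets, function(fs)
    c(fs$upstream$length, fs$downstream$length)))
  ct <- unlist(lapply(flank_sets, function(fs) fs$controls$length))
  if (length(fl) == 0)
    stop("intron_length_compare: empty circRNA flank set")
  tst <- mw_test(fl, ct, alternative = "two.sided")
  list(mean_flank = mean(fl), mean_control = mean(ct),
       p.value = tst$p.value, flank_lengths = fl, control_lengths = ct)
}
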