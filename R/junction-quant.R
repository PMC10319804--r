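# Junction pseudo-reference and junction-spanning read-pair counting.
# Back-spliced junction contigs are 160 nt (80 nt of donor-exon 3' end
# spliced to 80 nt of acceptor-exon 5' start); linear junction contigs keep
# the full exon pair so an aligner prefers them for reads without a
# back-splice.

# strand-oriented genome slice (reverse complement on '-')
seq_range <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome))
    stop("seq_range: unknown chromosome ", chrom)
  if (start < 1 || end > length(genome[[chrom]]))
    stop("seq_range: coordinates ", chrom, ":", start, "-", end,
         " outside chromosome")
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Build the back-spliced / linear junction pseudo-reference
#'
#' Per confident circRNA, the back-splice contig is the last `flank` nt of
#' the donor exon followed by the first `flank` nt of the acceptor exon
#' (strand-oriented, breakpoint at offset `flank`); circRNAs whose donor or
#' acceptor exon is shorter than `flank` are removed (reason
#' `untrimmable`). Per gene, every unique annotated exon-exon junction
#' becomes a linear contig at its original length (full upstream exon plus
#' full downstream exon in transcript orientation); genes with no linear
#' junction lose all their circRNAs (reason `no_linear`). Candidate boundary
#' discrepancies (up to 1 bp) are preserved: the junction-side boundaries of
#' the acceptor and donor exons are taken from the candidate coordinates.
#'
#' @param confident confident-set data.frame ([annotate_candidates()] or
#'   [truth_confident()]).
#' @param annotation exon table.
#' @param genome `Biostrings::DNAStringSet`.
#' @param flank nt kept on each side of the back-splice breakpoint.
#' @return a `junction_reference`: list with `contigs` (name, kind
#'   bsj/linear, gene_id, circ_id, offset, length, junction exon intervals,
#'   span of bsj circRNAs) and `sequences` (named `DNAStringSet`);
#'   `attr(, "removed")` records dropped circRNAs and reasons.
#' @export
build_junction_reference <- function(confident, annotation, genome,
                                     flank = 80L) {
  stopifnot(nrow(confident) > 0)
  lj <- linear_junctions(annotation[annotation$gene_id %in%
                                      confident$gene_id, , drop = FALSE])
  genes_with_linear <- unique(lj$gene_id)
  removed <- data.frame(circ_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  rows <- list(); seqs <- list()
  for (i in seq_len(nrow(confident))) {
    cc <- confident[i, ]
    if (!cc$gene_id %in% genes_with_linear) {
      removed <- rbind(removed, data.frame(circ_id = cc$circ_id,
                                           reason = "no_linear"))
      next
    }
    plus <- cc$strand == "+"
    # junction-side boundaries from the candidate, far boundaries from the
    # matched annotation exons
    acc_iv <- if (plus) c(cc$start, cc$acceptor_end)
              else c(cc$acceptor_start, cc$end)
    don_iv <- if (plus) c(cc$donor_start, cc$end)
              else c(cc$start, cc$donor_end)
    if (acc_iv[2] - acc_iv[1] + 1L < flank ||
        don_iv[2] - don_iv[1] + 1L < flank) {
      removed <- rbind(removed, data.frame(circ_id = cc$circ_id,
                                           reason = "untrimmable"))
      next
    }
    acc_seq <- seq_range(genome, cc$chrom, acc_iv[1], acc_iv[2], cc$strand)
    don_seq <- seq_range(genome, cc$chrom, don_iv[1], don_iv[2], cc$strand)
    contig <- paste0(substring(don_seq, nchar(don_seq) - flank + 1L),
                     substring(acc_seq, 1L, flank))
    rows[[length(rows) + 1L]] <- data.frame(
      name = cc$circ_id, kind = "bsj", gene_id = cc$gene_id,
      circ_id = cc$circ_id, offset = flank, length = 2L * flank,
      up_start = NA_integer_, up_end = NA_integer_,
      dn_start = NA_integer_, dn_end = NA_integer_,
      span_start = min(acc_iv[1], don_iv[1]),
      span_end = max(acc_iv[2], don_iv[2]), stringsAsFactors = FALSE)
    seqs[[cc$circ_id]] <- contig
  }

  for (j in seq_len(nrow(lj))) {
    l <- lj[j, ]
    up_seq <- seq_range(genome, l$chrom, l$up_start, l$up_end, l$strand)
    dn_seq <- seq_range(genome, l$chrom, l$dn_start, l$dn_end, l$strand)
    # transcript order: on '-' the genomic-right exon comes first
    contig <- if (l$strand == "+") paste0(up_seq, dn_seq)
              else paste0(dn_seq, up_seq)
    offset <- if (l$strand == "+") nchar(up_seq) else nchar(dn_seq)
    rows[[length(rows) + 1L]] <- data.frame(
      name = l$junction_id, kind = "linear", gene_id = l$gene_id,
      circ_id = NA_character_, offset = offset, length = nchar(contig),
      up_start = l$up_start, up_end = l$up_end,
      dn_start = l$dn_start, dn_end = l$dn_end,
      span_start = NA_integer_, span_end = NA_integer_,
      stringsAsFactors = FALSE)
    seqs[[l$junction_id]] <- contig
  }

  contigs <- do.call(rbind, rows)
  if (is.null(contigs)) {
    empty <- structure(list(contigs = data.frame(name = character(0),
                                                 kind = character(0),
                                                 gene_id = character(0)),
                            sequences = Biostrings::DNAStringSet()),
                       class = "junction_reference", removed = removed)
    return(empty)
  }
  # keep only linear contigs for genes whose circRNAs survived, and vice
  # versa bsj contigs always have >= 1 linear contig by construction
  keep_genes <- unique(contigs$gene_id[contigs$kind == "bsj"])
  contigs <- contigs[contigs$kind == "bsj" |
                       contigs$gene_id %in% keep_genes, , drop = FALSE]
  rownames(contigs) <- NULL
  sequences <- Biostrings::DNAStringSet(unlist(seqs[contigs$name]))
  structure(list(contigs = contigs, sequences = sequences),
            class = "junction_reference", removed = removed)
}

#' @export
print.junction_reference <- function(x, ...) {
  cat("junction_reference:", sum(x$contigs$kind == "bsj"), "bsj +",
      sum(x$contigs$kind == "linear"), "linear contigs over",
      length(unique(x$contigs$gene_id)), "genes\n")
  invisible(x)
}

#' Count junction-spanning read pairs
#'
#' A fragment is counted once for a contig when at least one of its mates'
#' primary alignment covers the breakpoint window
#' `[offset - min_overhang + 1, offset + min_overhang]`, has mapping
#' quality at least `min_mapq`, and the pair orientation is first mate
#' reverse / second mate forward. Secondary and supplementary records are
#' ignored; records on unknown contigs are skipped with a warning.
#'
#' @param sam_paths named character vector of SAM (or BAM) files, one per
#'   sample; names become the count matrix columns.
#' @param ref a `junction_reference`.
#' @param min_mapq minimum mapping quality.
#' @param min_overhang nt the spanning mate must cover on each side of the
#'   breakpoint.
#' @return integer matrix, contig x sample.
#' @export
count_junction_reads <- function(sam_paths, ref, min_mapq = 13L,
                                 min_overhang = 5L) {
  stopifnot(inherits(ref, "junction_reference"))
  if (is.null(names(sam_paths)))
    names(sam_paths) <- sub("\\.(sam|bam)$", "", basename(sam_paths))
  contigs <- ref$contigs
  counts <- matrix(0L, nrow(contigs), length(sam_paths),
                   dimnames = list(contigs$name, names(sam_paths)))
  for (s in names(sam_paths)) {
    path <- sam_paths[[s]]
    bam <- if (grepl("\\.sam$", path)) {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    } else path
    a <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "qwidth")))[[1]]
    fl <- a$flag
    primary <- bitwAnd(fl, 256L) == 0L & bitwAnd(fl, 2048L) == 0L &
      bitwAnd(fl, 4L) == 0L
    rn <- as.character(a$rname)
    unknown <- primary & !is.na(rn) & !(rn %in% contigs$name)
    if (any(unknown))
      warning("count_junction_reads: skipped ", sum(unknown),
              " alignment(s) on unknown contigs in ", basename(path))
    idx <- which(primary & rn %in% contigs$name)
    if (length(idx) == 0) next
    off <- contigs$offset[match(rn[idx], contigs$name)]
    win_lo <- off - min_overhang + 1L
    win_hi <- off + min_overhang
    covers <- a$pos[idx] <= win_lo & (a$pos[idx] + a$qwidth[idx] - 1L) >= win_hi
    mapq_ok <- !is.na(a$mapq[idx]) & a$mapq[idx] >= min_mapq
    f <- fl[idx]
    is_first <- bitwAnd(f, 64L) > 0L
    is_rev <- bitwAnd(f, 16L) > 0L
    mate_rev <- bitwAnd(f, 32L) > 0L
    orient_ok <- (is_first & is_rev & !mate_rev) |
      (!is_first & !is_rev & mate_rev)
    ok <- covers & mapq_ok & orient_ok
    if (!any(ok)) next
    key <- unique(paste(rn[idx][ok], a$qname[idx][ok], sep = "\r"))
    tab <- table(vapply(strsplit(key, "\r", fixed = TRUE), `[[`, "", 1L))
    counts[names(tab), s] <- counts[names(tab), s] + as.integer(tab)
  }
  counts
}

#' Summarize circular and linear junction counts per circRNA
#'
#' For each back-splice junction and sample: its own count, the arithmetic
#' mean over all the gene's linear junction counts, and the mean over the
#' linear junctions external to the back-splice span (a linear junction is
#' external when neither of its exons lies within the circRNA's exon span).
#' CircRNAs with no external linear junction get `NA` for the external
#' mean (absent, not zero).
#'
#' @param counts matrix from [count_junction_reads()] (or the simulated
#'   matrices bound by contig name).
#' @param ref a `junction_reference`.
#' @return data.frame: circ_id, gene_id, sample_id, bsj, linear_all_mean,
#'   linear_external_mean.
#' @export
summarize_bsj_linear <- function(counts, ref) {
  contigs <- ref$contigs
  bsj <- contigs[contigs$kind == "bsj", , drop = FALSE]
  lin <- contigs[contigs$kind == "linear", , drop = FALSE]
  samples <- colnames(counts)
  out <- vector("list", nrow(bsj))
  for (i in seq_len(nrow(bsj))) {
    b <- bsj[i, ]
    gl <- lin[lin$gene_id == b$gene_id, , drop = FALSE]
    inside <- function(s, e) s >= b$span_start & e <= b$span_end
    external <- !(inside(gl$up_start, gl$up_end) |
                    inside(gl$dn_start, gl$dn_end))
    lin_counts <- counts[gl$name, , drop = FALSE]
    all_mean <- colMeans(lin_counts)
    ext_mean <- if (any(external))
      colMeans(lin_counts[external, , drop = FALSE]) else
      rep(NA_real_, length(samples))
    out[[i]] <- data.frame(
      circ_id = b$circ_id, gene_id = b$gene_id, sample_id = samples,
      bsj = as.numeric(counts[b$name, ]),
      linear_all_mean = as.numeric(all_mean),
      linear_external_mean = as.numeric(ext_mean),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
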