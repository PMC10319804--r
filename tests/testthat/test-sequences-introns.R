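toy_circ <- function(gene = "gA", start = 501L, end = 1700L, strand = "+",
                     acc = 2L, don = 4L) {
  data.frame(circ_id = sprintf("chr1:%d-%d:%s", start, end, strand),
             gene_id = gene, chrom = "chr1", start = start, end = end,
             strand = strand, acceptor_exon = acc, donor_exon = don,
             stringsAsFactors = FALSE)
}

test_that("circ sequences splice the in-span exons, resolving overlaps by length", {
  ann <- toy_annotation()
  genome <- toy_genome()
  cs <- build_circ_sequence(toy_circ(), ann, genome)
  expect_equal(nrow(cs$exon_chain), 3)                  # e2, e3, e4
  expect_equal(nchar(cs$sequence), 150 + 120 + 200)
  gstr <- as.character(genome[[1]])
  want <- paste0(substr(gstr, 501, 650), substr(gstr, 1001, 1120),
                 substr(gstr, 1501, 1700))
  expect_identical(cs$sequence, want)
  # overlapping exon variant: the longer one wins
  ann_ov <- rbind(ann, data.frame(
    gene_id = "gA", transcript_id = "gA.t2", exon_number = 3L,
    chrom = "chr1", start = 1001L, end = 1090L, strand = "+",
    stringsAsFactors = FALSE))
  cs2 <- build_circ_sequence(toy_circ(), ann_ov, genome)
  expect_identical(cs2$sequence, want)   # 120-nt variant beats 90-nt
  expect_error(build_circ_sequence(toy_circ(start = 300L, end = 400L),
                                   ann, genome), "no annotated exons")
})

test_that("minus-strand circ sequences are reverse-complemented in transcript order", {
  ann <- toy_annotation()
  genome <- toy_genome()
  circ <- toy_circ(gene = "gB", start = 5501L, end = 6700L, strand = "-",
                   acc = 2L, don = 4L)
  cs <- build_circ_sequence(circ, ann, genome)
  gstr <- as.character(genome[[1]])
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  want <- paste0(rc(substr(gstr, 6501, 6700)), rc(substr(gstr, 6001, 6120)),
                 rc(substr(gstr, 5501, 5650)))
  expect_identical(cs$sequence, want)
})

test_that("control sequences pick the longer side and trim symmetrically", {
  ann <- toy_annotation()
  genome <- toy_genome()
  # circ over e2-e4 (470 nt); upstream has e1 (100 nt), downstream e5 (100)
  ctl <- build_control_sequence(toy_circ(), ann, genome, 470L)
  expect_false(ctl$length_matched)       # both sides shorter than the circ
  expect_equal(nchar(ctl$sequence), 100)
  # shrink the circ to e3 only: downstream e4+e5 (300 nt) beats upstream
  # e1+e2 (250 nt); excess 180 is split 90/90
  circ3 <- toy_circ(start = 1001L, end = 1120L, acc = 3L, don = 3L)
  ctl3 <- build_control_sequence(circ3, ann, genome, 120L)
  expect_true(ctl3$length_matched)
  expect_equal(nchar(ctl3$sequence), 120)
  gstr <- as.character(genome[[1]])
  spliced <- paste0(substr(gstr, 1501, 1700), substr(gstr, 2001, 2100))
  expect_identical(ctl3$sequence, substr(spliced, 91, 210))
  expect_equal(ctl3$side, "downstream")
  # odd excess (181): floor(90) from the start, ceil(91) from the end
  ctl_odd <- build_control_sequence(circ3, ann, genome, 119L)
  expect_identical(ctl_odd$sequence, substr(spliced, 91, 209))
  # gene with nothing outside the span: absent control, flagged
  circ_all <- toy_circ(start = 101L, end = 2100L, acc = 1L, don = 5L)
  ctl_none <- build_control_sequence(circ_all, ann, genome, 670L)
  expect_true(is.na(ctl_none$sequence))
  expect_false(ctl_none$length_matched)
})

test_that("flank selection takes the longest side introns and greedy controls", {
  introns <- data.frame(
    gene_id = "g", chrom = "chr1",
    start = c(100L, 3000L, 9000L, 20000L, 40000L, 60000L),
    end = c(1099L, 5000L, 10999L, 22499L, 41999L, 60013L),
    strand = "+", stringsAsFactors = FALSE)
  introns$length <- introns$end - introns$start + 1L
  # circ span 6000-8999: upstream introns are #1 (1000) and #2 (2001);
  # downstream #3 (2000 nt), #4 (2500), #5 (2000); #6 is 14 nt -> ignored
  circ <- data.frame(circ_id = "c", gene_id = "g", chrom = "chr1",
                     start = 6000L, end = 8999L, strand = "+",
                     stringsAsFactors = FALSE)
  fs <- select_flanking_and_control_introns(circ, introns)
  expect_equal(fs$upstream$start, 3000L)     # longest upstream
  expect_equal(fs$downstream$start, 20000L)  # longest downstream
  expect_equal(fs$flank_cum, 2001L + 2500L)
  # greedy controls: longest non-overlapping leftovers until cum >= 4501
  expect_equal(fs$controls$start, c(9000L, 40000L, 100L))
  expect_gte(fs$control_cum, fs$flank_cum)
  expect_false(60000L %in% fs$controls$start)  # 14-nt intron never used
  # circ at the gene 5' end: no upstream intron
  circ5 <- circ; circ5$start <- 50L; circ5$end <- 2000L
  fs5 <- select_flanking_and_control_introns(circ5, introns)
  expect_null(fs5$upstream)
  expect_equal(fs5$flank_cum, fs5$downstream$length)
})

test_that("control sequence and intron invariants hold across the synthetic cohort", {
  sim <- small_sim()
  conf <- truth_confident(sim)
  introns <- annotation_introns(sim$annotation)
  for (i in seq_len(nrow(conf))) {
    circ <- conf[i, ]
    cs <- build_circ_sequence(circ, sim$annotation, sim$genome)
    ctl <- build_control_sequence(circ, sim$annotation, sim$genome,
                                  nchar(cs$sequence))
    if (!is.na(ctl$sequence) && ctl$length_matched)
      expect_equal(nchar(ctl$sequence), nchar(cs$sequence))
    fs <- select_flanking_and_control_introns(circ, introns)
    iv <- rbind(
      if (!is.null(fs$upstream)) fs$upstream[c("start", "end")],
      if (!is.null(fs$downstream)) fs$downstream[c("start", "end")],
      data.frame(start = circ$start, end = circ$end),
      fs$controls[c("start", "end")])
    # controls overlap nothing (pairwise disjoint intervals overall)
    o <- order(iv$start)
    expect_true(all(iv$start[o][-1] > iv$end[o][-nrow(iv)]))
    expect_true(all(fs$controls$length >= 15))
    expect_gte(fs$control_cum, fs$flank_cum)
  }
})

test_that("Fisher tables agree with hypergeometric enumeration", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    a <- sample(0:n, 1); b <- n - a
    c_ <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + c_ == 0 || b + d == 0) next
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expect_equal(stats::fisher.test(tab)$p.value,
                 hyper_fisher_two(a, b, c_, d), tolerance = 1e-9)
    expect_equal(stats::fisher.test(tab, alternative = "greater")$p.value,
                 hyper_fisher_greater(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("Alu enrichment detects the planted flank bias", {
  sim <- small_sim()
  conf <- truth_confident(sim)
  introns <- annotation_introns(sim$annotation)
  fs <- lapply(seq_len(nrow(conf)), function(i)
    select_flanking_and_control_introns(conf[i, ], introns))
  enr <- alu_enrichment(fs, sim$repeats)
  expect_equal(enr$stratum, c("upstream", "downstream", "combined"))
  comb <- enr[enr$stratum == "combined", ]
  expect_lt(comb$p.value, 0.05)
  expect_gt(comb$flank_alu / comb$flank_total,
            comb$control_alu / comb$control_total)
  # balanced table gives p = 1
  bal <- alu_enrichment(fs[0], sim$repeats)
  expect_true(all(is.na(bal$p.value)))
})

test_that("flanking introns are longer than controls in the planted simulation", {
  sim <- small_sim()
  conf <- truth_confident(sim)
  introns <- annotation_introns(sim$annotation)
  fs <- lapply(seq_len(nrow(conf)), function(i)
    select_flanking_and_control_introns(conf[i, ], introns))
  cmp <- intron_length_compare(fs)
  expect_gt(cmp$mean_flank, cmp$mean_control)
  expect_lt(cmp$p.value, 0.01)
  expect_error(intron_length_compare(list()), "empty")
})

test_that("a three-exon circle splices to the expected length (synthetic ARID1A-like locus)", {
  # synthetic stand-in for a three-exon circle whose spliced length is 783 nt
  set.seed(83)
  lens <- c(251L, 280L, 252L)
  starts <- c(1001L, 2001L, 3001L)
  ann <- data.frame(gene_id = "ARID1A_syn", transcript_id = "t1",
                    exon_number = 2:4, chrom = "chrZ", start = starts,
                    end = starts + lens - 1L, strand = "+",
                    stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chrZ = paste(
    sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")))
  circ <- data.frame(circ_id = "syn", gene_id = "ARID1A_syn", chrom = "chrZ",
                     start = 1001L, end = 3252L, strand = "+",
                     acceptor_exon = 2L, donor_exon = 4L,
                     stringsAsFactors = FALSE)
  cs <- build_circ_sequence(circ, ann, genome)
  expect_equal(nchar(cs$sequence), 783L)
  expect_equal(nrow(cs$exon_chain), 3L)
})
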