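write_ciri2_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
              "junction_reads", "strand", "circRNA_type")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

test_that("CIRI2 tables parse, with malformed rows reported by line", {
  p <- write_ciri2_fixture(c(
    "chr1:100|500\tchr1\t100\t500\t23\t+\texon",
    "chr1:900|700\tchr1\t900\t700\t5\t+\texon",    # end < start
    "chr2:10|90\tchr2\t10\t90\t7\t-\tintron"))
  expect_warning(cc <- read_ciri2(p, "s1"), "malformed")
  expect_equal(nrow(cc$table), 2)
  expect_equal(cc$counts["chr1:100-500:+", "s1"], 23L)
  expect_equal(attr(cc, "malformed")$line, 3L)

  empty <- write_ciri2_fixture(character(0))
  expect_equal(nrow(read_ciri2(empty, "s1")$table), 0)

  bad <- tempfile(); writeLines("circRNA_ID\tchr\tstart", bad)
  expect_error(read_ciri2(bad), "circRNA_start")
})

test_that("blacklist removes chrM, chrY, and unplaced contigs", {
  p <- write_ciri2_fixture(c(
    "a\tchr1\t10\t50\t3\t+\texon",
    "b\tchrM\t10\t50\t3\t+\texon",
    "c\tchrY\t10\t50\t3\t+\texon",
    "d\tKI270713.1\t10\t50\t3\t+\texon"))
  cc <- read_ciri2(p, "s1")
  kept <- filter_blacklist(cc)
  expect_equal(kept$table$chrom, "chr1")
})

test_that("expression filter applies the 25% OR >=20-reads-in-3 rule", {
  # cohort of 12: expressed in 3 samples passes via ceil(0.25 * 12) = 3
  mk <- function(counts) {
    structure(list(
      table = data.frame(circ_id = "x", chrom = "chr1", start = 1L,
                         end = 10L, strand = "+", circ_type = "exon",
                         stringsAsFactors = FALSE),
      counts = matrix(counts, nrow = 1,
                      dimnames = list("x", paste0("s", seq_along(counts))))),
      class = "circ_candidates")
  }
  expect_equal(nrow(filter_expression(mk(c(1, 1, 1, rep(0, 9))))$table), 1)
  expect_equal(nrow(filter_expression(mk(c(1, 1, rep(0, 10))))$table), 0)
  # cohort of 104: 25/25/25 passes via the read-support branch
  expect_equal(nrow(filter_expression(mk(c(25, 25, 25, rep(0, 101))))$table),
               1)
  # 19 reads in 10 samples fails both branches (10 < 26; no sample >= 20)
  expect_equal(nrow(filter_expression(mk(c(rep(19, 10), rep(0, 94))))$table),
               0)
  expect_error(filter_expression(mk(c(1, 1)), n_samples = 0), "positive")
})

test_that("catalog filters are idempotent and order-independent", {
  sim <- small_sim()
  cnt <- small_counts()
  dir <- file.path(tempdir(), "ciri2")
  paths <- simulate_ciri2_tables(sim, cnt$bsj, dir, n_noise = 6L)
  cands <- merge_candidates(lapply(paths, read_ciri2))
  chroms <- names(sim$genome)
  ab <- filter_expression(filter_blacklist(cands, chroms))
  ba <- filter_blacklist(filter_expression(cands), chroms)
  expect_identical(ab$table, ba$table)
  expect_identical(filter_blacklist(filter_blacklist(cands, chroms),
                                    chroms)$table,
                   filter_blacklist(cands, chroms)$table)
  expect_identical(filter_expression(ab)$table, ab$table)
})

test_that("annotation matching accepts <=1 bp discrepancies and rejects cross-gene joins", {
  ann <- toy_annotation()
  mk_cands <- function(df) {
    df$circ_id <- sprintf("%s:%d-%d:%s", df$chrom, df$start, df$end,
                          df$strand)
    structure(list(table = df,
                   counts = matrix(1L, nrow(df), 1,
                                   dimnames = list(df$circ_id, "s1"))),
              class = "circ_candidates")
  }
  cands <- mk_cands(data.frame(
    chrom = "chr1",
    start = c(501L, 502L, 501L, 3000L, 501L),
    end = c(1700L, 1700L, 6700L, 3400L, 1690L),
    strand = c("+", "+", ".", "+", "+"),
    circ_type = "exon", stringsAsFactors = FALSE))
  res <- annotate_candidates(cands, ann)
  conf <- res$confident
  # exact match: exon2 acceptor, exon4 donor of gA
  expect_equal(conf$gene_id[conf$circ_id == "chr1:501-1700:+"], "gA")
  expect_equal(conf$acceptor_exon[1], 2L)
  expect_equal(conf$donor_exon[1], 4L)
  expect_equal(conf$disc_start[1], 0L)
  # 1 bp off at the start: matched, discrepancy recorded
  off1 <- conf[conf$circ_id == "chr1:502-1700:+", ]
  expect_equal(nrow(off1), 1)
  expect_equal(off1$disc_start, 1L)
  # ends in different genes: cross-gene rejection
  expect_equal(res$rejected$reason[res$rejected$circ_id == "chr1:501-6700:."],
               "cross-gene")
  # nowhere near an exon boundary: no-gene
  expect_equal(res$rejected$reason[res$rejected$circ_id == "chr1:3000-3400:+"],
               "no-gene")
  # one end matches, the other misses by 10: boundary rejection
  expect_equal(res$rejected$reason[res$rejected$circ_id == "chr1:501-1690:+"],
               "boundary")
})

test_that("minus-strand acceptor/donor roles follow transcript orientation", {
  ann <- toy_annotation()
  df <- data.frame(chrom = "chr1", start = 5501L, end = 6700L, strand = "-",
                   circ_type = "exon", stringsAsFactors = FALSE)
  df$circ_id <- "chr1:5501-6700:-"
  cands <- structure(list(table = df,
                          counts = matrix(1L, 1, 1,
                                          dimnames = list(df$circ_id, "s1"))),
                     class = "circ_candidates")
  conf <- annotate_candidates(cands, ann)$confident
  # gB exons (genomic left to right) carry exon_number 5..1; the acceptor is
  # the transcript-upstream exon, whose genomic END matches the span end
  expect_equal(conf$gene_id, "gB")
  expect_equal(conf$acceptor_exon, 2L)
  expect_equal(conf$donor_exon, 4L)
})

test_that("truth circRNAs that satisfy the filters are recovered from simulated tables", {
  sim <- small_sim()
  cnt <- small_counts()
  dir <- file.path(tempdir(), "ciri2rec")
  paths <- simulate_ciri2_tables(sim, cnt$bsj, dir, n_noise = 4L)
  cands <- merge_candidates(lapply(paths, read_ciri2))
  kept <- filter_expression(filter_blacklist(cands, names(sim$genome)))
  res <- annotate_candidates(kept, sim$annotation)
  # every sufficiently expressed truth circRNA survives, nothing else does
  n <- ncol(cnt$bsj)
  ok <- rowSums(cnt$bsj >= 1) >= ceiling(0.25 * n) |
    rowSums(cnt$bsj >= 20) >= 3
  expect_setequal(res$confident$circ_id, rownames(cnt$bsj)[ok])
  expect_equal(nrow(res$rejected[res$rejected$circ_id %in%
                                   rownames(cnt$bsj), ]), 0)
})

test_that("catalog statistics count isoforms and exons", {
  ann <- toy_annotation()
  conf <- data.frame(
    circ_id = c("c1", "c2"), gene_id = "gA", chrom = "chr1",
    start = c(501L, 501L), end = c(1700L, 2100L), strand = "+",
    acceptor_exon = 2L, donor_exon = c(4L, 5L),
    stringsAsFactors = FALSE)
  st <- catalog_stats(conf, ann)
  expect_equal(st$isoforms_per_gene$n_isoforms, 2L)
  expect_equal(st$exons_per_circ$n_exons, c(3L, 4L))
  expect_equal(nrow(catalog_stats(conf[0, ], ann)$exons_per_circ), 0)
})

test_that("GTF written by the generator round-trips through the reader", {
  sim <- small_sim()
  dir <- file.path(tempdir(), "gtf_rt")
  paths <- write_sim(sim, dir)
  back <- read_gtf(paths[["gtf"]])
  a <- sim$annotation[order(sim$annotation$gene_id, sim$annotation$start), ]
  b <- back[order(back$gene_id, back$start), ]
  for (col in c("gene_id", "transcript_id", "exon_number", "chrom", "start",
                "end", "strand")) {
    expect_equal(unname(a[[col]]), unname(b[[col]]), label = col)
  }
})
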