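write_motif_db_fixture <- function(entries) {
  # entries: list of list(id, rbp, consensus, matrix)
  db <- data.frame(
    Gene_name = vapply(entries, `[[`, "", "rbp"),
    Matrix_id = vapply(entries, `[[`, "", "id"),
    Motif = vapply(entries, `[[`, "", "consensus"),
    stringsAsFactors = FALSE)
  db_path <- tempfile(fileext = ".txt")
  utils::write.table(db, db_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pwm_path <- tempfile(fileext = ".txt")
  con <- file(pwm_path, "w")
  seen <- character(0)
  for (e in entries) {
    if (e$id %in% seen) next
    seen <- c(seen, e$id)
    writeLines(sprintf(">%s\t%d", e$id, nrow(e$matrix)), con)
    apply(e$matrix, 1, function(r)
      writeLines(paste(sprintf("%.6f", r), collapse = "\t"), con))
  }
  close(con)
  list(db = db_path, pwm = pwm_path)
}

consensus_pwm <- function(cons, p = 0.97) {
  L <- nchar(cons)
  m <- matrix((1 - p) / 3, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(L)) m[i, substr(cons, i, i)] <- p
  m
}

test_that("motif loading drops spurious entries and merges identical matrices", {
  m7 <- consensus_pwm("ACGTACG")
  fx <- write_motif_db_fixture(list(
    list(id = "M1", rbp = "RBPB", consensus = "ACGTACG", matrix = m7),
    list(id = "M2", rbp = "RBPA", consensus = "ACGTACG", matrix = m7),
    list(id = "M3", rbp = "RBPC", consensus = "ACGTAC",
         matrix = consensus_pwm("ACGTACGA")),     # 8-row PWM, 6-long consensus
    list(id = "M4", rbp = "RBPD", consensus = "ACGTA",
         matrix = consensus_pwm("ACGTA"))))       # 5-mer
  db <- load_motif_db(fx$db, fx$pwm)
  expect_length(db, 1)
  expect_equal(db[[1]]$rbp_names, c("RBPA", "RBPB"))
  expect_equal(db[[1]]$motif_id, "M1/M2")
  expect_equal(db[[1]]$length, 7L)
  # rows not summing to 1 are renormalized with a warning
  bad <- m7; bad[1, ] <- bad[1, ] * 2
  fx2 <- write_motif_db_fixture(list(
    list(id = "MX", rbp = "R", consensus = "ACGTACG", matrix = bad)))
  expect_warning(db2 <- load_motif_db(fx2$db, fx2$pwm), "renormalizing")
  expect_equal(rowSums(db2[[1]]$matrix), rep(1, 7), tolerance = 1e-9)
})

test_that("the shipped synthetic motif collection cleans to two motifs", {
  db <- load_motif_db(
    system.file("extdata", "attract_like_synthetic.txt",
                package = "circscape"),
    system.file("extdata", "attract_like_synthetic_pwm.txt",
                package = "circscape"))
  # duplicate-matrix pair merged; mismatched and 5-mer entries dropped
  expect_length(db, 2)
  ids <- vapply(db, `[[`, "", "motif_id")
  expect_true("SM001/SM002" %in% ids)
  merged <- db[[which(ids == "SM001/SM002")]]
  expect_equal(merged$rbp_names, c("ELAVL1", "HNRNPC"))
})

test_that("DP tail probabilities equal brute force for L up to 8", {
  set.seed(23)
  bgs <- list(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
              c(A = 0.32, C = 0.18, G = 0.21, T = 0.29))
  for (L in 6:8) {
    mt <- make_motif(random_pwm(L))
    for (bg in bgs) {
      thr <- score_threshold(mt, bg)
      qs <- sample(thr$null$score_int,
                   min(6, length(thr$null$score_int)))
      bf <- brute_pwm_tail(thr$scores_int, bg, qs)
      dp <- vapply(qs, function(q)
        sum(thr$null$prob[thr$null$score_int >= q]), numeric(1))
      expect_equal(dp, bf, tolerance = 1e-9)
    }
  }
})

test_that("exact thresholds make 6-mers unmatchable under a uniform background", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  thr6 <- score_threshold(make_motif(consensus_pwm("ACGTAC", p = 0.997)), bg)
  expect_equal(thr6$cutoff, Inf)
  expect_equal(min(thr6$null$tail), 0.25^6 * 4^6 / 4^6, tolerance = 1e-12)
  expect_equal(min(thr6$null$tail), 4^-6, tolerance = 1e-12)
  # a 7-mer with a unique maximal word passes: P(max) = 4^-7 < 1e-4
  thr7 <- score_threshold(make_motif(consensus_pwm("ACGTACG", p = 0.997)), bg)
  expect_true(is.finite(thr7$cutoff))
  expect_equal(thr7$p_at_cutoff, 4^-7, tolerance = 1e-12)
  # uniform PWM: every word scores 0, nothing can pass
  thr_u <- score_threshold(make_motif(matrix(
    0.25, 7, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
    consensus = "NNNNNNN"), bg)
  expect_equal(thr_u$cutoff, Inf)
})

test_that("scanning counts disjoint embeddings additively and respects orientation", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mt <- make_motif(consensus_pwm("ACGTACG", p = 0.997))
  # "two" carries the word at both ends plus one overlapping
  # reverse-complement occurrence (CGTACGT) - overlaps count individually
  sc <- scan_sequences(c(one = "ACGTACG",
                         two = "ACGTACGTTTTTTACGTACG",
                         none = "CCCCCCCCCC"),
                       list(mt), bg)
  expect_equal(unname(sc$hits[, 1]), c(1L, 3L, 0L))
  # disjoint embeddings in an RC-free context are purely additive
  sc2 <- scan_sequences(c(a = "CCCCACGTACGCCCC",
                          b = "CCCCACGTACGCCCCCCACGTACGCCCC"),
                        list(mt), bg)
  expect_equal(unname(sc2$hits[, 1]), c(1L, 2L))
  # reverse-complement orientation is found
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTACG")))
  sc_rc <- scan_sequences(c(x = paste0("TTTT", rc, "TTTT")), list(mt), bg)
  expect_equal(unname(sc_rc$hits[1, 1]), 1L)
  # non-ACGT windows are skipped and tallied
  sc_n <- scan_sequences(c(x = "ACGNACGTACG"), list(mt), bg)
  expect_gt(sc_n$skipped_windows[1, 1], 0)
})

test_that("scanning a sequence equals scanning its reverse complement with the flipped motif", {
  set.seed(29)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  for (rep in 1:5) {
    mt <- make_motif(random_pwm(6), id = "m")
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    s_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    h1 <- scan_sequences(c(a = s), list(mt), bg, pvalue = 0.02)$hits
    h2 <- scan_sequences(c(a = s_rc), list(mt), bg, pvalue = 0.02)$hits
    expect_equal(unname(h1), unname(h2))
  }
})

test_that("dinucleotide shuffle preserves counts and end nucleotides on every draw", {
  expect_equal(dinucleotide_shuffle("AAAA"), "AAAA")
  expect_error(dinucleotide_shuffle("ACGN"), "non-ACGT")
  set.seed(37)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  outs <- character(50)
  for (i in 1:50) {
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_identical(dinu_counts(sh), dinu_counts(s))
    outs[i] <- sh
  }
  expect_identical(substr(outs, 1, 1), rep(substr(s, 1, 1), 50))
  expect_identical(substr(outs, 500, 500), rep(substr(s, 500, 500), 50))
  expect_gt(length(unique(outs)), 1)
  # short alternating case: every emitted permutation stays dinucleotide-true
  for (i in 1:200) {
    sh <- dinucleotide_shuffle("ACGTACGT")
    expect_identical(dinu_counts(sh), dinu_counts("ACGTACGT"))
  }
})

test_that("motif enrichment reproduces the hypergeometric tail on planted sets", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mt <- make_motif(consensus_pwm("ACGTACG", p = 0.997))
  mk_seq <- function(with) {
    base <- paste(sample(c("C", "T"), 40, replace = TRUE), collapse = "")
    if (with) paste0(base, "ACGTACG", base) else paste0(base, base)
  }
  set.seed(41)
  targets <- vapply(c(rep(TRUE, 8), rep(FALSE, 2)), mk_seq, "")
  controls <- vapply(rep(FALSE, 10), mk_seq, "")
  enr <- motif_enrichment(targets, controls, list(mt), bg)
  expect_equal(enr$target_with, 8L)
  expect_equal(enr$control_with, 0L)
  expect_equal(enr$p.value, hyper_fisher_greater(8, 2, 0, 10),
               tolerance = 1e-9)
  # identical sets carry no enrichment signal: the one-sided hypergeometric
  # p is the full upper tail including the observed table
  same <- motif_enrichment(targets, targets, list(mt), bg)
  expect_equal(same$p.value, hyper_fisher_greater(8, 2, 8, 2),
               tolerance = 1e-9)
  expect_gt(same$p.value, 0.5)
  expect_equal(nrow(motif_enrichment(targets, controls, list(), bg)), 0)
})
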