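# Shared small synthetic cohort, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

small_spec <- function() {
  sim_spec(n_genes = 30L, n_samples_per_group = c(MNA = 4L, HR_nMNA = 4L),
           circ_fraction = 0.4, alu_seed_fraction = 0.3,
           mean_gene_count = 60, seed = 42L)
}

small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- generate_annotation(small_spec())
  .sim_cache$sim
}

small_counts <- function() {
  if (is.null(.sim_cache$counts))
    .sim_cache$counts <- simulate_cohort_counts(small_sim())
  .sim_cache$counts
}

mid_counts <- function() {
  if (is.null(.sim_cache$mid)) {
    sim <- generate_annotation(sim_spec(
      n_genes = 100L, n_samples_per_group = c(MNA = 10L, HR_nMNA = 10L),
      circ_fraction = 0.4, mean_gene_count = 100, seed = 7L))
    .sim_cache$mid <- simulate_cohort_counts(sim)
  }
  .sim_cache$mid
}

small_ref <- function() {
  if (is.null(.sim_cache$ref)) {
    sim <- small_sim()
    .sim_cache$ref <- build_junction_reference(truth_confident(sim),
                                               sim$annotation, sim$genome)
  }
  .sim_cache$ref
}

# a tiny hand-made annotation: one gene per strand with known exon layout
toy_annotation <- function() {
  plus <- data.frame(
    gene_id = "gA", transcript_id = "gA.t1", exon_number = 1:5,
    chrom = "chr1",
    start = c(101L, 501L, 1001L, 1501L, 2001L),
    end = c(200L, 650L, 1120L, 1700L, 2100L),
    strand = "+", stringsAsFactors = FALSE)
  minus <- data.frame(
    gene_id = "gB", transcript_id = "gB.t1", exon_number = 5:1,
    chrom = "chr1",
    start = c(5001L, 5501L, 6001L, 6501L, 7001L),
    end = c(5100L, 5650L, 6120L, 6700L, 7100L),
    strand = "-", stringsAsFactors = FALSE)
  rbind(plus, minus)
}

toy_genome <- function() {
  set.seed(77)
  Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")))
}
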