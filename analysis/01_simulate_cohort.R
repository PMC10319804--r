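#!/usr/bin/env Rscript
# Step 1 - synthetic cohort. Generates the genome, annotation, Alu-like
# repeat track, truth circRNA set, and the cohort count matrices (two groups
# of 20 samples; circRNA count means halved in the MNA-like group; ten
# cohort-specific circRNAs at 8-fold), plus per-sample CIRI2-style
# prediction tables. Everything downstream reads from results/sim/.

suppressPackageStartupMessages(library(circscape))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- sim_spec(seed = 1L)
sim <- generate_annotation(spec)
print(sim)

paths <- write_sim(sim, outdir)
cnt <- simulate_cohort_counts(sim)

write_mat <- function(m, file) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, file.path(outdir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write_mat(cnt$bsj, "bsj_counts.tsv")
write_mat(cnt$linear, "linear_counts.tsv")
write_mat(cnt$gene, "gene_counts.tsv")
write.table(cnt$samples, file.path(outdir, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
simulate_ciri2_tables(sim, cnt$bsj, file.path(outdir, "ciri2"), n_noise = 5L)

cat(sprintf(
  "simulated %d genes, %d truth circRNAs (%d cohort-specific), %d samples\n",
  nrow(sim$genes), nrow(sim$truth$circ_records),
  length(sim$truth$specific_ids), nrow(cnt$samples)))
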