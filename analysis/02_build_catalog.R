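#!/usr/bin/env Rscript
# Step 2 - confident circRNA catalog. Parses the per-sample CIRI2-style
# tables, removes blacklist contigs, applies the expression filter
# (expressed in >= 25% of samples OR >= 20 reads in >= 3 samples), and
# matches the survivors to the annotation with 1-bp boundary tolerance.

suppressPackageStartupMessages(library(circscape))

annotation <- read_gtf("results/sim/annotation.gtf")
chroms <- names(Biostrings::readDNAStringSet("results/sim/genome.fa"))
tabs <- list.files("results/sim/ciri2", full.names = TRUE)
cands <- merge_candidates(lapply(tabs, read_ciri2))
cat("candidates across the cohort:", nrow(cands$table), "\n")

kept <- filter_expression(filter_blacklist(cands, chroms))
cat("after blacklist + expression filters:", nrow(kept$table), "\n")

ann <- annotate_candidates(kept, annotation)
cat("confident circRNAs:", nrow(ann$confident),
    "| rejected:", nrow(ann$rejected), "\n")
print(table(ann$rejected$reason))

write.table(ann$confident, "results/confident_circrnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
st <- catalog_stats(ann$confident, annotation)
write.table(st$isoforms_per_gene, "results/isoforms_per_gene.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(st$exons_per_circ, "results/exons_per_circ.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
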