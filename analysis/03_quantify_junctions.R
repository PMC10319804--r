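#!/usr/bin/env Rscript
# Step 3 - junction quantification. Builds the 160-nt back-splice /
# full-length linear junction pseudo-reference, emits junction-spanning
# read pairs (with labeled decoys) for a subset of samples, counts them
# under the MAPQ >= 13 / first-mate-reverse rules, and verifies the counts
# against the simulated matrix before summarizing circular vs linear
# expression for the whole cohort.

suppressPackageStartupMessages(library(circscape))

annotation <- read_gtf("results/sim/annotation.gtf")
genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
conf <- read.delim("results/confident_circrnas.tsv")
cnt_bsj <- as.matrix(read.delim("results/sim/bsj_counts.tsv",
                                row.names = 1, check.names = FALSE))
cnt_lin <- as.matrix(read.delim("results/sim/linear_counts.tsv",
                                row.names = 1, check.names = FALSE))

ref <- build_junction_reference(conf, annotation, genome)
print(ref)
removed <- attr(ref, "removed")
if (nrow(removed) > 0) print(removed)

counts <- rbind(cnt_bsj, cnt_lin)[ref$contigs$name, , drop = FALSE]

# SAM round trip on four samples, with decoys of every class
sub <- colnames(counts)[c(1, 2, 21, 22)]
paths <- simulate_junction_reads(
  ref, counts[, sub, drop = FALSE], "results/sam",
  decoys = c(lowmapq = 3L, secondary = 2L, wrong_orient = 2L,
             nonspanning = 2L))
got <- count_junction_reads(paths, ref)
acc <- mean(got[rownames(counts), sub] == counts[, sub])
cat(sprintf("counting round-trip accuracy on %d cells: %.4f\n",
            length(sub) * nrow(counts), acc))

summ <- summarize_bsj_linear(counts, ref)
write.table(summ, "results/junction_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("summarized", length(unique(summ$circ_id)), "circRNAs x",
    length(unique(summ$sample_id)), "samples\n")
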