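#!/usr/bin/env Rscript
# Step 7 - RBP motif scanning. Loads the shipped synthetic ATtRACT-style
# motif collection, fits the zero-order background on the circRNA
# sequences, scans circRNA sequences against dinucleotide-preserving
# shuffles of themselves, and tabulates sequence-level motif enrichment.

suppressPackageStartupMessages(library(circscape))

db <- load_motif_db(
  system.file("extdata", "attract_like_synthetic.txt", package = "circscape"),
  system.file("extdata", "attract_like_synthetic_pwm.txt",
              package = "circscape"))
cat("motifs after cleaning:", length(db), "\n")

circ_seq <- Biostrings::readDNAStringSet("results/circ_sequences.fa")
bg <- background_model(circ_seq)
cat("background:", paste(sprintf("%s=%.3f", names(bg), bg),
                         collapse = " "), "\n")

shuffled <- vapply(seq_along(circ_seq), function(i)
  dinucleotide_shuffle(as.character(circ_seq[[i]]), seed = 7000L + i), "")
names(shuffled) <- paste0(names(circ_seq), "_shuf")

hits <- scan_sequences(circ_seq, db, bg)
write.table(data.frame(circ_id = rownames(hits$hits), hits$hits,
                       check.names = FALSE),
            "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
enr <- motif_enrichment(as.character(circ_seq), shuffled, db, bg)
write.table(enr, "results/motif_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(enr[, c("motif_id", "rbp_names", "target_with", "control_with",
              "p.value", "q.value")])
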