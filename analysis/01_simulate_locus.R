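#!/usr/bin/env Rscript
# Step 1: generate the synthetic IgH-like germline locus used throughout the
# analysis: 30 V, 10 D, 8 J and 9 C genes in two D-J-C clusters, with 40%
# of V genes planted as pseudogenes (all defect codes represented), 10% as
# ORFs, and 20% of V genes in reversed transcriptional orientation.
# Writes the genome FASTA, the ground-truth GFF3 and the seed sequences.

suppressPackageStartupMessages(library(igloci))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

spec <- locus_spec(n_v = 30L, n_d = 10L, n_j = 8L, n_c = 9L,
                   n_clusters = 2L, pseudogene_fraction = 0.4,
                   orf_fraction = 0.1, reversed_v_fraction = 0.2,
                   seed = 2024L)
locus <- generate_locus(spec)

write_fasta(locus$genome, file.path(out_dir, "locus_genome.fasta"))
write_fasta(locus$v_seeds, file.path(out_dir, "v_seeds.fasta"))
write_fasta(locus$c_seeds, file.path(out_dir, "c_seeds.fasta"))
write_gff3(locus$genes, file.path(out_dir, "locus_truth.gff3"))
utils::write.table(locus$genes, file.path(out_dir, "locus_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Generated", nchar(locus$genome[[1]]), "bp locus with",
    nrow(locus$genes), "planted genes:\n")
print(table(locus$genes$segment_type, locus$genes$functionality))
cat("Reversed-orientation V genes:",
    sum(locus$genes$strand == "-"), "\n")
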