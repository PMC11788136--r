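#!/usr/bin/env Rscript
# Step 6: repertoire statistics across the five samples: inverse Simpson
# diversity, analytic rarefaction, top/rare/clonal proportions (on total
# clone counts), pairwise overlap and all-sample shared clonotypes, CDR3
# length distribution with ultra-long reporting, V/D/J usage and the
# junction trimming/insertion profile (on unique clones).

suppressPackageStartupMessages(library(igloci))

out_dir <- "results"
samples <- paste0("S", 1:5)
tabs <- lapply(samples, function(nm)
  read_airr(file.path(out_dir, paste0("clonotypes_", nm, ".airr.tsv"))))
names(tabs) <- samples

div <- data.frame(
  sample = samples,
  inverse_simpson = vapply(tabs, function(t) inverse_simpson(t$count),
                           numeric(1)),
  top10_proportion = vapply(tabs, function(t) top_proportion(t$count, 10L),
                            numeric(1)),
  clones_at_31pct = vapply(tabs, function(t)
    clonal_proportion(t$count, 0.31), numeric(1)))
utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(div, row.names = FALSE)

# rarefaction curves at shared depths
depths <- round(seq(10, min(vapply(tabs, function(t) sum(t$count),
                                   numeric(1))), length.out = 20))
rar <- cbind(depth = depths,
             as.data.frame(lapply(tabs, function(t)
               rarefaction(t$count, depths))))
utils::write.table(rar, file.path(out_dir, "rarefaction.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# pairwise overlap (exact CDR3 amino-acid identity)
ov <- outer(seq_along(tabs), seq_along(tabs),
            Vectorize(function(i, j) overlap(tabs[[i]], tabs[[j]])))
dimnames(ov) <- list(samples, samples)
utils::write.table(ov, file.path(out_dir, "overlap_matrix.tsv"), sep = "\t",
                   quote = FALSE)
shared <- shared_across(tabs)
cat("Clonotypes shared across all five samples:", length(shared$shared), "\n")

# length distribution and ultra-long clones per sample
for (nm in samples) {
  ld <- length_distribution(tabs[[nm]])
  hist_df <- data.frame(length_aa = as.integer(names(ld$histogram)),
                        unique_clones = ld$histogram)
  utils::write.table(hist_df,
                     file.path(out_dir, paste0("cdr3_lengths_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(nm, ": modal CDR3 length",
      hist_df$length_aa[which.max(hist_df$unique_clones)], "aa; ultra-long (>50 aa)",
      ld$ultra_long, "; max", ld$max_length, "aa\n")
}

# gene usage
for (seg in c("V", "J")) {
  usage <- lapply(tabs, gene_usage, segment = seg)
  all_genes <- sort(unique(unlist(lapply(usage, names))))
  mat <- vapply(usage, function(u) {
    v <- setNames(numeric(length(all_genes)), all_genes)
    v[names(u)] <- u
    v
  }, numeric(length(all_genes)))
  utils::write.table(data.frame(gene = all_genes, mat),
                     file.path(out_dir, paste0(tolower(seg),
                                               "_usage.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- all_genes[which.max(rowMeans(mat))]
  cat("Most used", seg, "gene across samples:", top, "\n")
}
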