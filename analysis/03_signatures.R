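#!/usr/bin/env Rscript

# Step 3: signature scoring. Scores the naive program across clusters,
# derives an exhaustion signature from the genes most correlated with the
# LAG3 anchor within T cells, and writes per-cluster score tables.

library(immunotme)

in_dir <- "results/cohort"
out_dir <- "results"

mat <- attach_metadata(
  read_counts_mtx(file.path(in_dir, "matrix.mtx"),
                  file.path(in_dir, "features.tsv"),
                  file.path(in_dir, "barcodes.tsv")),
  file.path(in_dir, "annotations.csv"))
norm <- normalize_log2(mat)
meta <- mat$cell_meta

nv <- naive_score(norm)
cat("naive score, top cluster:", names(which.max(nv$cluster_scores)), "\n")
write.csv(scores_table(nv, "cluster"),
          file.path(out_dir, "naive_scores.csv"), row.names = FALSE)

t_types <- c("CD8_Tex", "CD8_Tcyto", "CD4_Treg", "CD4_Tn")
t_cells <- meta$barcode[meta$cell_type %in% t_types]
sig <- derive_correlation_signature(norm, "LAG3", k = 50, subset = t_cells)
ex <- score_signature(zscore_by_gene(norm, within = t_cells), sig)
labels <- meta$cluster[match(t_cells, meta$barcode)]
cl <- sort(tapply(ex$cell_scores, labels, mean), decreasing = TRUE)
cat("exhaustion signature, cluster ranking:\n")
print(round(cl, 3))
write.csv(data.frame(gene = sig$genes, correlation = sig$correlations),
          file.path(out_dir, "exhaustion_signature.csv"), row.names = FALSE)
write.csv(data.frame(cluster = names(cl), mean_score = as.numeric(cl)),
          file.path(out_dir, "exhaustion_cluster_scores.csv"),
          row.names = FALSE)

# pairwise correlation between the anchor and the top derived gene
pc <- pairwise_gene_correlation(norm, "LAG3", sig$genes[1], subset = t_cells)
cat(sprintf("LAG3 vs %s within T cells: r = %.3f, p = %.3g\n",
            sig$genes[1], pc$r, pc$p_value))
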