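#!/usr/bin/env Rscript

# Step 6: compositional analysis. Per-sample cell-type fractions and paired
# tumor-vs-adjacent tests for each cell type.

library(immunotme)

in_dir <- "results/cohort"
out_dir <- "results"

mat <- attach_metadata(
  read_counts_mtx(file.path(in_dir, "matrix.mtx"),
                  file.path(in_dir, "features.tsv"),
                  file.path(in_dir, "barcodes.tsv")),
  file.path(in_dir, "annotations.csv"))
meta <- mat$cell_meta

ftab <- fraction_table(meta, "cell_type")
write.csv(ftab, file.path(out_dir, "fractions.csv"), row.names = FALSE)

tests <- do.call(rbind, lapply(sort(unique(ftab$unit)), function(u) {
  r <- paired_tissue_test(ftab, u)
  data.frame(cell_type = u, p_value = r$p_value,
             direction = r$direction, n_pairs = r$n_pairs,
             stringsAsFactors = FALSE)
}))
print(tests)
write.csv(tests, file.path(out_dir, "composition_tests.csv"),
          row.names = FALSE)
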