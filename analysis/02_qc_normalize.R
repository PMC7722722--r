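#!/usr/bin/env Rscript

# Step 2: read the cohort back from disk, apply quality filtering and
# normalization, and save the QC report.
#
# The synthetic cohort has ~200 genes, so the detected-gene threshold is
# scaled down from the droplet-scale default; the mitochondrial rule is
# relaxed accordingly because the generator inflates its 13 mitochondrial
# genes to create realistic mass there.

library(immunotme)

in_dir <- "results/cohort"
out_dir <- "results"

mat <- read_counts_mtx(file.path(in_dir, "matrix.mtx"),
                       file.path(in_dir, "features.tsv"),
                       file.path(in_dir, "barcodes.tsv"))
mat <- attach_metadata(mat, file.path(in_dir, "annotations.csv"))

qc <- qc_filter(mat, min_genes = 30, max_mito_frac = 0.5)
print(qc$report)

norm <- normalize_log2(qc$matrix)
cat(sprintf("normalized: %d cells, scale = %s\n",
            ncol(norm$values), norm$scale))

dir.create(out_dir, showWarnings = FALSE)
rep <- qc$report
write.csv(data.frame(metric = names(unclass(rep)),
                     value = unlist(unclass(rep), use.names = FALSE)),
          file.path(out_dir, "qc_report.csv"), row.names = FALSE)
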