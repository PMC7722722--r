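#!/usr/bin/env Rscript

# Step 1: simulate the paired tumor/adjacent immune cohort and write it to
# disk in the 10x-style text layout the rest of the workflow reads back.

library(immunotme)

seed <- 20260101L
out_dir <- "results/cohort"

cfg <- sim_config(seed = seed)
ds <- simulate_cohort(cfg)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_cohort(ds, out_dir)

meta <- ds$matrix$cell_meta
cat(sprintf("cohort: %d cells, %d genes, %d patients x 2 tissues\n",
            ncol(ds$matrix$counts), nrow(ds$matrix$counts),
            cfg$n_patients))
cat(sprintf("contig rows: %d over %d T cells\n", nrow(ds$contigs),
            sum(meta$cell_type %in% ds$truth$t_cell_types)))
cat("written to", out_dir, "\n")
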