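# Shared fixtures and independent oracles, all built in code.

# Small annotated count matrix with explicit values.
toy_matrix <- function() {
  counts <- rbind(
    GZMB  = c(5, 0, 2, 1),
    FOXP3 = c(0, 3, 0, 0),
    CCR7  = c(1, 1, 4, 0),
    CONST = c(2, 2, 2, 2)
  )
  colnames(counts) <- paste0("c", 1:4)
  meta <- data.frame(
    barcode = colnames(counts),
    patient_id = c("P1", "P1", "P2", "P2"),
    tissue = c("tumor", "adjacent", "tumor", "adjacent"),
    cell_type = c("T", "T", "B", "B"),
    cluster = c("T", "T", "B", "B"),
    stringsAsFactors = FALSE
  )
  expression_matrix(counts, cell_meta = meta)
}

# QC toy: 5 cells with prescribed detected-gene counts and mito fractions.
# Per cell: one mito gene with m counts plus (d - 1) non-mito genes with one
# count each, then top up the first non-mito gene so totals hit 1000.
qc_toy_matrix <- function(detected = c(500, 399, 450, 600, 700),
                          mito_frac = c(0.02, 0.01, 0.15, 0.09, 0.11),
                          total = 1000) {
  n_genes <- max(detected)  # non-mito pool
  genes <- c("MT-ND1", sprintf("G%04d", seq_len(n_genes)))
  counts <- matrix(0, nrow = length(genes), ncol = length(detected),
                   dimnames = list(genes, sprintf("cell%02d", seq_along(detected))))
  for (i in seq_along(detected)) {
    m <- mito_frac[i] * total
    stopifnot(m == round(m))
    counts["MT-ND1", i] <- m
    k <- detected[i] - 1
    counts[1 + seq_len(k), i] <- 1
    counts[2, i] <- counts[2, i] + (total - m - k)
  }
  expression_matrix(counts)
}

# Brute-force QC rule check: per-cell loop over the two stated rules.
brute_qc_kept <- function(mat, min_genes = 400, max_mito = 0.10,
                          prefix = "MT-") {
  counts <- as.matrix(mat$counts)
  keep <- logical(ncol(counts))
  for (i in seq_len(ncol(counts))) {
    x <- counts[, i]
    det <- sum(x > 0)
    mito <- sum(x[startsWith(names(x), prefix)])
    frac <- if (sum(x) > 0) mito / sum(x) else 0
    keep[i] <- !(det < min_genes) && !(frac > max_mito)
  }
  keep
}

# Exact one-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (zeros dropped, midranks under ties). Independent of the
# package's convolution path.
brute_wilcox_greater <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(w_all >= w_obs - 1e-9)
}

# Brute-force clonotype assignment: per-cell explicit dominant-chain
# selection, then a group-by on (patient, alpha, beta).
brute_assign <- function(contigs, universe, patient_of) {
  pick_dominant <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(NA_character_)
    best <- df[df$umis == max(df$umis), , drop = FALSE]
    sort(best$cdr3_nt)[1]
  }
  by_bc_a <- split(contigs[contigs$chain == "TRA", , drop = FALSE],
                   contigs$barcode[contigs$chain == "TRA"])
  by_bc_b <- split(contigs[contigs$chain == "TRB", , drop = FALSE],
                   contigs$barcode[contigs$chain == "TRB"])
  res <- data.frame(barcode = universe, alpha = NA_character_,
                    beta = NA_character_, key = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(universe)) {
    bc <- universe[i]
    a <- pick_dominant(by_bc_a[[bc]])
    b <- pick_dominant(by_bc_b[[bc]])
    res$alpha[i] <- a
    res$beta[i] <- b
    if (!is.na(a) && !is.na(b)) {
      res$key[i] <- paste(patient_of[bc], a, b, sep = "|")
    }
  }
  res
}

# Random productive contig table over a universe, with multi-TRA cells,
# chain dropout and UMI ties.
random_contig_table <- function(n_cells, n_patients = 3, seed = 1) {
  set.seed(seed)
  universe <- sprintf("bc%04d", seq_len(n_cells))
  patient_of <- setNames(sample(sprintf("P%d", seq_len(n_patients)),
                                n_cells, replace = TRUE), universe)
  seq_pool_a <- sprintf("A%03d", seq_len(max(3, n_cells %/% 4)))
  seq_pool_b <- sprintf("B%03d", seq_len(max(3, n_cells %/% 4)))
  rows <- list()
  for (bc in universe) {
    n_tra <- sample(0:3, 1, prob = c(0.2, 0.5, 0.2, 0.1))
    n_trb <- sample(0:2, 1, prob = c(0.15, 0.7, 0.15))
    if (n_tra > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        barcode = bc, chain = "TRA",
        cdr3_nt = paste0(patient_of[bc], sample(seq_pool_a, n_tra)),
        productive = "True", full_length = "True",
        umis = sample(1:5, n_tra, replace = TRUE),
        patient_id = unname(patient_of[bc]), stringsAsFactors = FALSE)
    }
    if (n_trb > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        barcode = bc, chain = "TRB",
        cdr3_nt = paste0(patient_of[bc], sample(seq_pool_b, n_trb)),
        productive = "True", full_length = "True",
        umis = sample(1:5, n_trb, replace = TRUE),
        patient_id = unname(patient_of[bc]), stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, rows)
  contigs$cdr3 <- substr(contigs$cdr3_nt, 1, 4)
  list(contigs = contigs, universe = universe, patient_of = patient_of)
}

# Rank-based AUROC of a score separating positives from negatives
# (Mann-Whitney identity).
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A small cohort config for fast unit tests (full-size defaults are kept
# for the acceptance checks).
small_config <- function(seed = 1, n_patients = 3, cells_per_sample = 300,
                         ...) {
  sim_config(seed = seed, cells_per_sample = cells_per_sample,
             n_patients = n_patients, ...)
}
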