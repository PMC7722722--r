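#' Default configuration for the synthetic paired-cohort generator
#'
#' Builds the full parameterization of a seeded synthetic cohort: a
#' multi-patient paired tumor/adjacent design with planted cell-type marker
#' programs, planted ligand-receptor co-expression, a lineage-silent gene
#' pool, mitochondrial genes, and clonal TCR structure. Defaults emulate a
#' seven-patient paired esophageal-tumor immune cohort at a reduced,
#' panel-sized gene space.
#'
#' Gene classes:
#' * marker genes carry a `fold_up` mean shift in their own cell type and
#'   baseline expression elsewhere;
#' * ligand/receptor genes and the dedicated null pool are lineage-silent
#'   (leaky mean `baseline_mean * silent_mean_frac`) everywhere except where
#'   a pair is planted, emulating lineage-restricted expression;
#' * mitochondrial genes (`MT-` prefix) have mean `baseline_mean * mito_mult`;
#' * remaining filler genes sit at baseline everywhere.
#'
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param n_patients number of patients, each contributing one tumor and one
#'   adjacent sample.
#' @param cells_per_sample cells per (patient, tissue) sample.
#' @param cell_types data.frame with columns `name`, `tumor_fraction`,
#'   `adjacent_fraction`, `is_t_cell`; per-tissue fractions must each sum
#'   to 1.
#' @param n_genes total genes simulated (markers + L-R + mito + silent pool +
#'   filler).
#' @param baseline_mean negative-binomial mean for an expressed gene in one
#'   cell.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param markers data.frame with columns `gene`, `cell_type`, `fold_up`.
#' @param planted_lr data.frame with columns `ligand`, `receptor`,
#'   `sender_type`, `receiver_type`, `fold_up`, `tissue` (tumor/adjacent/both).
#' @param n_silent_genes size of the dedicated lineage-silent null pool.
#' @param silent_mean_frac leaky-background mean of silent genes as a
#'   fraction of `baseline_mean`.
#' @param mito_mult mean multiplier for the 13 mitochondrial genes.
#' @param p_singleton probability a clonotype is a singleton; larger clones
#'   have size 1 + Geometric(`geometric_p`).
#' @param geometric_p geometric success probability for clone-size tails.
#' @param p_alpha_missing,p_beta_missing per-cell chain dropout
#'   probabilities (defaults emulate cohort-scale alpha/beta recovery of
#'   roughly 71 and 82 percent).
#' @param p_secondary_tra fraction of cells receiving a second, lower-UMI TRA
#'   contig (exercises dominant-chain selection).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 7L,
                       cells_per_sample = 2000L,
                       cell_types = default_cell_types(),
                       n_genes = 200L,
                       baseline_mean = 0.5,
                       dispersion = 2,
                       markers = default_markers(),
                       planted_lr = default_planted_lr(),
                       n_silent_genes = 60L,
                       silent_mean_frac = 0.005,
                       mito_mult = 5,
                       p_singleton = 0.6,
                       geometric_p = 0.5,
                       p_alpha_missing = 0.29,
                       p_beta_missing = 0.18,
                       p_secondary_tra = 0.10) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              cells_per_sample = as.integer(cells_per_sample),
              cell_types = cell_types, n_genes = as.integer(n_genes),
              baseline_mean = baseline_mean, dispersion = dispersion,
              markers = markers, planted_lr = planted_lr,
              n_silent_genes = as.integer(n_silent_genes),
              silent_mean_frac = silent_mean_frac, mito_mult = mito_mult,
              p_singleton = p_singleton, geometric_p = geometric_p,
              p_alpha_missing = p_alpha_missing,
              p_beta_missing = p_beta_missing,
              p_secondary_tra = p_secondary_tra)
  class(cfg) <- "SimulationConfig"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ct <- cfg$cell_types
  stopifnot(all(c("name", "tumor_fraction", "adjacent_fraction", "is_t_cell")
                %in% names(ct)))
  if (abs(sum(ct$tumor_fraction) - 1) > 1e-9 ||
      abs(sum(ct$adjacent_fraction) - 1) > 1e-9) {
    stop("per-tissue cell-type fractions must sum to 1")
  }
  probs <- c(cfg$p_singleton, cfg$geometric_p, cfg$p_alpha_missing,
             cfg$p_beta_missing, cfg$p_secondary_tra, cfg$silent_mean_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (nrow(cfg$markers) && any(cfg$markers$fold_up < 1)) {
    stop("marker fold_up must be >= 1")
  }
  if (nrow(cfg$planted_lr) && any(cfg$planted_lr$fold_up < 1)) {
    stop("planted L-R fold_up must be >= 1")
  }
  unknown <- setdiff(c(cfg$markers$cell_type, cfg$planted_lr$sender_type,
                       cfg$planted_lr$receiver_type), ct$name)
  if (length(unknown)) stop("unknown cell type(s): ",
                            paste(unique(unknown), collapse = ", "))
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("CD8_Tex", "CD8_Tcyto", "CD4_Treg", "CD4_Tn",
             "NK", "Macrophage", "B"),
    tumor_fraction    = c(0.15, 0.10, 0.15, 0.15, 0.10, 0.20, 0.15),
    adjacent_fraction = c(0.05, 0.20, 0.05, 0.25, 0.10, 0.15, 0.20),
    is_t_cell = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_markers <- function() {
  prog <- list(
    CD8_Tex = c("LAG3", "PDCD1", "TIGIT", "CTLA4", "HAVCR2", "TOX",
                "ENTPD1", "BATF", "PRDM1", "CXCL13", "LAYN", "DUSP4",
                "CD27", "TNFRSF9", "ID2", "RBPJ"),
    CD8_Tcyto = c("FGFBP2", "GZMB", "PRF1", "NKG7", "GNLY", "GZMH"),
    CD4_Treg = c("FOXP3", "IL2RA", "IKZF2", "TNFRSF4"),
    CD4_Tn = c("CCR7", "TCF7", "LEF1", "SELL"),
    NK = c("KLRC1", "KLRD1", "XCL1"),
    Macrophage = c("CD68", "CD14", "CSF1R", "LYZ"),
    B = c("CD79A", "MS4A1", "CD19")
  )
  data.frame(
    gene = unlist(prog, use.names = FALSE),
    cell_type = rep(names(prog), lengths(prog)),
    fold_up = 6,
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_planted_lr <- function() {
  data.frame(
    ligand = c("IL1B", "CCL4", "TNF"),
    receptor = c("IL1R2", "CCR8", "TNFRSF1B"),
    sender_type = "Macrophage",
    receiver_type = "CD4_Treg",
    fold_up = 4,
    tissue = "tumor",
    stringsAsFactors = FALSE
  )
}

mito_gene_names <- function() {
  paste0("MT-", c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                  "CO1", "CO2", "CO3", "ATP6", "ATP8", "CYB"))
}

# Full gene universe for a config, with per-gene class labels.
sim_gene_table <- function(cfg) {
  marker_genes <- unique(cfg$markers$gene)
  lr_genes <- unique(c(cfg$planted_lr$ligand, cfg$planted_lr$receptor))
  lr_genes <- setdiff(lr_genes, marker_genes)
  mito <- mito_gene_names()
  silent <- sprintf("NULLG%03d", seq_len(cfg$n_silent_genes))
  n_fixed <- length(marker_genes) + length(lr_genes) + length(mito) +
    length(silent)
  n_filler <- cfg$n_genes - n_fixed
  if (n_filler < 0) stop("n_genes too small for the configured gene classes")
  filler <- if (n_filler > 0) sprintf("GENE%03d", seq_len(n_filler)) else character()
  data.frame(
    gene = c(marker_genes, lr_genes, mito, silent, filler),
    class = rep(c("marker", "lr", "mito", "silent", "filler"),
                c(length(marker_genes), length(lr_genes), length(mito),
                  length(silent), n_filler)),
    stringsAsFactors = FALSE
  )
}

# gene x (type, tissue) mean matrix implied by a config
sim_mean_model <- function(cfg) {
  genes <- sim_gene_table(cfg)
  types <- cfg$cell_types$name
  combos <- expand.grid(type = types, tissue = valid_tissues,
                        stringsAsFactors = FALSE)
  mu <- matrix(cfg$baseline_mean, nrow = nrow(genes), ncol = nrow(combos),
               dimnames = list(genes$gene,
                               paste(combos$type, combos$tissue, sep = ".")))
  silent_rows <- genes$class %in% c("lr", "silent")
  mu[silent_rows, ] <- cfg$baseline_mean * cfg$silent_mean_frac
  mu[genes$class == "mito", ] <- cfg$baseline_mean * cfg$mito_mult
  for (i in seq_len(nrow(cfg$markers))) {
    m <- cfg$markers[i, ]
    if (!m$gene %in% genes$gene) stop("marker gene not simulated: ", m$gene)
    cols <- combos$type == m$cell_type
    mu[m$gene, cols] <- cfg$baseline_mean * m$fold_up
  }
  for (i in seq_len(nrow(cfg$planted_lr))) {
    p <- cfg$planted_lr[i, ]
    tissues <- if (p$tissue == "both") valid_tissues else p$tissue
    lcols <- combos$type == p$sender_type & combos$tissue %in% tissues
    rcols <- combos$type == p$receiver_type & combos$tissue %in% tissues
    mu[p$ligand, lcols] <- cfg$baseline_mean * p$fold_up
    mu[p$receptor, rcols] <- cfg$baseline_mean * p$fold_up
  }
  list(mu = mu, genes = genes, combos = combos)
}

#' Simulate the expression side of a synthetic paired cohort
#'
#' Draws negative-binomial UMI counts for every cell of every
#' (patient, tissue) sample under the mean model implied by the
#' configuration, and fills in annotations (patient, tissue, cell type,
#' cluster). Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return an annotated `ExpressionMatrix`.
#' @export
simulate_expression <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  model <- sim_mean_model(cfg)
  ct <- cfg$cell_types
  n_genes <- nrow(model$mu)

  metas <- list()
  for (p in seq_len(cfg$n_patients)) {
    patient <- sprintf("P%02d", p)
    for (tissue in valid_tissues) {
      frac <- if (tissue == "tumor") ct$tumor_fraction else ct$adjacent_fraction
      type_idx <- sample.int(nrow(ct), cfg$cells_per_sample, replace = TRUE,
                             prob = frac)
      types <- ct$name[type_idx]
      barcodes <- sprintf("%s_%s_c%04d", patient, tissue,
                          seq_len(cfg$cells_per_sample))
      metas[[length(metas) + 1]] <- data.frame(
        barcode = barcodes, patient_id = patient, tissue = tissue,
        cell_type = types, cluster = types, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, metas)
  mu_cells <- model$mu[, paste(meta$cell_type, meta$tissue, sep = "."),
                       drop = FALSE]
  counts <- matrix(
    stats::rnbinom(length(mu_cells), mu = as.numeric(mu_cells),
                   size = cfg$dispersion),
    nrow = n_genes, dimnames = list(rownames(model$mu), meta$barcode))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  expression_matrix(counts, cell_meta = meta)
}

# deterministic DNA prefix encoding a patient index (8-mer)
patient_prefix <- function(p) {
  digits <- integer(4)
  x <- p - 1
  for (i in 4:1) { digits[i] <- x %% 4; x <- x %/% 4 }
  paste(c("ACGT")[1], paste0(c("A", "C", "G", "T")[digits + 1], collapse = ""),
        sep = "")
}

random_cdr3 <- function(n, prefix) {
  lens <- sample(25:40, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(prefix, paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                          collapse = ""))
  }, character(1))
}

#' Simulate TCR contigs with planted clonal structure
#'
#' Assigns each T cell to a clonotype within its patient (clonotypes never
#' cross patients: CDR3 strings carry a deterministic per-patient prefix),
#' with singleton probability `p_singleton` and otherwise size
#' 1 + Geometric(`geometric_p`). Each cell emits a TRA and a TRB contig
#' subject to independent chain dropout; a configurable fraction of cells
#' receives a second, lower-UMI TRA.
#'
#' @param cfg a [sim_config()].
#' @param t_cell_barcodes barcodes of the T cells (nonempty).
#' @param patient_ids patient id per barcode.
#' @return list with `contigs` (a contig data.frame in the filtered-contig
#'   dialect) and `truth` (data.frame barcode/clonotype id/clone size).
#' @export
simulate_tcr <- function(cfg, t_cell_barcodes, patient_ids) {
  if (length(t_cell_barcodes) == 0) stop("empty barcode list")
  stopifnot(length(patient_ids) == length(t_cell_barcodes))
  set.seed(cfg$seed + 1L)

  truth <- NULL
  contigs <- list()
  for (patient in unique(patient_ids)) {
    bcs <- t_cell_barcodes[patient_ids == patient]
    n <- length(bcs)
    bcs <- sample(bcs)  # random clone membership across tissues/types
    prefix <- patient_prefix(match(patient, unique(patient_ids)))

    # draw clone sizes until the patient's cells are exhausted
    sizes <- integer(0)
    total <- 0
    while (total < n) {
      s <- if (stats::runif(1) < cfg$p_singleton) 1L else
        1L + stats::rgeom(1, cfg$geometric_p) + 1L
      s <- min(s, n - total)
      sizes <- c(sizes, s)
      total <- total + s
    }
    clone_of_cell <- rep(seq_along(sizes), sizes)

    alpha_seqs <- random_cdr3(length(sizes), paste0(prefix, "A"))
    beta_seqs <- random_cdr3(length(sizes), paste0(prefix, "B"))
    cell_alpha <- alpha_seqs[clone_of_cell]
    cell_beta <- beta_seqs[clone_of_cell]

    keep_a <- stats::runif(n) >= cfg$p_alpha_missing
    keep_b <- stats::runif(n) >= cfg$p_beta_missing
    umi_a <- 2L + stats::rpois(n, 3)
    umi_b <- 2L + stats::rpois(n, 3)

    mk <- function(bc, chain, cdr3nt, umis) {
      data.frame(barcode = bc, chain = chain,
                 v_gene = paste0("TR", substr(chain, 3, 3), "V1"),
                 j_gene = paste0("TR", substr(chain, 3, 3), "J1"),
                 cdr3 = substr(cdr3nt, 1, 15), cdr3_nt = cdr3nt,
                 productive = "True", full_length = "True",
                 umis = umis, patient_id = patient,
                 stringsAsFactors = FALSE)
    }
    contigs[[length(contigs) + 1]] <-
      mk(bcs[keep_a], "TRA", cell_alpha[keep_a], umi_a[keep_a])
    contigs[[length(contigs) + 1]] <-
      mk(bcs[keep_b], "TRB", cell_beta[keep_b], umi_b[keep_b])

    # secondary lower-UMI TRA for a fraction of alpha-carrying cells
    sec <- keep_a & stats::runif(n) < cfg$p_secondary_tra
    if (any(sec)) {
      sec_seqs <- random_cdr3(sum(sec), paste0(prefix, "S"))
      contigs[[length(contigs) + 1]] <-
        mk(bcs[sec], "TRA", sec_seqs, pmax(1L, umi_a[sec] - 1L))
    }

    truth <- rbind(truth, data.frame(
      barcode = bcs, patient_id = patient,
      clonotype_id = paste0(patient, ":", clone_of_cell),
      clone_size = sizes[clone_of_cell],
      has_alpha = keep_a, has_beta = keep_b,
      stringsAsFactors = FALSE))
  }
  contigs <- do.call(rbind, contigs)
  rownames(contigs) <- NULL
  list(contigs = contigs, truth = truth)
}

#' Simulate a full paired cohort with ground truth
#'
#' @param cfg a [sim_config()].
#' @return a `SyntheticDataset`: list with `matrix` (annotated
#'   `ExpressionMatrix`), `contigs` (contig table over the T cells), and
#'   `truth` (planted markers, planted L-R pairs, silent-gene pool, per-cell
#'   clonotype membership and sizes).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  mat <- simulate_expression(cfg)
  meta <- mat$cell_meta
  t_types <- cfg$cell_types$name[cfg$cell_types$is_t_cell]
  is_t <- meta$cell_type %in% t_types
  tcr <- simulate_tcr(cfg, meta$barcode[is_t], meta$patient_id[is_t])
  genes <- sim_gene_table(cfg)
  structure(list(
    matrix = mat,
    contigs = tcr$contigs,
    truth = list(markers = cfg$markers, planted_lr = cfg$planted_lr,
                 gene_classes = genes,
                 silent_genes = genes$gene[genes$class == "silent"],
                 t_cell_types = t_types,
                 clonotypes = tcr$truth),
    config = cfg
  ), class = "SyntheticDataset")
}

#' Write a synthetic cohort in the formats the readers consume
#'
#' Emits `matrix.mtx` + `features.tsv` + `barcodes.tsv`, `annotations.csv`
#' and `contigs.csv` under `dir`, so the pipeline runs unchanged on synthetic
#' output.
#'
#' @param dataset a `SyntheticDataset`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  paths <- write_counts_mtx(dataset$matrix, dir)
  contig_path <- file.path(dir, "contigs.csv")
  utils::write.csv(dataset$contigs, contig_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(paths, contig_path))
}
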