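#' Rank-based AUROC
#'
#' Area under the ROC curve for a score separating a positive class from the
#' rest, computed via the Mann-Whitney rank identity.
#'
#' @param score numeric score per unit.
#' @param positive logical vector marking the positive class.
#' @return AUROC in \[0, 1\].
#' @export
rank_auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be nonempty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Planted ligand-receptor recovery experiment
#'
#' Repeatedly simulates the paired cohort and screens the planted
#' ligand-receptor pairs, recording whether each is called significant in
#' the tissue it was planted in and in the other tissue. Sensitivity is the
#' fraction of (replicate, pair) combinations called in the planted tissue.
#'
#' @param n_reps number of simulation replicates.
#' @param base_seed seed offset; replicate r uses `base_seed + r`.
#' @param cfg cohort configuration template (its seed field is overridden
#'   per replicate).
#' @param alpha significance level for the call.
#' @return list with `sensitivity`, `off_tissue_call_rate`, and the
#'   per-replicate `calls` data.frame.
#' @export
lr_recovery_experiment <- function(n_reps = 100, base_seed = 1000,
                                   cfg = sim_config(), alpha = 0.05) {
  planted <- cfg$planted_lr
  stopifnot(nrow(planted) > 0, all(planted$tissue != "both"))
  type_pairs <- unique(planted[, c("sender_type", "receiver_type")])
  calls <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    mat <- simulate_expression(cfg_r)
    scr <- interaction_screen(normalize_log2(mat), load_lr_pairs(planted),
                              type_pairs, alpha = alpha)
    key <- paste(scr$ligand, scr$receptor, scr$sender_type,
                 scr$receiver_type)
    pkey <- paste(planted$ligand, planted$receptor, planted$sender_type,
                  planted$receiver_type)
    on_t <- scr$significant[match(paste(pkey, planted$tissue),
                                  paste(key, scr$tissue))]
    other <- ifelse(planted$tissue == "tumor", "adjacent", "tumor")
    off_t <- scr$significant[match(paste(pkey, other),
                                   paste(key, scr$tissue))]
    calls[[r]] <- data.frame(rep = r, ligand = planted$ligand,
                             receptor = planted$receptor,
                             called_planted_tissue = on_t,
                             called_other_tissue = off_t,
                             stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  list(sensitivity = mean(calls$called_planted_tissue),
       off_tissue_call_rate = mean(calls$called_other_tissue),
       calls = calls)
}

#' Null ligand-receptor false-call experiment
#'
#' Screens pairs drawn from the cohort's lineage-silent gene pool — genes
#' with no planted expression in any cell type — across random sender and
#' receiver types, and reports the fraction called significant. These pairs
#' satisfy the null of the "significantly larger than zero" test, so the
#' rate estimates the screen's false-call rate.
#'
#' @param dataset a `SyntheticDataset` from [simulate_cohort()], or NULL to
#'   simulate one from `cfg`.
#' @param cfg configuration used when `dataset` is NULL.
#' @param n_pairs number of null pairs to draw.
#' @param seed seed for the pair draw (and the cohort when simulated here).
#' @param alpha significance level.
#' @return list with `false_call_rate`, `n_pairs`, and the screen table.
#' @export
lr_null_experiment <- function(dataset = NULL, cfg = sim_config(),
                               n_pairs = 1000, seed = 1, alpha = 0.05) {
  if (is.null(dataset)) {
    cfg$seed <- as.integer(seed)
    dataset <- simulate_cohort(cfg)
  }
  silent <- dataset$truth$silent_genes
  stopifnot(length(silent) >= 3)
  types <- dataset$config$cell_types$name
  set.seed(seed + 7L)
  lig <- sample(silent, n_pairs, replace = TRUE)
  rec <- sample(silent, n_pairs, replace = TRUE)
  fix <- lig == rec
  while (any(fix)) {  # redraw self-pairs
    rec[fix] <- sample(silent, sum(fix), replace = TRUE)
    fix <- lig == rec
  }
  senders <- sample(types, n_pairs, replace = TRUE)
  receivers <- sample(types, n_pairs, replace = TRUE)

  norm <- normalize_log2(dataset$matrix)
  ts <- type_sample_means(norm)
  group_key <- paste(ts$groups$cell_type, ts$groups$patient_id,
                     ts$groups$tissue)
  patients <- sort(unique(ts$groups$patient_id))
  called <- logical(n_pairs)
  pvals <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    s_col <- match(paste(senders[i], patients, "tumor"), group_key)
    r_col <- match(paste(receivers[i], patients, "tumor"), group_key)
    lm <- ts$means[lig[i], ifelse(is.na(s_col), 1, s_col)]
    lm[is.na(s_col)] <- NA
    rm_ <- ts$means[rec[i], ifelse(is.na(r_col), 1, r_col)]
    rm_[is.na(r_col)] <- NA
    res <- call_interactions(lm * rm_, alpha = alpha)
    called[i] <- res$significant
    pvals[i] <- res$p_value
  }
  list(false_call_rate = mean(called), n_pairs = n_pairs,
       table = data.frame(ligand = lig, receptor = rec,
                          sender_type = senders, receiver_type = receivers,
                          p_value = pvals, significant = called,
                          stringsAsFactors = FALSE))
}

#' Exhaustion-signature separation experiment
#'
#' Simulates a cohort, derives the exhaustion signature from the genes most
#' correlated with the LAG3 anchor within T cells, scores the T cells, and
#' measures how well the signature separates the planted exhausted cluster
#' from the other T clusters.
#'
#' @param seed cohort seed.
#' @param cells_per_sample cells per sample (one patient, two tissues).
#' @param k signature size.
#' @param anchor anchor gene.
#' @param exhausted_cluster the cluster the signature should single out.
#' @return list with `auroc`, `top_cluster`, `cluster_scores`, `signature`.
#' @export
exhaustion_separation_experiment <- function(seed = 1,
                                             cells_per_sample = 1000,
                                             k = 50, anchor = "LAG3",
                                             exhausted_cluster = "CD8_Tex") {
  cfg <- sim_config(seed = as.integer(seed), n_patients = 1L,
                    cells_per_sample = as.integer(cells_per_sample))
  mat <- simulate_expression(cfg)
  meta <- mat$cell_meta
  t_types <- cfg$cell_types$name[cfg$cell_types$is_t_cell]
  t_cells <- meta$barcode[meta$cell_type %in% t_types]
  norm <- normalize_log2(mat)
  sig <- derive_correlation_signature(norm, anchor, k = k, subset = t_cells)
  z <- zscore_by_gene(norm, within = t_cells)
  scores <- score_signature(z, sig)
  labels <- meta$cluster[match(t_cells, meta$barcode)]
  cluster_scores <- sort(tapply(scores$cell_scores, labels, mean),
                         decreasing = TRUE)
  list(auroc = rank_auroc(scores$cell_scores,
                          labels == exhausted_cluster),
       top_cluster = names(cluster_scores)[1],
       cluster_scores = cluster_scores,
       signature = sig)
}
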