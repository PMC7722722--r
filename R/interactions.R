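#' Load a ligand-receptor pair catalogue
#'
#' @param pairs data.frame or two-column CSV path with header columns
#'   `ligand`, `receptor` (extra columns kept as annotations). Duplicate
#'   rows are collapsed; a pair whose ligand equals its receptor is kept but
#'   flagged.
#' @return data.frame with columns `ligand`, `receptor`, `self_pair`.
#' @export
load_lr_pairs <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1) {
    pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    stop("pair table needs 'ligand' and 'receptor' columns")
  }
  if (nrow(pairs) == 0) stop("empty pair table")
  pairs$ligand <- trimws(pairs$ligand)
  pairs$receptor <- trimws(pairs$receptor)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    stop("blank ligand or receptor gene")
  }
  pairs <- pairs[!duplicated(pairs[, c("ligand", "receptor")]), , drop = FALSE]
  pairs$self_pair <- pairs$ligand == pairs$receptor
  rownames(pairs) <- NULL
  pairs
}

#' Per-sample ligand-receptor score
#'
#' The score of a pair for one sample is the average expression of the
#' ligand over the sender-type cells of that sample multiplied by the
#' average expression of the receptor over the receiver-type cells, on
#' log2(count+1) values.
#'
#' @param norm an annotated `NormalizedMatrix` at scale `log2p1`.
#' @param ligand,receptor gene symbols.
#' @param sender_type,receiver_type cell types.
#' @param patient,tissue sample identity.
#' @return the non-negative score, or `NA` when either cell type is absent
#'   from the sample (absent, not zero).
#' @export
lr_score <- function(norm, ligand, receptor, sender_type, receiver_type,
                     patient, tissue) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log2p1") stop("lr_score expects log2p1 values")
  meta <- norm$cell_meta
  if (is.null(meta)) stop("annotated matrix required")
  for (g in c(ligand, receptor)) {
    if (!g %in% rownames(norm$values)) stop("gene missing: ", g)
  }
  in_sample <- meta$patient_id == patient & meta$tissue == tissue
  send <- in_sample & meta$cell_type == sender_type
  recv <- in_sample & meta$cell_type == receiver_type
  if (!any(send) || !any(recv)) return(NA_real_)
  mean(norm$values[ligand, send]) * mean(norm$values[receptor, recv])
}

#' Exact one-sided Wilcoxon signed-rank test against zero
#'
#' Tests whether scores are significantly larger than zero. Zeros are
#' dropped before ranking (standard signed-rank convention); ties in the
#' absolute values take midranks. For n <= `exact_max` nonzero scores the
#' p-value P(W+ >= observed) is computed from the exact null distribution of
#' the signed-rank sum (all 2^n sign assignments equiprobable, evaluated by
#' dynamic programming over doubled midranks, which handles ties exactly);
#' above that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param scores numeric vector.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `p_value`, `statistic` (W+), `n_used` (nonzero scores),
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank_greater <- function(scores, exact_max = 25) {
  x <- scores[!is.na(scores)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) {
    return(list(p_value = 1, statistic = 0, n_used = 0L, method = "exact"))
  }
  r <- rank(abs(x))  # midranks under ties
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    d <- as.integer(round(2 * r))  # doubled midranks are integers
    # null distribution of the doubled signed-rank sum by convolution
    f <- 1
    for (di in d) {
      g <- numeric(length(f) + di)
      g[seq_along(f)] <- f / 2
      g[seq_along(f) + di] <- g[seq_along(f) + di] + f / 2
      f <- g
    }
    support <- seq_along(f) - 1L
    p <- sum(f[support >= round(2 * w) - 1e-9])
    list(p_value = p, statistic = w, n_used = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    list(p_value = stats::pnorm(z, lower.tail = FALSE), statistic = w,
         n_used = n, method = "normal")
  }
}

#' Call an interaction from per-sample scores
#'
#' An interaction is called when the per-patient scores are significantly
#' larger than zero by the exact one-sided Wilcoxon signed-rank test at
#' level `alpha`. Samples where either cell type was absent (`NA` scores)
#' are excluded from the test; fewer than `min_samples` usable scores flags
#' the result as having insufficient samples (never significant).
#'
#' @param per_sample_scores numeric vector of per-patient scores (may
#'   contain `NA` for missing samples).
#' @param alpha significance level (default 0.05).
#' @param min_samples minimum usable samples for a call (default 2).
#' @return list: `p_value`, `significant`, `mean_score`, `n_samples`,
#'   `insufficient_samples`, `statistic`.
#' @export
call_interactions <- function(per_sample_scores, alpha = 0.05,
                              min_samples = 2) {
  usable <- per_sample_scores[!is.na(per_sample_scores)]
  if (length(usable) == 0) stop("no usable sample scores")
  insufficient <- length(usable) < min_samples
  test <- wilcoxon_signed_rank_greater(usable)
  list(p_value = test$p_value,
       significant = !insufficient && test$p_value < alpha,
       mean_score = mean(usable),
       n_samples = length(usable),
       insufficient_samples = insufficient,
       statistic = test$statistic)
}

# per-(gene, cell type, sample) mean expression; fast path for the screen
type_sample_means <- function(norm) {
  meta <- norm$cell_meta
  grp <- interaction(meta$cell_type, meta$patient_id, meta$tissue,
                     sep = "\r", drop = TRUE)
  idx <- as.integer(grp)
  k <- nlevels(grp)
  design <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                                 dims = c(length(idx), k))
  n_per <- Matrix::colSums(design)
  means <- sweep(as.matrix(norm$values %*% design), 2, n_per, "/")
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  list(means = means,
       groups = data.frame(cell_type = parts[, 1], patient_id = parts[, 2],
                           tissue = parts[, 3], stringsAsFactors = FALSE))
}

#' Screen ligand-receptor pairs across cell-type pairs and tissues
#'
#' Scores every (pair, sender type, receiver type, tissue) combination per
#' patient and applies the exact Wilcoxon call. No multiple-testing
#' correction enters the call itself; a Benjamini-Hochberg column
#' (`p_adj_bh`, per tissue) is emitted alongside purely for the reader, and
#' the number of tests performed is reported in the `n_tests` attribute.
#'
#' @param norm an annotated `NormalizedMatrix` at scale `log2p1`.
#' @param pairs pair catalogue (see [load_lr_pairs()]).
#' @param type_pairs data.frame with columns `sender_type`, `receiver_type`.
#' @param alpha significance level.
#' @param tissues tissues to screen (default both).
#' @param min_samples minimum usable samples per call.
#' @return data.frame, one row per (ligand, receptor, sender, receiver,
#'   tissue), sorted by tissue then descending mean score: `n_samples`,
#'   `mean_score`, `p_value`, `significant`, `insufficient_samples`,
#'   `p_adj_bh`.
#' @export
interaction_screen <- function(norm, pairs, type_pairs, alpha = 0.05,
                               tissues = valid_tissues, min_samples = 2) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log2p1") stop("interaction_screen expects log2p1 values")
  if (is.null(norm$cell_meta)) stop("annotated matrix required")
  ts <- type_sample_means(norm)
  patients <- sort(unique(ts$groups$patient_id))
  group_key <- paste(ts$groups$cell_type, ts$groups$patient_id,
                     ts$groups$tissue)
  genes_missing <- setdiff(unique(c(pairs$ligand, pairs$receptor)),
                           rownames(ts$means))
  if (length(genes_missing)) {
    stop("gene(s) missing from matrix: ",
         paste(utils::head(genes_missing, 5), collapse = ", "))
  }

  rows <- vector("list", nrow(pairs) * nrow(type_pairs) * length(tissues))
  ri <- 0
  for (tissue in tissues) {
    for (tp in seq_len(nrow(type_pairs))) {
      sender <- type_pairs$sender_type[tp]
      receiver <- type_pairs$receiver_type[tp]
      s_col <- match(paste(sender, patients, tissue), group_key)
      r_col <- match(paste(receiver, patients, tissue), group_key)
      for (pi in seq_len(nrow(pairs))) {
        lmeans <- ts$means[pairs$ligand[pi], ifelse(is.na(s_col), 1, s_col)]
        lmeans[is.na(s_col)] <- NA
        rmeans <- ts$means[pairs$receptor[pi], ifelse(is.na(r_col), 1, r_col)]
        rmeans[is.na(r_col)] <- NA
        scores <- lmeans * rmeans
        call <- if (all(is.na(scores))) {
          list(p_value = NA_real_, significant = FALSE,
               mean_score = NA_real_, n_samples = 0L,
               insufficient_samples = TRUE)
        } else {
          call_interactions(scores, alpha, min_samples)
        }
        ri <- ri + 1
        rows[[ri]] <- data.frame(
          ligand = pairs$ligand[pi], receptor = pairs$receptor[pi],
          sender_type = sender, receiver_type = receiver, tissue = tissue,
          n_samples = call$n_samples, mean_score = call$mean_score,
          p_value = call$p_value, significant = call$significant,
          insufficient_samples = call$insufficient_samples,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out$p_adj_bh <- NA_real_
  for (tissue in tissues) {
    sel <- out$tissue == tissue
    out$p_adj_bh[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out <- out[order(out$tissue, -out$mean_score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- ri
  out
}
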