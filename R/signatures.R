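#' Create a gene signature
#'
#' @param name signature name.
#' @param genes character vector of gene symbols; duplicates are removed
#'   (first occurrence kept).
#' @param provenance one of `published`, `anchor_derived`, `fixed_naive`.
#' @param anchor,correlations for anchor-derived signatures: the anchor gene
#'   and the per-gene correlation values (sorted non-increasing, one per
#'   signature gene).
#' @return a `GeneSignature`.
#' @export
gene_signature <- function(name, genes, provenance = "published",
                           anchor = NULL, correlations = NULL) {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0) stop("signature has no genes")
  if (provenance == "anchor_derived") {
    if (is.null(correlations) || length(correlations) != length(genes)) {
      stop("anchor-derived signatures need one correlation per gene")
    }
    if (is.unsorted(rev(correlations))) {
      stop("anchor-derived correlations must be non-increasing")
    }
  }
  structure(list(name = name, genes = genes, provenance = provenance,
                 anchor = anchor, correlations = correlations),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes\n", x$name, x$provenance,
              length(x$genes)))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of `GeneSignature` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_signature(parts[1], parts[-(1:2)])
  })
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  sigs
}

#' Score cells (and clusters) against a gene signature
#'
#' The per-cell score is the mean, over the signature genes present in the
#' matrix, of the gene's per-gene z-scored log2(count+1) value. Genes absent
#' from the matrix are dropped with a warning and recorded. Cluster-level
#' scores are means of member-cell scores, optionally re-z-scored across
#' clusters (population sd) for dot-plot style output.
#'
#' @param norm a `NormalizedMatrix` at scale `zscore_log2p1` (a `log2p1`
#'   matrix is z-scored internally).
#' @param sig a `GeneSignature`.
#' @param cluster_labels optional per-cell cluster labels (defaults to the
#'   `cluster` annotation column when present); when supplied, cluster-level
#'   scores are returned alongside the per-cell scores.
#' @param rescale_clusters re-z-score cluster means across clusters.
#' @return a `SignatureScores` object: per-cell scores, optional cluster
#'   scores, dropped genes, normalization note.
#' @export
score_signature <- function(norm, sig, cluster_labels = NULL,
                            rescale_clusters = FALSE) {
  stopifnot(inherits(norm, "NormalizedMatrix"), inherits(sig, "GeneSignature"))
  if (norm$scale == "log2p1") norm <- zscore_by_gene(norm)
  v <- norm$values
  present <- intersect(sig$genes, rownames(v))
  dropped <- setdiff(sig$genes, present)
  if (length(present) == 0) {
    stop("no signature gene present in matrix for '", sig$name, "'")
  }
  if (length(dropped)) {
    warning(sprintf("signature '%s': %d gene(s) absent from matrix (%s)",
                    sig$name, length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  cell_scores <- colMeans(v[present, , drop = FALSE])

  if (is.null(cluster_labels) && !is.null(norm$cell_meta) &&
      "cluster" %in% names(norm$cell_meta)) {
    cluster_labels <- norm$cell_meta$cluster
  }
  cluster_scores <- NULL
  normalization <- "raw_mean_z"
  if (!is.null(cluster_labels)) {
    stopifnot(length(cluster_labels) == length(cell_scores))
    cluster_scores <- tapply(cell_scores, cluster_labels, mean)
    cluster_scores <- cluster_scores[sort(names(cluster_scores))]
    if (rescale_clusters) {
      mu <- mean(cluster_scores)
      sd_pop <- sqrt(mean((cluster_scores - mu)^2))
      cluster_scores <- if (sd_pop > 1e-12) (cluster_scores - mu) / sd_pop
                        else cluster_scores * 0
      normalization <- "re_zscored_across_clusters"
    }
  }
  structure(list(signature = sig$name, cell_scores = cell_scores,
                 cluster_scores = cluster_scores,
                 dropped_genes = dropped, normalization = normalization),
            class = "SignatureScores")
}

#' @export
print.SignatureScores <- function(x, ...) {
  cat(sprintf("SignatureScores '%s': %d cells%s [%s]\n", x$signature,
              length(x$cell_scores),
              if (is.null(x$cluster_scores)) "" else
                sprintf(", %d clusters", length(x$cluster_scores)),
              x$normalization))
  invisible(x)
}

naive_marker_genes <- c("CCR7", "TCF7", "LEF1", "SELL")

#' Naive T cell score
#'
#' Z-score of the average expression of the four canonical naive markers
#' (CCR7, TCF7, LEF1, SELL).
#'
#' @inheritParams score_signature
#' @return a `SignatureScores`.
#' @export
naive_score <- function(norm, cluster_labels = NULL,
                        rescale_clusters = FALSE) {
  sig <- gene_signature("naive", naive_marker_genes,
                        provenance = "fixed_naive")
  score_signature(norm, sig, cluster_labels, rescale_clusters)
}

#' Derive a signature from genes most correlated with an anchor
#'
#' Ranks every other gene by its Pearson correlation with the anchor gene
#' across the chosen cell subset, computed on log2(count+1) values, and
#' returns the top `k` (anchor excluded; ties broken lexicographically;
#' constant genes ineligible).
#'
#' @param norm a `NormalizedMatrix` at scale `log2p1`.
#' @param anchor anchor gene symbol (e.g. LAG3 for exhaustion, FOXP3 for
#'   Treg, FGFBP2 for cytotoxicity).
#' @param k number of genes to keep (default 50).
#' @param subset optional cell subset (barcodes, logical or integer index);
#'   needs at least 3 cells.
#' @return an anchor-derived `GeneSignature` carrying the correlations.
#' @export
derive_correlation_signature <- function(norm, anchor, k = 50, subset = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log2p1") {
    stop("derive_correlation_signature expects log2p1 values")
  }
  v <- norm$values
  if (!anchor %in% rownames(v)) stop("anchor gene missing: ", anchor)
  if (!is.null(subset)) {
    v <- v[, resolve_cells(subset, colnames(v)), drop = FALSE]
  }
  if (ncol(v) < 3) stop("subset too small (< 3 cells)")
  a <- as.numeric(v[anchor, ])
  if (stats::sd(a) == 0) {
    stop("undefined correlation: anchor '", anchor, "' constant on subset")
  }
  m <- as.matrix(v)
  mu <- rowMeans(m)
  centered <- m - mu
  ac <- a - mean(a)
  denom <- sqrt(rowSums(centered^2)) * sqrt(sum(ac^2))
  r <- as.numeric(centered %*% ac) / denom
  names(r) <- rownames(m)
  r <- r[names(r) != anchor]
  r <- r[is.finite(r)]  # constant genes drop out
  if (k >= length(r)) {
    stop(sprintf("k = %d but only %d eligible genes", k, length(r)))
  }
  ord <- order(-r, names(r))
  top <- r[ord][seq_len(k)]
  gene_signature(paste0(anchor, "_top", k), names(top),
                 provenance = "anchor_derived", anchor = anchor,
                 correlations = unname(top))
}

#' Proliferation score from G1/S and G2/M phase signatures
#'
#' Per-cell score is the maximum of the two phase scores (a cell in either
#' phase is cycling); cluster scores are means of member-cell scores.
#'
#' @inheritParams score_signature
#' @param g1s,g2m `GeneSignature` objects for the two cell-cycle phases.
#' @return a `SignatureScores` named `proliferation`.
#' @export
proliferation_score <- function(norm, g1s, g2m, cluster_labels = NULL,
                                rescale_clusters = FALSE) {
  if (norm$scale == "log2p1") norm <- zscore_by_gene(norm)
  s1 <- score_signature(norm, g1s)
  s2 <- score_signature(norm, g2m)
  cell_scores <- pmax(s1$cell_scores, s2$cell_scores)
  if (is.null(cluster_labels) && !is.null(norm$cell_meta) &&
      "cluster" %in% names(norm$cell_meta)) {
    cluster_labels <- norm$cell_meta$cluster
  }
  cluster_scores <- NULL
  normalization <- "raw_mean_z"
  if (!is.null(cluster_labels)) {
    cluster_scores <- tapply(cell_scores, cluster_labels, mean)
    cluster_scores <- cluster_scores[sort(names(cluster_scores))]
    if (rescale_clusters) {
      mu <- mean(cluster_scores)
      sd_pop <- sqrt(mean((cluster_scores - mu)^2))
      cluster_scores <- if (sd_pop > 1e-12) (cluster_scores - mu) / sd_pop
                        else cluster_scores * 0
      normalization <- "re_zscored_across_clusters"
    }
  }
  structure(list(signature = "proliferation", cell_scores = cell_scores,
                 cluster_scores = cluster_scores,
                 dropped_genes = union(s1$dropped_genes, s2$dropped_genes),
                 normalization = normalization),
            class = "SignatureScores")
}

#' Pearson correlation between two genes
#'
#' Pearson r on log2(count+1) values over a cell subset, with the two-sided
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param norm a `NormalizedMatrix` at scale `log2p1`.
#' @param gene_a,gene_b gene symbols.
#' @param subset optional cell subset; at least 3 cells.
#' @return list with `r`, `p_value`, `n`.
#' @export
pairwise_gene_correlation <- function(norm, gene_a, gene_b, subset = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log2p1") {
    stop("pairwise_gene_correlation expects log2p1 values")
  }
  v <- norm$values
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(v)) stop("gene missing: ", g)
  }
  if (!is.null(subset)) v <- v[, resolve_cells(subset, colnames(v)), drop = FALSE]
  if (ncol(v) < 3) stop("subset too small (< 3 cells)")
  x <- as.numeric(v[gene_a, ])
  y <- as.numeric(v[gene_b, ])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant gene: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Export signature scores as a tidy table
#'
#' @param scores a `SignatureScores`.
#' @param level `cell` or `cluster`.
#' @return data.frame with columns `unit`, `signature`, `score`.
#' @export
scores_table <- function(scores, level = c("cell", "cluster")) {
  level <- match.arg(level)
  s <- if (level == "cell") scores$cell_scores else scores$cluster_scores
  if (is.null(s)) stop("no ", level, "-level scores available")
  data.frame(unit = names(s), signature = scores$signature,
             score = as.numeric(s), stringsAsFactors = FALSE,
             row.names = NULL)
}
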