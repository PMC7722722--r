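#' Construct an expression matrix with per-cell annotations
#'
#' Bundles a sparse gene x cell UMI count matrix with its per-cell annotation
#' table. Counts must be non-negative integers; gene symbols and cell barcodes
#' must be unique.
#'
#' @param counts sparse or dense numeric matrix, genes in rows, cells in
#'   columns. Coerced to `Matrix::dgCMatrix`.
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   `rownames(counts)`).
#' @param cell_barcodes character vector of unique cell barcodes (defaults to
#'   `colnames(counts)`).
#' @param cell_meta optional data.frame of per-cell annotations, one row per
#'   cell in barcode order (see [attach_metadata()]).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `counts` (dgCMatrix with dimnames), and `cell_meta` (data.frame or NULL).
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_barcodes = colnames(counts),
                              cell_meta = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_barcodes)) {
    stop("gene_ids and cell_barcodes are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_barcodes <- as.character(cell_barcodes)
  if (length(gene_ids) != nrow(counts)) {
    stop(sprintf("dimension mismatch: %d gene ids for %d matrix rows",
                 length(gene_ids), nrow(counts)))
  }
  if (length(cell_barcodes) != ncol(counts)) {
    stop(sprintf("dimension mismatch: %d barcodes for %d matrix columns",
                 length(cell_barcodes), ncol(counts)))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cell_barcodes)) {
    stop("duplicate barcode: ",
         paste(unique(cell_barcodes[duplicated(cell_barcodes)]), collapse = ", "))
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_barcodes)
  if (!is.null(cell_meta)) {
    cell_meta <- validate_cell_meta(cell_meta, cell_barcodes)
  }
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s annotations)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$cell_meta)) "no" else "with"))
  if (!is.null(x$cell_meta)) {
    cat(sprintf("  patients: %d; tissues: %s\n",
                length(unique(x$cell_meta$patient_id)),
                paste(sort(unique(x$cell_meta$tissue)), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

valid_tissues <- c("tumor", "adjacent")

validate_cell_meta <- function(meta, barcodes) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("barcode", "patient_id", "tissue")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta$barcode <- as.character(meta$barcode)
  if (anyDuplicated(meta$barcode)) {
    stop("duplicate barcode in metadata")
  }
  absent <- setdiff(barcodes, meta$barcode)
  if (length(absent)) {
    stop("metadata missing barcode(s): ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" ... (%d total)", length(absent)) else "")
  }
  bad <- setdiff(unique(meta$tissue), valid_tissues)
  if (length(bad)) {
    stop("unknown tissue value(s): ", paste(bad, collapse = ", "),
         " (expected tumor/adjacent)")
  }
  extra <- !(meta$barcode %in% barcodes)
  if (any(extra)) meta <- meta[!extra, , drop = FALSE]
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Read a 10x-style MatrixMarket count triplet with sidecar tables
#'
#' @param matrix_path path to a MatrixMarket coordinate file with integer
#'   entries (genes as rows).
#' @param features_path path to a one-gene-per-line table; the first column is
#'   taken as the gene symbol.
#' @param barcodes_path path to a one-barcode-per-line file.
#' @return an [expression_matrix()] without annotations.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "",
                                comment.char = "")[[1]]
  expression_matrix(m, gene_ids = feats[[1]], cell_barcodes = barcodes)
}

#' Write an expression matrix as MatrixMarket triplet plus sidecars
#'
#' Inverse of [read_counts_mtx()]; annotations, if present, go to
#' `annotations.csv` in the same directory.
#'
#' @param mat an `ExpressionMatrix`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_counts_mtx <- function(mat, dir) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(mat$counts, paths[1])
  writeLines(rownames(mat$counts), paths[2])
  writeLines(colnames(mat$counts), paths[3])
  if (!is.null(mat$cell_meta)) {
    meta_path <- file.path(dir, "annotations.csv")
    utils::write.csv(mat$cell_meta, meta_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, meta_path)
  }
  invisible(paths)
}

#' Attach per-cell annotations to an expression matrix
#'
#' Every cell must be covered by the metadata; missing barcodes are an error,
#' never a silent drop. Metadata rows for barcodes absent from the matrix are
#' discarded.
#'
#' @param mat an `ExpressionMatrix`.
#' @param meta a data.frame (or CSV/TSV path, sniffed by extension) with
#'   columns `barcode`, `patient_id`, `tissue` (in `tumor`/`adjacent`) and
#'   optionally `cell_type`, `cluster` and flags.
#' @return the annotated `ExpressionMatrix`.
#' @export
attach_metadata <- function(mat, meta) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.character(meta) && length(meta) == 1) {
    sep <- if (grepl("\\.tsv$", meta, ignore.case = TRUE)) "\t" else ","
    meta <- utils::read.table(meta, sep = sep, header = TRUE,
                              stringsAsFactors = FALSE, quote = "\"")
  }
  mat$cell_meta <- validate_cell_meta(meta, colnames(mat$counts))
  mat
}

#' Filter low-quality cells
#'
#' Removes cells with fewer than `min_genes` detected genes or a mitochondrial
#' UMI fraction above `max_mito_frac` (strict inequalities: a cell with
#' exactly `min_genes` genes or mito fraction exactly `max_mito_frac` is
#' kept). Mitochondrial genes are recognized by id prefix. A cell failing both
#' rules is tallied under the low-gene count only, so the report is additive.
#'
#' @param mat an `ExpressionMatrix`.
#' @param min_genes minimum detected genes per cell (default 400).
#' @param max_mito_frac maximum mitochondrial count fraction (default 0.10).
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return list with elements `matrix` (filtered `ExpressionMatrix`) and
#'   `report` (a `QcReport`: cells in/kept, per-rule removal tallies,
#'   thresholds).
#' @export
qc_filter <- function(mat, min_genes = 400, max_mito_frac = 0.10,
                      mito_prefix = "MT-") {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  counts <- mat$counts
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_rows <- startsWith(rownames(counts), mito_prefix)
  mito_counts <- if (any(mito_rows)) {
    Matrix::colSums(counts[mito_rows, , drop = FALSE])
  } else {
    numeric(ncol(counts))
  }
  mito_frac <- ifelse(total > 0, mito_counts / total, 0)

  low_genes <- detected < min_genes
  high_mito <- mito_frac > max_mito_frac
  keep <- !low_genes & !high_mito
  if (!any(keep)) stop("empty matrix after QC")

  report <- structure(list(
    n_cells_in = ncol(counts),
    n_cells_kept = sum(keep),
    n_removed_low_genes = sum(low_genes),
    n_removed_high_mito = sum(high_mito & !low_genes),
    min_genes = min_genes,
    max_mito_frac = max_mito_frac,
    mito_prefix = mito_prefix
  ), class = "QcReport")

  out <- mat
  out$counts <- counts[, keep, drop = FALSE]
  if (!is.null(mat$cell_meta)) {
    out$cell_meta <- mat$cell_meta[keep, , drop = FALSE]
    rownames(out$cell_meta) <- NULL
  }
  list(matrix = out, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf(
    "QC: %d cells in, %d kept (%d removed: %d with < %d genes, %d with mito > %g)\n",
    x$n_cells_in, x$n_cells_kept, x$n_cells_in - x$n_cells_kept,
    x$n_removed_low_genes, x$min_genes, x$n_removed_high_mito,
    x$max_mito_frac))
  invisible(x)
}

#' log2(count + 1) normalization
#'
#' @param mat an `ExpressionMatrix`.
#' @return a `NormalizedMatrix` at scale `log2p1` (sparse; zeros preserved),
#'   carrying the cell annotations forward.
#' @export
normalize_log2 <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  values <- mat$counts
  values@x <- log2(values@x + 1)
  structure(list(values = values, scale = "log2p1",
                 cell_meta = mat$cell_meta),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix [%s]: %d genes x %d cells\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-gene z-scoring of log2(count + 1) values
#'
#' Centers and scales each gene over the chosen cell subset using the
#' population standard deviation (divide by n). Genes constant over the
#' subset become all-zero rows.
#'
#' @param norm a `NormalizedMatrix` at scale `log2p1`.
#' @param within optional cell subset: barcodes or logical/integer index.
#'   Statistics are computed over, and the result restricted to, this subset.
#' @return a dense `NormalizedMatrix` at scale `zscore_log2p1`.
#' @export
zscore_by_gene <- function(norm, within = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (norm$scale != "log2p1") {
    stop("zscore_by_gene expects a log2p1-scale matrix")
  }
  v <- norm$values
  meta <- norm$cell_meta
  if (!is.null(within)) {
    idx <- resolve_cells(within, colnames(v))
    if (length(idx) == 0) stop("empty cell subset")
    v <- v[, idx, drop = FALSE]
    if (!is.null(meta)) meta <- meta[idx, , drop = FALSE]
  }
  n <- ncol(v)
  mu <- Matrix::rowMeans(v)
  # population variance via E[x^2] - mu^2 on the sparse matrix
  ex2 <- Matrix::rowMeans(v^2)
  sd_pop <- sqrt(pmax(ex2 - mu^2, 0))
  z <- as.matrix(v) - mu
  nonconst <- sd_pop > 1e-12
  z[nonconst, ] <- z[nonconst, , drop = FALSE] / sd_pop[nonconst]
  z[!nonconst, ] <- 0
  if (!is.null(meta)) rownames(meta) <- NULL
  structure(list(values = z, scale = "zscore_log2p1", cell_meta = meta),
            class = "NormalizedMatrix")
}

resolve_cells <- function(within, barcodes) {
  if (is.logical(within)) {
    stopifnot(length(within) == length(barcodes))
    which(within)
  } else if (is.numeric(within)) {
    as.integer(within)
  } else {
    idx <- match(as.character(within), barcodes)
    if (anyNA(idx)) {
      stop("unknown barcode(s) in subset: ",
           paste(utils::head(within[is.na(idx)], 5), collapse = ", "))
    }
    idx
  }
}
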