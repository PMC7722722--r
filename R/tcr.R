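as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Parse a filtered-contig annotation table
#'
#' Reads a contig CSV in the Cell Ranger VDJ filtered-contig dialect and
#' keeps productive, full-length TRA/TRB rows; everything else is dropped
#' with tallies.
#'
#' @param contigs a data.frame or CSV path with columns `barcode`, `chain`,
#'   `cdr3_nt`, `productive`, `full_length`, `umis` (plus optional `cdr3`,
#'   `v_gene`, `j_gene`, `patient_id`). Boolean columns accept
#'   "True"/"False" in any case.
#' @return data.frame of retained contigs, with a `dropped` attribute
#'   tallying removals by reason.
#' @export
parse_contigs <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1) {
    contigs <- utils::read.csv(contigs, stringsAsFactors = FALSE)
  }
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  required <- c("barcode", "chain", "cdr3_nt", "productive", "full_length",
                "umis")
  missing_cols <- setdiff(required, names(contigs))
  if (length(missing_cols)) {
    stop("contig table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  productive <- as_flag(contigs$productive)
  full_length <- as_flag(contigs$full_length)
  tr_chain <- contigs$chain %in% c("TRA", "TRB")
  keep <- productive & full_length & tr_chain
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(
    non_tr_chain = sum(!tr_chain),
    unproductive = sum(tr_chain & !productive),
    not_full_length = sum(tr_chain & productive & !full_length)
  )
  out
}

#' Assign paired alpha/beta clonotypes
#'
#' Per cell and chain, the dominant contig is the one with the highest UMI
#' count (ties broken by lexicographically smallest CDR3 nucleotide
#' sequence). Cells carrying both a dominant TRA and a dominant TRB receive
#' the clonotype key (alpha CDR3 nt, beta CDR3 nt), scoped within patient:
#' two cells share a clonotype only when both their alpha and beta sequences
#' match. Cells missing either chain stay unassigned.
#'
#' @param contigs parsed contigs (see [parse_contigs()]).
#' @param cell_universe barcodes of the annotated T cells.
#' @param patient_map optional named vector barcode -> patient id; defaults
#'   to the contigs' `patient_id` column, else a single-patient cohort.
#' @param outside_universe `warn` (drop with a warning) or `error` for
#'   contig barcodes outside the universe.
#' @return a `ClonotypeTable`: `cells` (one row per universe cell: dominant
#'   alpha/beta, clonotype id or NA), `clonotypes` (id, patient, alpha,
#'   beta, size), and a `diagnostics` table of non-dominant extra chains.
#' @export
assign_clonotypes <- function(contigs, cell_universe,
                              patient_map = NULL,
                              outside_universe = c("warn", "error")) {
  outside_universe <- match.arg(outside_universe)
  cell_universe <- as.character(cell_universe)
  stopifnot(!anyDuplicated(cell_universe))

  outside <- !(contigs$barcode %in% cell_universe)
  if (any(outside)) {
    msg <- sprintf("%d contig(s) with barcodes outside the cell universe",
                   sum(outside))
    if (outside_universe == "error") stop(msg)
    warning(msg, "; dropped")
    contigs <- contigs[!outside, , drop = FALSE]
  }

  if (is.null(patient_map)) {
    if ("patient_id" %in% names(contigs)) {
      patient_map <- tapply(contigs$patient_id, contigs$barcode,
                            function(p) p[1])
    } else {
      patient_map <- stats::setNames(rep("cohort", length(cell_universe)),
                                     cell_universe)
    }
  }

  # dominant contig per (barcode, chain): max umis, tie -> smallest cdr3_nt
  dominant_of <- function(df) {
    if (nrow(df) == 0) {
      return(data.frame(barcode = character(), cdr3_nt = character(),
                        stringsAsFactors = FALSE))
    }
    ord <- order(df$barcode, -df$umis, df$cdr3_nt)
    df <- df[ord, , drop = FALSE]
    first <- !duplicated(df$barcode)
    dom <- df[first, c("barcode", "cdr3_nt"), drop = FALSE]
    rownames(dom) <- NULL
    attr(dom, "extras") <- df[!first, , drop = FALSE]
    dom
  }
  dom_a <- dominant_of(contigs[contigs$chain == "TRA", , drop = FALSE])
  dom_b <- dominant_of(contigs[contigs$chain == "TRB", , drop = FALSE])

  cells <- data.frame(barcode = cell_universe, stringsAsFactors = FALSE)
  cells$patient_id <- unname(patient_map[cells$barcode])
  cells$alpha <- dom_a$cdr3_nt[match(cells$barcode, dom_a$barcode)]
  cells$beta <- dom_b$cdr3_nt[match(cells$barcode, dom_b$barcode)]
  paired <- !is.na(cells$alpha) & !is.na(cells$beta)
  key <- ifelse(paired,
                paste(cells$patient_id, cells$alpha, cells$beta, sep = "|"),
                NA_character_)
  cells$clonotype_id <- key

  assigned <- cells[paired, , drop = FALSE]
  if (nrow(assigned)) {
    sizes <- table(assigned$clonotype_id)
    first <- assigned[!duplicated(assigned$clonotype_id), , drop = FALSE]
    clonotypes <- data.frame(
      clonotype_id = first$clonotype_id, patient_id = first$patient_id,
      alpha = first$alpha, beta = first$beta,
      size = as.integer(sizes[first$clonotype_id]),
      stringsAsFactors = FALSE, row.names = NULL)
    clonotypes <- clonotypes[order(-clonotypes$size,
                                   clonotypes$clonotype_id), , drop = FALSE]
    rownames(clonotypes) <- NULL
  } else {
    clonotypes <- data.frame(clonotype_id = character(),
                             patient_id = character(), alpha = character(),
                             beta = character(), size = integer(),
                             stringsAsFactors = FALSE)
  }

  diagnostics <- rbind(attr(dom_a, "extras"), attr(dom_b, "extras"))
  structure(list(cells = cells, clonotypes = clonotypes,
                 diagnostics = diagnostics),
            class = "ClonotypeTable")
}

#' @export
print.ClonotypeTable <- function(x, ...) {
  cat(sprintf(
    "ClonotypeTable: %d cells, %d assigned, %d clonotypes (%d patients)\n",
    nrow(x$cells), sum(!is.na(x$cells$clonotype_id)), nrow(x$clonotypes),
    length(unique(x$clonotypes$patient_id))))
  invisible(x)
}

#' Chain recovery over a cell universe
#'
#' Fractions of universe cells carrying at least one productive dominant
#' TRA, TRB, and both, as percentages rounded to two decimals.
#'
#' @inheritParams assign_clonotypes
#' @return list with `frac_alpha`, `frac_beta`, `frac_paired` (unrounded
#'   fractions) and `pct_alpha`, `pct_beta`, `pct_paired` (2-decimal
#'   percentages), plus `n_cells`.
#' @export
chain_recovery_stats <- function(contigs, cell_universe) {
  cell_universe <- as.character(cell_universe)
  if (length(cell_universe) == 0) stop("empty cell universe")
  has_a <- cell_universe %in% contigs$barcode[contigs$chain == "TRA"]
  has_b <- cell_universe %in% contigs$barcode[contigs$chain == "TRB"]
  n <- length(cell_universe)
  f <- c(alpha = mean(has_a), beta = mean(has_b), paired = mean(has_a & has_b))
  list(frac_alpha = f[["alpha"]], frac_beta = f[["beta"]],
       frac_paired = f[["paired"]],
       pct_alpha = round(100 * f[["alpha"]], 2),
       pct_beta = round(100 * f[["beta"]], 2),
       pct_paired = round(100 * f[["paired"]], 2),
       n_cells = n)
}

#' Clonal expansion profile per group
#'
#' For each group of clonotype-assigned cells: the fraction of cells in
#' clonotype-size bins n = 1, n = 2 and n >= 3, and the clonal fraction
#' (cells whose clonotype is carried by at least two cells).
#'
#' @param table a `ClonotypeTable`.
#' @param group_labels named vector barcode -> group covering the assigned
#'   cells (e.g. sample, cluster, tissue).
#' @return data.frame with one row per group: `n_cells`, `bin_1`, `bin_2`,
#'   `bin_3plus`, `clonal_fraction`.
#' @export
clonal_expansion_profile <- function(table, group_labels) {
  stopifnot(inherits(table, "ClonotypeTable"))
  cells <- table$cells[!is.na(table$cells$clonotype_id), , drop = FALSE]
  if (nrow(cells) == 0) stop("no clonotype-assigned cells")
  missing <- setdiff(cells$barcode, names(group_labels))
  if (length(missing)) {
    stop("group labels missing for ", length(missing), " assigned cell(s)")
  }
  size_of <- stats::setNames(table$clonotypes$size,
                             table$clonotypes$clonotype_id)
  cells$size <- size_of[cells$clonotype_id]
  cells$group <- unname(group_labels[cells$barcode])
  res <- lapply(split(cells, cells$group), function(g) {
    n <- nrow(g)
    data.frame(group = g$group[1], n_cells = n,
               bin_1 = sum(g$size == 1) / n,
               bin_2 = sum(g$size == 2) / n,
               bin_3plus = sum(g$size >= 3) / n,
               clonal_fraction = sum(g$size >= 2) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Shared-clonotype counts and percentages between clusters
#'
#' A clonotype is present in a cluster when at least one member cell carries
#' that cluster label. `counts[i, j]` is the number of clonotypes present in
#' both clusters (symmetric; the diagonal is the cluster's clonotype count).
#' `percentages[i, j]` divides by the focal (row) cluster's clonotype count,
#' so the matrix is deliberately asymmetric.
#'
#' @param table a `ClonotypeTable`.
#' @param cluster_labels named vector barcode -> cluster covering the
#'   assigned cells.
#' @return a `SharingMatrix`: list with `clusters`, `counts`, `percentages`.
#' @export
shared_clonotype_matrix <- function(table, cluster_labels) {
  stopifnot(inherits(table, "ClonotypeTable"))
  cells <- table$cells[!is.na(table$cells$clonotype_id), , drop = FALSE]
  missing <- setdiff(cells$barcode, names(cluster_labels))
  if (length(missing)) {
    stop("cluster labels missing for ", length(missing), " assigned cell(s)")
  }
  cells$cluster <- unname(cluster_labels[cells$barcode])
  clusters <- sort(unique(cells$cluster))
  presence <- lapply(clusters, function(cl) {
    unique(cells$clonotype_id[cells$cluster == cl])
  })
  names(presence) <- clusters
  k <- length(clusters)
  counts <- matrix(0L, k, k, dimnames = list(clusters, clusters))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      counts[i, j] <- length(intersect(presence[[i]], presence[[j]]))
    }
  }
  denom <- vapply(presence, length, integer(1))
  percentages <- 100 * counts / denom  # row-wise focal denominator
  structure(list(clusters = clusters, counts = counts,
                 percentages = percentages,
                 n_clonotypes = denom),
            class = "SharingMatrix")
}

#' @export
print.SharingMatrix <- function(x, ...) {
  cat(sprintf("SharingMatrix over %d clusters\n", length(x$clusters)))
  print(x$counts)
  invisible(x)
}

#' Clone-size spectrum
#'
#' Histogram of clonotype sizes: for each observed size, the number of
#' clonotypes of that size. The sum of size x count equals the number of
#' clonotype-assigned cells.
#'
#' @param table a `ClonotypeTable`.
#' @return data.frame with columns `size`, `n_clonotypes`.
#' @export
clone_size_spectrum <- function(table) {
  stopifnot(inherits(table, "ClonotypeTable"))
  if (nrow(table$clonotypes) == 0) stop("empty clonotype table")
  tab <- table(table$clonotypes$size)
  data.frame(size = as.integer(names(tab)),
             n_clonotypes = as.integer(tab),
             row.names = NULL)
}
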