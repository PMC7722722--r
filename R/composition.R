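#' Per-sample cell-type or cluster fraction table
#'
#' Computes, for every (patient, tissue) sample, the fraction of cells in
#' each unit (cell type or cluster) relative to the chosen denominator:
#' * `all_cells` — all cells of the sample;
#' * `cd45_cells` — cells flagged TRUE in the `is_cd45` annotation column;
#' * `parent_lineage` — cells of the unit's parent lineage (the `parent_col`
#'   annotation, by default `cell_type`), e.g. a cluster's share of its
#'   compartment.
#'
#' Within each sample and denominator the fractions over units sum to 1
#' whenever the units partition the denominator.
#'
#' @param annotations per-cell annotation data.frame with `patient_id`,
#'   `tissue` and the unit column (an `ExpressionMatrix` is also accepted).
#' @param unit_column annotation column defining the units (default
#'   `cell_type`).
#' @param denominator one of `all_cells`, `cd45_cells`, `parent_lineage`.
#' @param parent_col parent-lineage column for `parent_lineage`.
#' @return a `FractionTable` data.frame: `patient_id`, `tissue`, `unit`,
#'   `n_cells`, `denominator_n`, `fraction`, `denominator`.
#' @export
fraction_table <- function(annotations, unit_column = "cell_type",
                           denominator = c("all_cells", "cd45_cells",
                                           "parent_lineage"),
                           parent_col = "cell_type") {
  if (inherits(annotations, "ExpressionMatrix")) {
    annotations <- annotations$cell_meta
  }
  if (!is.character(denominator) ||
      !denominator[1] %in% c("all_cells", "cd45_cells", "parent_lineage")) {
    stop("unknown denominator tag: ", denominator[1])
  }
  denominator <- denominator[1]
  stopifnot(is.data.frame(annotations),
            all(c("patient_id", "tissue", unit_column) %in% names(annotations)))
  ann <- annotations
  if (denominator == "cd45_cells") {
    if (!"is_cd45" %in% names(ann)) {
      stop("cd45_cells denominator needs an 'is_cd45' annotation column")
    }
    ann <- ann[as_flag(ann$is_cd45), , drop = FALSE]
  }
  sample_key <- paste(ann$patient_id, ann$tissue, sep = "\r")
  unit <- as.character(ann[[unit_column]])

  if (denominator == "parent_lineage") {
    if (!parent_col %in% names(ann)) stop("missing parent column: ", parent_col)
    denom_key <- paste(sample_key, ann[[parent_col]], sep = "\r")
  } else {
    denom_key <- sample_key
  }
  cnt <- table(paste(sample_key, unit, sep = "\r"))
  denom_cnt <- table(denom_key)
  # map each (sample, unit) back to its denominator count
  first_idx <- match(names(cnt), paste(sample_key, unit, sep = "\r"))
  denom_of <- as.integer(denom_cnt[denom_key[first_idx]])
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  out <- data.frame(patient_id = parts[, 1], tissue = parts[, 2],
                    unit = parts[, 3], n_cells = as.integer(cnt),
                    denominator_n = denom_of,
                    fraction = as.integer(cnt) / denom_of,
                    denominator = denominator,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$patient_id, out$tissue, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FractionTable", "data.frame")
  out
}

#' Paired tumor-versus-adjacent test on a unit's fractions
#'
#' Two-tailed paired test on per-patient (tumor minus adjacent) fractions of
#' one unit: Student's t-test by default, Wilcoxon signed-rank selectable.
#' Patients lacking either tissue are dropped with a warning; units absent
#' from a sample contribute fraction 0 for that sample.
#'
#' @param ft a `FractionTable`.
#' @param unit the unit (cell type or cluster) to test.
#' @param method `t` (paired Student's t-test) or `wilcoxon` (paired
#'   signed-rank).
#' @return list with `statistic`, `p_value`, `direction`
#'   (`tumor-enriched` / `adjacent-enriched` / `none`), `mean_diff`,
#'   `n_pairs`.
#' @export
paired_tissue_test <- function(ft, unit, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(inherits(ft, "FractionTable") || is.data.frame(ft))
  sub <- ft[ft$unit == unit, , drop = FALSE]
  if (nrow(sub) == 0) stop("unit not present in table: ", unit)
  patients <- sort(unique(ft$patient_id))
  get_frac <- function(p, tis) {
    # unit absent from an existing sample counts as fraction 0; a sample
    # absent from the table altogether is a missing pair member
    if (!any(ft$patient_id == p & ft$tissue == tis)) return(NA_real_)
    i <- sub$patient_id == p & sub$tissue == tis
    if (any(i)) sub$fraction[i][1] else 0
  }
  tum <- vapply(patients, get_frac, numeric(1), tis = "tumor")
  adj <- vapply(patients, get_frac, numeric(1), tis = "adjacent")
  paired <- !is.na(tum) & !is.na(adj)
  if (any(!paired)) {
    warning(sum(!paired), " unpaired patient(s) dropped")
  }
  if (sum(paired) < 2) stop("insufficient pairs (< 2 patients with both tissues)")
  tum <- tum[paired]; adj <- adj[paired]
  diffs <- tum - adj
  if (method == "t") {
    if (stats::sd(diffs) == 0) {
      res <- list(statistic = 0, p.value = if (all(diffs == 0)) 1 else 0)
      if (!all(diffs == 0)) res <- list(statistic = Inf * sign(diffs[1]),
                                        p.value = 0)
    } else {
      tt <- stats::t.test(tum, adj, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
    }
  } else {
    wt <- suppressWarnings(stats::wilcox.test(tum, adj, paired = TRUE))
    res <- list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  md <- mean(diffs)
  direction <- if (md > 0) "tumor-enriched" else if (md < 0)
    "adjacent-enriched" else "none"
  list(statistic = res$statistic, p_value = res$p.value,
       direction = direction, mean_diff = md, n_pairs = sum(paired))
}
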