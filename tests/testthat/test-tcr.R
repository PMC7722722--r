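make_contig <- function(barcode, chain, cdr3_nt, umis = 1,
                        productive = "True", full_length = "True") {
  data.frame(barcode = barcode, chain = chain, cdr3_nt = cdr3_nt,
             productive = productive, full_length = full_length,
             umis = umis, stringsAsFactors = FALSE)
}

test_that("parse_contigs keeps productive full-length TRA/TRB rows only", {
  rows <- rbind(
    make_contig("c1", "TRA", "AAA"),
    make_contig("c1", "TRB", "CCC"),
    make_contig("c2", "IGH", "GGG"),
    make_contig("c2", "TRA", "TTT", productive = "False"),
    make_contig("c3", "TRB", "ACG", full_length = "false"),
    make_contig("c3", "TRB", "ACT"),
    make_contig("c4", "TRA", "CGT"),
    make_contig("c4", "TRB", "CGA"),
    make_contig("c5", "TRB", "AAC"),
    make_contig("c5", "TRA", "AAG")
  )
  parsed <- parse_contigs(rows)
  expect_equal(nrow(parsed), 7)
  dropped <- attr(parsed, "dropped")
  expect_equal(unname(dropped["non_tr_chain"]), 1)
  expect_equal(unname(dropped["unproductive"]), 1)
  expect_equal(unname(dropped["not_full_length"]), 1)
  expect_error(parse_contigs(rows[, -3]), "missing required column")
})

test_that("clonotype assignment follows the paired dominant-chain rules", {
  # hand-built 6-cell table: cell1 has two TRAs (umis 7 vs 2); cells 2 and 3
  # share an alpha-beta pair; cell4 is alpha-only; cells 5 and 6 have
  # distinct pairs
  contigs <- rbind(
    make_contig("cell1", "TRA", "AAAA", umis = 7),
    make_contig("cell1", "TRA", "GGGG", umis = 2),
    make_contig("cell1", "TRB", "BBB1", umis = 3),
    make_contig("cell2", "TRA", "CCCC", umis = 1),
    make_contig("cell2", "TRB", "BBB2", umis = 1),
    make_contig("cell3", "TRA", "CCCC", umis = 4),
    make_contig("cell3", "TRB", "BBB2", umis = 2),
    make_contig("cell4", "TRA", "DDDD", umis = 5),
    make_contig("cell5", "TRA", "EEEE", umis = 1),
    make_contig("cell5", "TRB", "BBB3", umis = 1),
    make_contig("cell6", "TRA", "FFFF", umis = 1),
    make_contig("cell6", "TRB", "BBB4", umis = 1)
  )
  universe <- paste0("cell", 1:6)
  tab <- assign_clonotypes(contigs, universe)
  expect_equal(sum(is.na(tab$cells$clonotype_id)), 1)
  expect_true(is.na(tab$cells$clonotype_id[tab$cells$barcode == "cell4"]))
  expect_equal(tab$cells$alpha[tab$cells$barcode == "cell1"], "AAAA")
  expect_equal(nrow(tab$clonotypes), 4)
  expect_equal(sort(tab$clonotypes$size), c(1, 1, 1, 2))
  shared <- tab$cells$clonotype_id[tab$cells$barcode %in% c("cell2", "cell3")]
  expect_equal(shared[1], shared[2])
  # the non-dominant TRA lands in diagnostics
  expect_equal(tab$diagnostics$cdr3_nt, "GGGG")

  # dominant-chain UMI tie broken by lexicographically smallest cdr3_nt
  tie <- rbind(make_contig("c1", "TRA", "ZZZZ", umis = 3),
               make_contig("c1", "TRA", "MMMM", umis = 3),
               make_contig("c1", "TRB", "BBBB", umis = 1))
  expect_equal(assign_clonotypes(tie, "c1")$cells$alpha, "MMMM")

  # a beta-only cell gets no clonotype
  solo <- make_contig("c9", "TRB", "QQQQ")
  expect_true(is.na(assign_clonotypes(solo, "c9")$cells$clonotype_id))
})

test_that("assignment matches the brute-force group-by reference", {
  for (seed in 1:25) {
    fx <- random_contig_table(n_cells = sample(20:120, 1), seed = seed)
    tab <- assign_clonotypes(fx$contigs, fx$universe)
    ref <- brute_assign(fx$contigs, fx$universe, fx$patient_of)
    expect_equal(tab$cells$alpha, ref$alpha)
    expect_equal(tab$cells$beta, ref$beta)
    expect_equal(tab$cells$clonotype_id, ref$key)
    ref_sizes <- sort(as.integer(table(ref$key[!is.na(ref$key)])))
    expect_equal(sort(tab$clonotypes$size), ref_sizes)
  }
})

test_that("clonotypes never span patients", {
  ds <- simulate_cohort(small_config(seed = 4))
  tab <- assign_clonotypes(parse_contigs(ds$contigs),
                           ds$truth$clonotypes$barcode)
  per_clone <- tapply(tab$clonotypes$patient_id, tab$clonotypes$clonotype_id,
                      function(p) length(unique(p)))
  expect_true(all(per_clone == 1))
  # and the simulator's planted truth is patient-disjoint on CDR3 strings
  alpha_patients <- tapply(ds$contigs$patient_id, ds$contigs$cdr3_nt,
                           function(p) length(unique(p)))
  expect_true(all(alpha_patients == 1))
})

test_that("chain recovery reproduces the printed cohort arithmetic", {
  # 38,134 T cells: 26,920 with a productive alpha, 31,440 with beta,
  # 26,672 with both
  n <- 38134L
  n_alpha <- 26920L
  n_beta <- 31440L
  n_both <- 26672L
  universe <- sprintf("b%05d", seq_len(n))
  with_both <- universe[seq_len(n_both)]
  alpha_only <- universe[n_both + seq_len(n_alpha - n_both)]
  beta_only <- universe[n_alpha + seq_len(n_beta - n_both)]
  contigs <- rbind(
    make_contig(c(with_both, alpha_only), "TRA", "AAAA"),
    make_contig(c(with_both, beta_only), "TRB", "CCCC")
  )
  stats <- chain_recovery_stats(contigs, universe)
  expect_equal(stats$pct_alpha, 70.59)
  expect_equal(stats$pct_beta, 82.45)
  expect_equal(stats$pct_paired, 69.94)

  expect_error(chain_recovery_stats(contigs, character(0)),
               "empty cell universe")
})

test_that("dropout-free synthetic cohorts recover every chain", {
  cfg <- small_config(seed = 6, p_alpha_missing = 0, p_beta_missing = 0)
  ds <- simulate_cohort(cfg)
  stats <- chain_recovery_stats(parse_contigs(ds$contigs),
                                ds$truth$clonotypes$barcode)
  expect_equal(stats$pct_alpha, 100)
  expect_equal(stats$pct_beta, 100)
  expect_equal(stats$pct_paired, 100)
})

test_that("expansion bins and clonal fraction follow the size definition", {
  contigs <- rbind(
    make_contig(sprintf("c%d", 1:4), "TRA", "AAAA"),
    make_contig(sprintf("c%d", 1:4), "TRB", "BBBB"),
    make_contig(sprintf("c%d", 5:10), "TRA", sprintf("A%d", 5:10)),
    make_contig(sprintf("c%d", 5:10), "TRB", sprintf("B%d", 5:10))
  )
  universe <- sprintf("c%d", 1:10)
  tab <- assign_clonotypes(contigs, universe)
  prof <- clonal_expansion_profile(
    tab, setNames(rep("all", 10), universe))
  # one clonotype of size 4 among 10 cells -> clonal fraction 0.4
  expect_equal(prof$clonal_fraction, 0.4)
  expect_equal(prof$bin_1, 0.6)
  expect_equal(prof$bin_2, 0)
  expect_equal(prof$bin_3plus, 0.4)

  singles <- assign_clonotypes(
    rbind(make_contig(sprintf("s%d", 1:5), "TRA", sprintf("A%d", 1:5)),
          make_contig(sprintf("s%d", 1:5), "TRB", sprintf("B%d", 1:5))),
    sprintf("s%d", 1:5))
  p2 <- clonal_expansion_profile(
    singles, setNames(rep("g", 5), sprintf("s%d", 1:5)))
  expect_equal(unlist(p2[, c("bin_1", "bin_2", "bin_3plus")]),
               c(bin_1 = 1, bin_2 = 0, bin_3plus = 0))
  expect_equal(p2$clonal_fraction, 0)
})

test_that("expansion bins on a synthetic cohort match the planted truth", {
  cfg <- small_config(seed = 8, p_alpha_missing = 0, p_beta_missing = 0)
  ds <- simulate_cohort(cfg)
  truth <- ds$truth$clonotypes
  tab <- assign_clonotypes(parse_contigs(ds$contigs), truth$barcode)
  labels <- setNames(truth$patient_id, truth$barcode)
  prof <- clonal_expansion_profile(tab, labels)
  for (p in unique(truth$patient_id)) {
    tp <- truth[truth$patient_id == p, ]
    expect_equal(prof$clonal_fraction[prof$group == p],
                 mean(tp$clone_size >= 2))
    expect_equal(prof$bin_1[prof$group == p], mean(tp$clone_size == 1))
  }
})

test_that("sharing matrix counts intersections with focal-row percentages", {
  # presence sets A:{1,2,3}, B:{2,3}, C:{3,4} via one cell per
  # (clonotype, cluster) membership
  cells <- c(A1 = 1, A2 = 2, A3 = 3, B2 = 2, B3 = 3, C3 = 3, C4 = 4)
  contigs <- rbind(
    make_contig(names(cells), "TRA", sprintf("A%d", cells)),
    make_contig(names(cells), "TRB", sprintf("B%d", cells))
  )
  tab <- assign_clonotypes(contigs, names(cells))
  labels <- setNames(substr(names(cells), 1, 1), names(cells))
  sh <- shared_clonotype_matrix(tab, labels)
  expect_equal(sh$counts["A", "B"], 2)
  expect_equal(sh$counts["B", "A"], 2)
  expect_equal(sh$counts["A", "C"], 1)
  expect_equal(unname(diag(sh$counts)), c(3, 2, 2))
  expect_equal(sh$percentages["A", "B"], 100 * 2 / 3)
  expect_equal(sh$percentages["B", "A"], 100)
  expect_true(all(diag(sh$percentages) == 100))
  expect_true(isSymmetric(sh$counts))

  # disjoint clusters share nothing
  lab2 <- setNames(c("X", "X", "X", "Y", "Y", "Y", "Y"), names(cells))
  contigs2 <- rbind(
    make_contig(names(cells), "TRA", sprintf("A%s", names(cells))),
    make_contig(names(cells), "TRB", sprintf("B%s", names(cells)))
  )
  sh2 <- shared_clonotype_matrix(assign_clonotypes(contigs2, names(cells)),
                                 lab2)
  expect_equal(sh2$counts["X", "Y"], 0)
})

test_that("clone-size spectrum conserves the assigned-cell count", {
  # explicit sizes (1,1,2,4)
  sizes <- c(1, 1, 2, 4)
  bc <- sprintf("z%02d", seq_len(sum(sizes)))
  clone <- rep(seq_along(sizes), sizes)
  contigs <- rbind(make_contig(bc, "TRA", sprintf("A%d", clone)),
                   make_contig(bc, "TRB", sprintf("B%d", clone)))
  tab <- assign_clonotypes(contigs, bc)
  spec <- clone_size_spectrum(tab)
  expect_equal(spec, data.frame(size = c(1L, 2L, 4L),
                                n_clonotypes = c(2L, 1L, 1L)))
  expect_equal(sum(spec$size * spec$n_clonotypes),
               sum(!is.na(tab$cells$clonotype_id)))

  # synthetic cohort spectrum equals the planted truth
  cfg <- small_config(seed = 9, p_alpha_missing = 0, p_beta_missing = 0)
  ds <- simulate_cohort(cfg)
  truth <- ds$truth$clonotypes
  tab2 <- assign_clonotypes(parse_contigs(ds$contigs), truth$barcode)
  spec2 <- clone_size_spectrum(tab2)
  truth_sizes <- table(truth$clone_size[!duplicated(truth$clonotype_id)])
  expect_equal(spec2$n_clonotypes,
               as.integer(truth_sizes[as.character(spec2$size)]))
  expect_equal(sum(spec2$size * spec2$n_clonotypes), nrow(truth))
})

test_that("contigs outside the universe warn and drop, or error on request", {
  contigs <- rbind(make_contig(c("in1", "out1"), "TRA", c("AAAA", "CCCC")),
                   make_contig("in1", "TRB", "GGGG"))
  expect_warning(tab <- assign_clonotypes(contigs, "in1"),
                 "outside the cell universe")
  expect_equal(nrow(tab$cells), 1)
  expect_error(assign_clonotypes(contigs, "in1", outside_universe = "error"),
               "outside the cell universe")
})
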