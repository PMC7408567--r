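toy_cells <- function(counts, regions = NULL, patients = NULL) {
  n <- ncol(counts)
  meta <- data.frame(
    cell_id = colnames(counts),
    patient_id = if (is.null(patients)) rep("P1", n) else patients,
    region = if (is.null(regions)) rep("core", n) else regions,
    stringsAsFactors = FALSE)
  cell_matrix(counts, meta)
}

test_that("QC filter enforces each threshold and reports failed rules", {
  # 10 hand-built cells on a 6-gene panel (1 mitochondrial)
  genes <- c("MT-ND1", paste0("G", 1:5))
  thr <- qc_thresholds(min_counts = 10, min_genes = 3, max_genes = 5,
                       max_mito_fraction = 0.10)
  mk <- function(...) c(...)
  cols <- cbind(
    ok1   = mk(0, 5, 5, 5, 0, 0),    # 15 counts, 3 genes
    low   = mk(0, 2, 2, 2, 0, 0),    # 6 counts < 10
    few   = mk(0, 12, 0, 0, 0, 0),   # 12 counts but 1 gene
    many  = mk(1, 3, 3, 3, 3, 3),    # 6 genes > 5
    mito  = mk(3, 5, 5, 5, 0, 0),    # 3/18 mito > 10%
    ok2   = mk(1, 5, 5, 0, 0, 0),    # 1/11 mito ~9%
    ok3   = mk(0, 4, 4, 4, 0, 0),
    low2  = mk(0, 3, 3, 3, 0, 0),    # 9 counts
    ok4   = mk(0, 10, 10, 10, 0, 0),
    ok5   = mk(1, 9, 9, 0, 0, 0))
  rownames(cols) <- genes
  cells <- toy_cells(cols)
  res <- qc_filter(cells, thr)
  expect_setequal(res$cells$cell_meta$cell_id,
                  c("ok1", "ok2", "ok3", "ok4", "ok5"))
  expect_match(res$report$failed_rules[res$report$cell_id == "low"],
               "low_counts")
  expect_match(res$report$failed_rules[res$report$cell_id == "few"],
               "few_genes")
  expect_match(res$report$failed_rules[res$report$cell_id == "many"],
               "many_genes")
  expect_match(res$report$failed_rules[res$report$cell_id == "mito"],
               "high_mito")

  # idempotent: filtering twice equals filtering once
  res2 <- qc_filter(res$cells, thr)
  expect_equal(res2$cells$cell_meta, res$cells$cell_meta)
  expect_true(all(res2$report$pass))

  # nothing survives -> error with tally
  thr_hard <- qc_thresholds(min_counts = 1e6, min_genes = 3, max_genes = 5)
  expect_error(qc_filter(cells, thr_hard), "no cells survive")
})

test_that("normalization is CP10K-log with per-cell scale invariance", {
  counts <- matrix(c(100, 0, 0, 50, 25, 25), 3,
                   dimnames = list(paste0("G", 1:3), c("C1", "C2")))
  cells <- toy_cells(counts)
  norm <- normalize_cells(cells)
  expect_equal(norm["G1", "C1"], log2(1 + 1e4))
  expect_equal(norm["G1", "C2"], log2(1 + 1e4 * 0.5))
  # doubling all counts of a cell leaves its vector unchanged
  cells2 <- toy_cells(cbind(counts, C3 = 2 * counts[, "C2"]))
  norm2 <- normalize_cells(cells2)
  expect_equal(norm2[, "C3"], norm2[, "C2"], ignore_attr = TRUE)
  # direct hand computation on a 5x4 fixture
  set.seed(3)
  m <- matrix(rpois(20, 10), 5,
              dimnames = list(paste0("G", 1:5), paste0("C", 1:4)))
  ref <- sapply(1:4, function(j) log2(1 + 1e4 * m[, j] / sum(m[, j])))
  expect_equal(unname(normalize_cells(toy_cells(m))), unname(ref))
})

test_that("per-cell scoring flags exactly floor(0.3 n) cells and is order-stable", {
  set.seed(8)
  sim <- simulate_cells(sim_config(n_patients = 2, cells_per_patient = 60,
                                   qc_fail_fraction = 0, seed = 8))
  norm <- normalize_cells(sim$cells)
  sc <- score_cells(norm, sim$cells$cell_meta)
  n <- nrow(sc$table)
  expect_equal(sum(sc$table$top30_glycolysis), floor(0.3 * n))
  expect_equal(sum(sc$table$top30_hypoxia), floor(0.3 * n))
  expect_true(all(abs(sc$table$glycolysis_score) <= 1))

  # shuffling cell order leaves scores unchanged
  perm <- sample(ncol(norm))
  sc2 <- score_cells(norm[, perm], sim$cells$cell_meta)
  m <- match(sc$table$cell_id, sc2$table$cell_id)
  expect_equal(sc$table$glycolysis_score, sc2$table$glycolysis_score[m],
               tolerance = 1e-12)
})

test_that("simulated QC failures are removed exactly per truth table", {
  sim <- simulate_cells(sim_config(n_patients = 3, cells_per_patient = 80,
                                   qc_fail_fraction = 0.1, seed = 21))
  res <- qc_filter(sim$cells)
  removed <- res$report$cell_id[!res$report$pass]
  expect_true(all(sim$truth$planted_qc_fail %in% removed))
  # removed set equals an independent recomputation from raw counts
  cnt <- as.matrix(sim$cells$counts)
  total <- colSums(cnt)
  ngene <- colSums(cnt > 0)
  mito <- colSums(cnt[startsWith(rownames(cnt), "MT-"), ]) / total
  bad <- colnames(cnt)[total < 200 | ngene < 200 | ngene > 6000 |
                         mito > 0.10]
  expect_setequal(removed, bad)
})

test_that("region ANOVA detects a planted core-elevated hypoxia program", {
  sim <- simulate_cells(sim_config(n_patients = 4, cells_per_patient = 120,
                                   region_shift = 0.8, qc_fail_fraction = 0,
                                   seed = 31))
  norm <- normalize_cells(sim$cells)
  sc <- score_cells(norm, sim$cells$cell_meta)
  ra <- region_compare(sc$table)
  hyp <- ra[ra$score == "hypoxia_score", ]
  expect_true(all(hyp$status == "ok"))
  expect_gte(mean(hyp$p_value < 0.05), 0.75)
  expect_true(all(hyp$mean_core > hyp$mean_edge))

  # patient with a single region is skipped with a status
  tab <- sc$table
  tab$region[tab$patient_id == "P01"] <- "edge"
  ra2 <- region_compare(tab)
  expect_match(ra2$status[ra2$patient_id == "P01"][1], "skipped")
})

test_that("independent programs yield near-zero cell-level correlation", {
  # overlap-free signatures: the shared six genes load on both programs
  # by design, so the pure-null check needs disjoint sets
  disjoint <- list(
    glycolysis = setdiff(builtin_signature("glycolysis22"),
                         builtin_signature("hypoxia14")),
    hypoxia = setdiff(builtin_signature("hypoxia14"),
                      builtin_signature("glycolysis22")))
  set.seed(17)
  rhos <- sapply(1:10, function(r) {
    sim <- simulate_cells(sim_config(n_patients = 2, cells_per_patient = 100,
                                     cell_rho = 0, region_shift = 0,
                                     qc_fail_fraction = 0,
                                     seed = 1000 + r))
    sc <- score_cells(normalize_cells(sim$cells), sim$cells$cell_meta,
                      sets = disjoint)
    sc$correlation$rho
  })
  expect_lte(median(abs(rhos)), 0.1)
})
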