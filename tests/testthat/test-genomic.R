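cna_fixture <- function(calls, genes = sprintf("G%02d", seq_len(nrow(calls))),
                        samples = sprintf("S%03d", seq_len(ncol(calls)))) {
  dimnames(calls) <- list(genes, samples)
  storage.mode(calls) <- "integer"
  calls
}

test_that("gain/loss calling applies the ratio-2 rule with its boundary", {
  # 20 gains / 9 losses -> ratio 2.22 -> gain
  m <- cna_fixture(matrix(c(rep(1L, 20), rep(-1L, 9), rep(0L, 11)), 1))
  res <- call_gain_loss(m)
  expect_equal(res$call, "gain")
  expect_equal(res$ratio, 20 / 9)

  # 4 gains / 2 losses -> ratio exactly 2, not > 2 -> ambiguous
  m2 <- cna_fixture(matrix(c(rep(1L, 4), rep(-1L, 2), rep(0L, 4)), 1))
  expect_equal(call_gain_loss(m2)$call, "ambiguous")

  # no alterations -> ambiguous, ratio undefined
  m3 <- cna_fixture(matrix(rep(0L, 6), 1))
  expect_equal(call_gain_loss(m3)$call, "ambiguous")
  expect_true(is.na(call_gain_loss(m3)$ratio))

  # zero denominator: any gain with no losses is a gain
  m4 <- cna_fixture(matrix(c(1L, rep(0L, 5)), 1))
  expect_equal(call_gain_loss(m4)$call, "gain")

  # symmetry: flipping the coding flips the calls
  set.seed(10)
  m5 <- cna_fixture(matrix(sample(c(-1L, 0L, 1L), 200, TRUE,
                                  prob = c(0.4, 0.3, 0.3)), 10))
  a <- call_gain_loss(m5)
  b <- call_gain_loss(cna_fixture(-m5))
  flip <- c(gain = "loss", loss = "gain", ambiguous = "ambiguous")
  expect_equal(unname(flip[a$call]), b$call)
})

genomic_fixture <- function(n = 200, n_genes = 50, shift_gene = NULL,
                            shift = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%04d", 1:n)
  cl <- data.frame(sample_id = ids, cancer_type = "CT01",
                   sample_type = "tumor", stage = NA, os_time = 100,
                   os_event = 0L, aneuploidy_score = NA,
                   genome_doublings = NA, stringsAsFactors = FALSE)
  cna <- matrix(sample(c(-1L, 0L, 1L), n_genes * n, TRUE,
                       prob = c(0.15, 0.7, 0.15)), n_genes,
                dimnames = list(sprintf("G%03d", 1:n_genes), ids))
  s <- setNames(rnorm(n, sd = 0.3), ids)
  if (!is.null(shift_gene))
    s[cna[shift_gene, ] == 1] <- s[cna[shift_gene, ] == 1] + shift
  list(cl = cl, cna = cna, scores = s)
}

test_that("CNA association detects a planted gain effect and adjusts per cohort", {
  fx <- genomic_fixture(n = 500, shift_gene = "G001", shift = 0.4)
  res <- cna_association(fx$scores, fx$cna, fx$cl)
  hit <- res[res$gene_id == "G001" & res$comparison == "gain_vs_neutral", ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$adj_p, 0.05)
  expect_gt(hit$delta_mean_score, 0.2)
  # BH is applied within the cohort: adj_p >= p everywhere
  expect_true(all(res$adj_p >= res$p_value - 1e-12))

  # direction map restricts comparisons
  dm <- c(G001 = "oncogene", G002 = "suppressor")
  res_d <- cna_association(fx$scores, fx$cna, fx$cl, direction_map = dm)
  expect_setequal(unique(res_d$comparison[res_d$gene_id == "G001"]),
                  "gain_vs_neutral")
  expect_setequal(unique(res_d$comparison[res_d$gene_id == "G002"]),
                  "loss_vs_neutral")
  expect_error(
    cna_association(fx$scores, fx$cna, fx$cl,
                    direction_map = c(G001 = "driver")),
    "oncogene")
})

test_that("BH within cohort is applied per cancer type, not pooled", {
  fx1 <- genomic_fixture(n = 100, seed = 3)
  fx2 <- genomic_fixture(n = 100, seed = 4)
  fx2$cl$cancer_type <- "CT02"
  fx2$cl$sample_id <- sub("^S", "T", fx2$cl$sample_id)
  colnames(fx2$cna) <- fx2$cl$sample_id
  names(fx2$scores) <- fx2$cl$sample_id
  cl <- rbind(fx1$cl, fx2$cl)
  cna <- cbind(fx1$cna, fx2$cna)
  s <- c(fx1$scores, fx2$scores)
  res <- cna_association(s, cna, cl)
  for (ct in c("CT01", "CT02")) {
    sub <- res[res$cancer_type == ct, ]
    expect_equal(sub$adj_p, bh_adjust(sub$p_value), tolerance = 1e-12)
  }
})

test_that("SNV association collapses multiplicity and skips degenerate genes", {
  set.seed(6)
  n <- 300
  ids <- sprintf("S%04d", 1:n)
  cl <- data.frame(sample_id = ids, cancer_type = "CT01",
                   sample_type = "tumor", stage = NA, os_time = 1,
                   os_event = 0L, aneuploidy_score = NA,
                   genome_doublings = NA, stringsAsFactors = FALSE)
  s <- setNames(rnorm(n, sd = 0.3), ids)
  carriers <- sample(ids, 60)
  s[carriers] <- s[carriers] + 0.5
  mut <- rbind(
    data.frame(sample_id = carriers, gene_id = "DRV",
               nonsynonymous = TRUE),
    data.frame(sample_id = carriers[1:10], gene_id = "DRV",
               nonsynonymous = TRUE),        # duplicates: must collapse
    data.frame(sample_id = sample(ids, 40), gene_id = "SYN_ONLY",
               nonsynonymous = FALSE),        # synonymous-only gene
    data.frame(sample_id = ids, gene_id = "ALLMUT",
               nonsynonymous = TRUE))         # no wildtype arm
  res <- snv_association(s, mut, cl)
  expect_false("SYN_ONLY" %in% res$gene_id)
  expect_false("ALLMUT" %in% res$gene_id)
  hit <- res[res$gene_id == "DRV", ]
  expect_equal(hit$n_alt, 60)  # collapsed presence/absence
  expect_lt(hit$adj_p, 0.05)
  expect_gt(hit$delta_mean_score, 0.3)
})

test_that("driver panorama counts significant types and ranks by recount", {
  assoc <- do.call(rbind, lapply(sprintf("CT%02d", 1:25), function(ct) {
    data.frame(gene_id = c("EGFR", "TP53", "MYC"), cancer_type = ct,
               comparison = c("gain_vs_neutral", "loss_vs_neutral",
                              "gain_vs_neutral"),
               delta_mean_score = c(0.3, -0.2, 0.1),
               statistic = 1, p_value = c(NA, NA, NA), n_alt = 10,
               n_ref = 10, adj_p = NA, stringsAsFactors = FALSE)
  }))
  # plant: EGFR significant in 11 types, TP53 in 5, MYC in none
  assoc$p_value <- 0.5
  assoc$p_value[assoc$gene_id == "EGFR"][1:11] <- 0.01
  assoc$p_value[assoc$gene_id == "TP53"][1:5] <- 0.01
  drv <- c(EGFR = "oncogene", TP53 = "suppressor", MYC = "oncogene")
  pano <- driver_panorama(assoc, drv)
  expect_equal(pano$gene_id, c("EGFR", "TP53", "MYC"))
  expect_equal(pano$n_significant, c(11L, 5L, 0L))
  # recount oracle
  recount <- sum(assoc$p_value[assoc$gene_id == "EGFR" &
                                 assoc$comparison == "gain_vs_neutral"] < 0.05)
  expect_equal(pano$n_significant[1], recount)

  # no driver significant anywhere: counts 0, stable sort incl. by name
  assoc$p_value <- 0.5
  pano0 <- driver_panorama(assoc, drv)
  expect_equal(pano0$n_significant, c(0L, 0L, 0L))
  # absent driver flagged with count 0
  pano_a <- driver_panorama(assoc, c(drv, NOPE = "oncogene"))
  expect_match(pano_a$flag[pano_a$gene_id == "NOPE"], "absent")
  expect_error(driver_panorama(assoc, c(EGFR = "onc")), "oncogene")
})

test_that("TMB counts nonsynonymous records only; burden analyses run", {
  mut <- data.frame(
    sample_id = c(rep("S1", 10), rep("S2", 3)),
    gene_id = paste0("G", 1:13),
    nonsynonymous = c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 3)),
    stringsAsFactors = FALSE)
  expect_equal(tmb(mut, c("S1", "S2", "S3")),
               c(S1 = 7L, S2 = 3L, S3 = 0L))

  cl <- make_clinical(120, 0, seed = 8)
  s <- setNames(rnorm(120), cl$sample_id)
  mut2 <- data.frame(sample_id = sample(cl$sample_id, 400, TRUE),
                     gene_id = sample(paste0("G", 1:50), 400, TRUE),
                     nonsynonymous = TRUE, stringsAsFactors = FALSE)
  res <- burden_and_ploidy(s, mut2, cl)
  expect_setequal(unique(res$analysis),
                  c("tmb_high_vs_low", "aneuploidy_spearman",
                    "genome_doubling_anova"))
  expect_true(all(res$status == "ok"))
  # identical doubling-class distributions -> no signal expected
  expect_gt(res$p_value[res$analysis == "genome_doubling_anova"], 0.001)

  # all-missing aneuploidy is skipped, not an error
  cl$aneuploidy_score <- NA
  res2 <- burden_and_ploidy(s, mut2, cl)
  expect_match(res2$status[res2$analysis == "aneuploidy_spearman"],
               "skipped")
})

test_that("planted aneuploidy correlation is recovered", {
  set.seed(13)
  hits <- 0
  for (r in 1:50) {
    n <- 300
    g <- rnorm(n)
    an <- pmax(0, round(8 + 3 * (0.4 * g + sqrt(1 - 0.16) * rnorm(n))))
    rho <- spearman(g, an)$rho
    hits <- hits + (abs(rho - 0.4) < 0.1)
  }
  expect_gte(hits / 50, 0.85)
})
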