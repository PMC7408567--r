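screen_fixture <- function(n_genes = 20, n_per_group = 30, n_up = 4,
                           shift = 1.2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group + 20
  ids <- sprintf("S%04d", 1:n)
  x <- matrix(rnorm(n_genes * n, 6, 0.5), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes), ids))
  s <- setNames(c(rep(2, n_per_group), rep(-2, n_per_group),
                  rnorm(20)), ids)
  lab <- classify_by_score(s, q = n_per_group / n, min_group = 2)
  hi <- lab$sample_id[lab$label == "high"]
  if (n_up > 0) x[1:n_up, hi] <- x[1:n_up, hi] + shift
  list(x = x, lab = lab, s = s, up = rownames(x)[seq_len(n_up)])
}

test_that("differential enrichment flags the stratifying signature itself", {
  set.seed(20)
  fx <- screen_fixture()
  scores <- cbind(stratifier = fx$s,
                  unrelated = rnorm(length(fx$s)))
  rownames(scores) <- names(fx$s)
  res <- diff_signature_enrichment(scores, fx$lab, cancer_type = "CT01")
  strat <- res[res$signature == "stratifier", ]
  expect_gt(strat$delta, 0)
  expect_lt(strat$adj_p, 0.05)
  expect_gt(res$adj_p[res$signature == "unrelated"], 0.05)
  expect_equal(res$adj_p, bh_adjust(res$p_value))
})

test_that("DE genes require the fold threshold and adjusted p jointly", {
  fx <- screen_fixture(n_up = 4, shift = 1.2)
  de <- de_genes(fx$x, fx$lab, fc_threshold = 1.5, alpha = 0.05)
  expect_setequal(de$gene_id[de$direction == "up"], fx$up)

  # exhaustive oracle recount: per-gene wilcoxon + BH + conjunctive rule
  hi <- fx$lab$sample_id[fx$lab$label == "high"]
  lo <- fx$lab$sample_id[fx$lab$label == "low"]
  p <- sapply(rownames(fx$x), function(g)
    wilcox.test(fx$x[g, hi], fx$x[g, lo], exact = FALSE)$p.value)
  fc <- rowMeans(2^fx$x[, hi]) / rowMeans(2^fx$x[, lo])
  adj <- p.adjust(p, "BH")
  expect_setequal(de$gene_id[de$direction == "up"],
                  names(which(fc >= 1.5 & adj < 0.05)))

  # a strong shift below the fold threshold is excluded
  fx2 <- screen_fixture(n_up = 1, shift = 0.45, n_per_group = 200, seed = 2)
  de2 <- de_genes(fx2$x, fx2$lab)
  g <- de2[de2$gene_id == fx2$up, ]
  expect_lt(g$adj_p, 0.05)                 # highly significant...
  expect_lt(2^g$log2_fold_change, 1.5)     # ...but under 1.5-fold
  expect_equal(g$direction, "ns")          # so not called up

  # constant gene gets p = 1
  fx3 <- screen_fixture(n_up = 0)
  fx3$x[1, ] <- 3
  de3 <- de_genes(fx3$x, fx3$lab)
  expect_equal(de3$p_value[de3$gene_id == rownames(fx3$x)[1]], 1)
})

test_that("recurrent genes are direction-specific and recounted", {
  mk <- function(up, down = character(0)) {
    data.frame(gene_id = c(up, down),
               direction = c(rep("up", length(up)),
                             rep("down", length(down))),
               stringsAsFactors = FALSE)
  }
  de_list <- c(replicate(13, mk("PAN1", "OSC1"), simplify = FALSE),
               replicate(12, mk(c("OSC1", "ALSO12")), simplify = FALSE))
  res <- recurrent_genes(de_list, k = 13)
  expect_equal(res$gene_id, "PAN1")
  expect_equal(res$n_up, 13L)
  # OSC1 is up in 12 and down in 13: direction-specific exclusion
  expect_false("OSC1" %in% res$gene_id)
  # k = 1 equals the union of per-cancer up lists
  res1 <- recurrent_genes(de_list, k = 1)
  expect_setequal(res1$gene_id, c("PAN1", "OSC1", "ALSO12"))
  expect_error(recurrent_genes(de_list[1:5], k = 13), "exceeds")
})

test_that("candidate ranking recovers a planted regulator among decoys", {
  set.seed(30)
  n <- 150
  hits <- 0
  for (r in 1:20) {
    g_lat <- rnorm(n)
    ids <- sprintf("S%03d", 1:n)
    x <- matrix(rnorm(51 * n, 5), 51,
                dimnames = list(c("REG", sprintf("D%02d", 1:50)), ids))
    x["REG", ] <- 5 + 0.8 * g_lat + sqrt(1 - 0.64) * rnorm(n)
    s <- setNames(g_lat + 0.2 * rnorm(n), ids)
    cr <- candidate_rank(list(CT01 = x), list(CT01 = s), rownames(x))
    hits <- hits + (cr$gene_id[1] == "REG")
  }
  expect_gte(hits / 20, 0.9)

  # deterministic tie-break by name and missing-candidate status
  x <- matrix(rnorm(2 * 50, 5), 2,
              dimnames = list(c("B", "A"), sprintf("S%02d", 1:50)))
  x["A", ] <- x["B", ]
  s <- setNames(rnorm(50), colnames(x))
  cr <- candidate_rank(list(CT = x), list(CT = s), c("B", "A", "ZZ"))
  expect_equal(cr$gene_id[1:2], c("A", "B"))
  expect_equal(cr$status[cr$gene_id == "ZZ"], "missing")
})

test_that("quadrant stratification matches the double-sort oracle", {
  # n = 4 distinct on both axes: one sample per quadrant
  ids <- paste0("S", 1:4)
  hyp <- setNames(c(1, 2, 3, 4), ids)
  x <- matrix(c(1, 2, 3, 4), 1, dimnames = list("P4HA1", ids))
  qs <- quadrant_stratify(hyp, x, "P4HA1")
  expect_equal(sort(table(qs$labels$quadrant)), sort(c("H+G+" = 1,
               "H+G-" = 1, "H-G+" = 1, "H-G-" = 1)), ignore_attr = TRUE)

  # n = 10: membership equals an exhaustive double sort
  set.seed(41)
  ids <- paste0("S", sprintf("%02d", 1:10))
  hyp <- setNames(rnorm(10), ids)
  x <- matrix(rnorm(10), 1, dimnames = list("GENE", ids))
  qs <- quadrant_stratify(hyp, x, "GENE")
  o <- order(hyp, ids)
  hplus <- ids[o[6:10]]; hminus <- ids[o[1:5]]
  oracle <- character(10); names(oracle) <- ids
  for (str in list(c("H+", hplus), c("H-", hminus))) {
    sids <- str[-1]
    og <- order(x[1, sids], sids)
    gplus <- sids[og][(length(sids) - floor(length(sids) / 2) + 1):length(sids)]
    oracle[sids] <- paste0(str[1], ifelse(sids %in% gplus, "G+", "G-"))
  }
  expect_equal(setNames(qs$labels$quadrant, qs$labels$sample_id),
               oracle[qs$labels$sample_id])
  # within each hypoxia stratum the quadrant sizes differ by at most 1
  tab <- table(qs$labels$quadrant)
  expect_lte(abs(tab["H+G+"] - tab["H+G-"]), 1)
  expect_lte(abs(tab["H-G+"] - tab["H-G-"]), 1)
  expect_error(quadrant_stratify(hyp, x, "NOPE"), "absent")
})

test_that("an amplifying gene makes the H+G+ quadrant score highest", {
  set.seed(55)
  hits <- 0
  for (r in 1:30) {
    n <- 200
    h <- rnorm(n)
    gx <- rnorm(n)                       # modifier gene expression
    gly <- 0.5 * h + 0.6 * h * (gx > 0) + 0.3 * rnorm(n)
    ids <- sprintf("S%03d", 1:n)
    x <- matrix(5 + gx, 1, dimnames = list("MOD", ids))
    qs <- quadrant_stratify(setNames(h, ids), x, "MOD",
                            targets = list(gly = setNames(gly, ids)))
    sm <- qs$summary
    hits <- hits + (sm$quadrant[which.max(sm$mean)] == "H+G+")
  }
  expect_gte(hits / 30, 0.9)
})
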