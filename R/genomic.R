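# Copy-number / mutation association with glycolysis scores, gain-loss
# calling, tumor mutation burden, aneuploidy and genome-doubling analyses.

#' Cohort-level gain/loss calling per gene
#'
#' Counts gain (+1), loss (-1) and neutral (0) samples per gene within a
#' cohort and applies the gain-loss ratio rule: a gene is called `gain`
#' when n_gain / n_loss > 2 and `loss` when n_loss / n_gain > 2; a zero
#' denominator with a nonzero numerator counts as exceeding the ratio.
#' Everything else (including 0/0) is `ambiguous`.
#'
#' @param cna CNA matrix (genes x samples, entries in \{-1, 0, 1\}).
#' @param samples optional character vector restricting the columns
#'   (e.g., one cancer type).
#' @return data.frame: gene_id, n_gain, n_loss, n_neutral, ratio
#'   (gain/loss; NA when undefined), call.
#' @export
call_gain_loss <- function(cna, samples = NULL) {
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(cna))
    if (length(missing_s))
      stop_fmt("samples absent from CNA matrix: %s",
               paste(utils::head(missing_s, 5), collapse = ", "))
    cna <- cna[, samples, drop = FALSE]
  }
  if (ncol(cna) < 1) stop_fmt("call_gain_loss needs >= 1 sample")
  n_gain <- rowSums(cna == 1)
  n_loss <- rowSums(cna == -1)
  n_neutral <- rowSums(cna == 0)
  ratio <- ifelse(n_loss > 0, n_gain / n_loss,
                  ifelse(n_gain > 0, Inf, NA_real_))
  call <- rep("ambiguous", nrow(cna))
  call[(n_gain > 0 & n_loss == 0) | (n_loss > 0 & n_gain / n_loss > 2)] <- "gain"
  call[(n_loss > 0 & n_gain == 0) | (n_gain > 0 & n_loss / n_gain > 2)] <- "loss"
  # both zero stays ambiguous; the two exclusive conditions cannot overlap
  call[n_gain == 0 & n_loss == 0] <- "ambiguous"
  data.frame(gene_id = rownames(cna), n_gain = n_gain, n_loss = n_loss,
             n_neutral = n_neutral, ratio = ratio, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

assoc_frame <- function(gene, type, comparison, res) {
  data.frame(gene_id = gene, cancer_type = type, comparison = comparison,
             delta_mean_score = res$delta, statistic = res$statistic,
             p_value = res$p_value, n_alt = res$n_alt, n_ref = res$n_ref,
             stringsAsFactors = FALSE)
}

#' Copy-number association with signature scores
#'
#' Per gene and cancer type, Welch t test of scores in copy-number-altered
#' versus copy-number-neutral samples. Without a `direction_map`, both
#' gain-vs-neutral and loss-vs-neutral scans run per gene; with one
#' (named vector, values `"oncogene"` / `"suppressor"`), gains are tested
#' for oncogenes and losses for tumor suppressors. Benjamini-Hochberg
#' adjustment is applied within each cancer type, never pooled.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param cna CNA matrix.
#' @param clinical clinical data.frame (supplies cancer types; tumor
#'   samples only).
#' @param direction_map optional named character vector of driver roles.
#' @param min_altered minimum altered-arm size per test (default 5;
#'   arms under 2 are never tested).
#' @return data.frame of association records with `adj_p` per cohort.
#' @export
cna_association <- function(scores, cna, clinical, direction_map = NULL,
                            min_altered = 5) {
  if (!is.null(direction_map)) {
    bad <- setdiff(unique(direction_map), c("oncogene", "suppressor"))
    if (length(bad))
      stop_fmt("direction_map values must be 'oncogene' or 'suppressor'")
  }
  cl <- clinical[clinical$sample_type == "tumor" &
                   clinical$sample_id %in% names(scores) &
                   clinical$sample_id %in% colnames(cna), ]
  out <- list()
  for (ct in sort(unique(cl$cancer_type))) {
    ids <- cl$sample_id[cl$cancer_type == ct]
    if (length(ids) < 4) next
    sub <- cna[, ids, drop = FALSE]
    s <- scores[ids]
    genes <- if (is.null(direction_map)) rownames(sub)
             else intersect(names(direction_map), rownames(sub))
    recs <- list()
    for (cmp in c("gain_vs_neutral", "loss_vs_neutral")) {
      alt_val <- if (cmp == "gain_vs_neutral") 1L else -1L
      gsel <- genes
      if (!is.null(direction_map)) {
        want <- if (cmp == "gain_vs_neutral") "oncogene" else "suppressor"
        gsel <- genes[direction_map[genes] == want]
      }
      if (!length(gsel)) next
      alt <- sub[gsel, , drop = FALSE] == alt_val
      ref <- sub[gsel, , drop = FALSE] == 0L
      n_alt <- rowSums(alt); n_ref <- rowSums(ref)
      test <- n_alt >= max(2, min_altered) & n_ref >= 2
      if (!any(test)) next
      wt <- welch_t_rows(s, alt[test, , drop = FALSE],
                         ref[test, , drop = FALSE])
      recs[[cmp]] <- assoc_frame(gsel[test], ct, cmp, wt)
    }
    if (!length(recs)) next
    rec <- do.call(rbind, recs)
    rec$adj_p <- bh_adjust(rec$p_value)
    out[[ct]] <- rec
  }
  if (!length(out))
    return(data.frame(gene_id = character(), cancer_type = character(),
                      comparison = character(), delta_mean_score = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      n_alt = numeric(), n_ref = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutation association with signature scores
#'
#' Nonsynonymous mutation records are collapsed to per-sample
#' presence/absence per gene; scores are compared mutated versus wildtype
#' (Welch t), with Benjamini-Hochberg adjustment within each cancer type.
#' Genes mutated in fewer than `min_mutated` samples, or with fewer than
#' 2 wildtype samples, are skipped.
#'
#' @param scores named numeric vector.
#' @param mutations mutation data.frame (see [read_mutations()]).
#' @param clinical clinical data.frame.
#' @param min_mutated minimum mutated-arm size (default 5).
#' @return data.frame of association records with `adj_p`.
#' @export
snv_association <- function(scores, mutations, clinical, min_mutated = 5) {
  mut <- mutations[mutations$nonsynonymous, c("sample_id", "gene_id")]
  cl <- clinical[clinical$sample_type == "tumor" &
                   clinical$sample_id %in% names(scores), ]
  out <- list()
  for (ct in sort(unique(cl$cancer_type))) {
    ids <- cl$sample_id[cl$cancer_type == ct]
    if (length(ids) < 4) next
    s <- scores[ids]
    msub <- unique(mut[mut$sample_id %in% ids, ])
    if (!nrow(msub)) next
    genes <- sort(unique(msub$gene_id))
    alt <- matrix(FALSE, length(genes), length(ids),
                  dimnames = list(genes, ids))
    alt[cbind(match(msub$gene_id, genes), match(msub$sample_id, ids))] <- TRUE
    ref <- !alt
    n_alt <- rowSums(alt); n_ref <- rowSums(ref)
    test <- n_alt >= max(2, min_mutated) & n_ref >= 2
    if (!any(test)) next
    wt <- welch_t_rows(s, alt[test, , drop = FALSE], ref[test, , drop = FALSE])
    rec <- assoc_frame(genes[test], ct, "mutated_vs_wildtype", wt)
    rec$adj_p <- bh_adjust(rec$p_value)
    out[[ct]] <- rec
  }
  if (!length(out))
    return(data.frame(gene_id = character(), cancer_type = character(),
                      comparison = character(), delta_mean_score = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      n_alt = numeric(), n_ref = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pan-cancer driver CNA panorama
#'
#' For each annotated driver, counts the cancer types in which its
#' directional association (gain for oncogenes, loss for tumor
#' suppressors) reached p < `alpha`, and ranks drivers by that count
#' (ties by mean |delta|, then gene name). Drivers absent from the
#' association records get count 0 and a flag.
#'
#' @param assoc association records from [cna_association()] run with a
#'   `direction_map`.
#' @param drivers named character vector: gene -> `"oncogene"` or
#'   `"suppressor"`; every queried driver must be annotated.
#' @param alpha per-type significance threshold (default 0.05).
#' @param top truncate the ranking to this many drivers (default 50).
#' @return data.frame: gene_id, role, n_significant, mean_abs_delta,
#'   rank, flag.
#' @export
driver_panorama <- function(assoc, drivers, alpha = 0.05, top = 50) {
  if (is.null(names(drivers)) || any(!nzchar(names(drivers))))
    stop_fmt("drivers must be a named vector (gene -> role)")
  bad <- setdiff(unique(drivers), c("oncogene", "suppressor"))
  if (length(bad))
    stop_fmt("unannotated driver role(s): every driver needs 'oncogene' or 'suppressor'")
  rows <- lapply(names(drivers), function(g) {
    cmp <- if (drivers[[g]] == "oncogene") "gain_vs_neutral" else "loss_vs_neutral"
    sub <- assoc[assoc$gene_id == g & assoc$comparison == cmp, ]
    data.frame(gene_id = g, role = unname(drivers[[g]]),
               n_significant = sum(sub$p_value < alpha, na.rm = TRUE),
               mean_abs_delta = if (nrow(sub)) mean(abs(sub$delta_mean_score))
                                else 0,
               flag = if (nrow(sub)) "" else "absent from association records",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  o <- order(-out$n_significant, -out$mean_abs_delta, out$gene_id)
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Tumor mutation burden per sample
#'
#' Raw count of nonsynonymous mutation records per sample (synonymous
#' records are ignored; samples without records count 0).
#'
#' @param mutations mutation data.frame.
#' @param sample_ids samples to report (defaults to those present in the
#'   table).
#' @return named integer vector.
#' @export
tmb <- function(mutations, sample_ids = NULL) {
  mut <- mutations[mutations$nonsynonymous, ]
  if (is.null(sample_ids)) sample_ids <- sort(unique(mutations$sample_id))
  counts <- table(factor(mut$sample_id, levels = sample_ids))
  stats::setNames(as.integer(counts), sample_ids)
}

#' Mutation-burden, aneuploidy and genome-doubling analyses
#'
#' Per cancer type: rank-sum test of tumor mutation burden between the
#' score-high and score-low groups, Spearman correlation of score with
#' aneuploidy score, and a one-way ANOVA of scores across genome-doubling
#' classes (0 / 1 / 2). Analyses whose inputs are entirely missing are
#' reported with a `skipped` status.
#'
#' @param scores named numeric vector.
#' @param mutations mutation data.frame.
#' @param clinical clinical data.frame.
#' @param q,min_group stratification parameters for the TMB group test.
#' @return data.frame, one row per cancer type x analysis.
#' @export
burden_and_ploidy <- function(scores, mutations, clinical, q = 0.30,
                              min_group = 2) {
  cl <- clinical[clinical$sample_type == "tumor" &
                   clinical$sample_id %in% names(scores), ]
  burden <- tmb(mutations, cl$sample_id)
  rows <- list()
  for (ct in sort(unique(cl$cancer_type))) {
    sub <- cl[cl$cancer_type == ct, ]
    s <- scores[sub$sample_id]
    # TMB: high vs low score groups
    lab <- classify_by_score(s, q = q, min_group = min_group)
    hi <- burden[lab$sample_id[lab$label == "high"]]
    lo <- burden[lab$sample_id[lab$label == "low"]]
    rows[[length(rows) + 1]] <- if (length(hi) >= 1 && length(lo) >= 1) {
      tr <- two_sample_test(hi, lo, "rank_sum")
      data.frame(cancer_type = ct, analysis = "tmb_high_vs_low",
                 estimate = mean(hi) - mean(lo), statistic = tr$statistic,
                 p_value = tr$p_value, n = length(hi) + length(lo),
                 status = "ok")
    } else {
      data.frame(cancer_type = ct, analysis = "tmb_high_vs_low",
                 estimate = NA_real_, statistic = NA_real_,
                 p_value = NA_real_, n = 0L, status = "skipped: empty group")
    }
    # aneuploidy Spearman
    an <- sub$aneuploidy_score
    ok <- !is.na(an)
    rows[[length(rows) + 1]] <- if (sum(ok) >= 3) {
      sp <- spearman(s[ok], an[ok])
      data.frame(cancer_type = ct, analysis = "aneuploidy_spearman",
                 estimate = sp$rho, statistic = sp$rho, p_value = sp$p_value,
                 n = sp$n, status = "ok")
    } else {
      data.frame(cancer_type = ct, analysis = "aneuploidy_spearman",
                 estimate = NA_real_, statistic = NA_real_,
                 p_value = NA_real_, n = sum(ok),
                 status = "skipped: aneuploidy missing")
    }
    # genome doublings: k-sample ANOVA across 0/1/2
    gd <- sub$genome_doublings
    groups <- split(s[!is.na(gd)], gd[!is.na(gd)])
    groups <- groups[lengths(groups) > 0]
    rows[[length(rows) + 1]] <- if (length(groups) >= 2) {
      kt <- k_sample_test(groups, "anova")
      data.frame(cancer_type = ct, analysis = "genome_doubling_anova",
                 estimate = NA_real_, statistic = kt$statistic,
                 p_value = kt$p_value, n = sum(lengths(groups)),
                 status = "ok")
    } else {
      data.frame(cancer_type = ct, analysis = "genome_doubling_anova",
                 estimate = NA_real_, statistic = NA_real_,
                 p_value = NA_real_, n = 0L,
                 status = "skipped: doubling classes missing")
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
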