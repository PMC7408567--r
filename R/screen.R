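# Differential enrichment / expression screening between score-high and
# score-low tumors, cross-cancer recurrence, candidate correlation
# ranking, and the double-median quadrant stratification.

high_low_ids <- function(labels) {
  list(high = labels$sample_id[labels$label == "high"],
       low = labels$sample_id[labels$label == "low"])
}

#' Differential signature enrichment between score-high and -low groups
#'
#' Welch t test on per-sample enrichment scores of each signature, high
#' versus low, with Benjamini-Hochberg adjustment across the signatures of
#' one cohort. Scores of single-sample enrichment are near-normal around
#' zero, so the t test is appropriate.
#'
#' @param scores samples x signatures matrix (e.g., from
#'   [score_matrix()]).
#' @param labels group labels from [classify_by_score()].
#' @param cancer_type label recorded in the output (single cohort).
#' @return data.frame: signature, cancer_type, delta (mean high - low),
#'   statistic, p_value, adj_p, enriched (adj_p < 0.05).
#' @export
diff_signature_enrichment <- function(scores, labels, cancer_type = NA) {
  hl <- high_low_ids(labels)
  hi <- intersect(hl$high, rownames(scores))
  lo <- intersect(hl$low, rownames(scores))
  if (length(hi) < 2 || length(lo) < 2)
    stop_fmt("both groups need >= 2 scored samples")
  rows <- lapply(colnames(scores), function(sig) {
    tr <- two_sample_test(scores[hi, sig], scores[lo, sig], "welch_t")
    data.frame(signature = sig, cancer_type = cancer_type,
               delta = mean(scores[hi, sig]) - mean(scores[lo, sig]),
               statistic = tr$statistic, p_value = tr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out$enriched <- out$adj_p < 0.05
  out
}

#' Differential expression between score-high and -low groups
#'
#' Per gene: Wilcoxon rank-sum p on log2(TPM+1) values, Benjamini-Hochberg
#' adjustment across genes, and fold change computed as the ratio of mean
#' linear TPM+1 values (the pseudocount is retained for stability at
#' zero). A gene is `up` when fold change >= `fc_threshold` and
#' adj_p < `alpha`; `down` symmetric; otherwise `ns`. Constant genes get
#' p = 1.
#'
#' @param expr genes x samples matrix, log2(TPM+1).
#' @param labels group labels from [classify_by_score()].
#' @param cancer_type cohort label for the output.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame: gene_id, cancer_type, log2_fold_change, p_value,
#'   adj_p, direction.
#' @export
de_genes <- function(expr, labels, cancer_type = NA, fc_threshold = 1.5,
                     alpha = 0.05) {
  hl <- high_low_ids(labels)
  hi <- intersect(hl$high, colnames(expr))
  lo <- intersect(hl$low, colnames(expr))
  if (length(hi) < 3 || length(lo) < 3)
    stop_fmt("both groups need >= 3 samples for DE")
  ehi <- expr[, hi, drop = FALSE]
  elo <- expr[, lo, drop = FALSE]
  fc <- rowMeans(2^ehi) / rowMeans(2^elo)  # linear TPM+1 scale
  p <- vapply(seq_len(nrow(expr)), function(i) {
    a <- ehi[i, ]; b <- elo[i, ]
    if (stats::sd(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  adj <- bh_adjust(p)
  direction <- rep("ns", nrow(expr))
  direction[fc >= fc_threshold & adj < alpha] <- "up"
  direction[fc <= 1 / fc_threshold & adj < alpha] <- "down"
  data.frame(gene_id = rownames(expr), cancer_type = cancer_type,
             log2_fold_change = log2(fc), p_value = p, adj_p = adj,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genes recurrently up-regulated across cancer types
#'
#' Genes flagged `up` in at least `k` of the per-cancer DE tables
#' (direction-specific: down-regulation never counts), sorted by
#' recurrence count (descending) then gene name.
#'
#' @param de_by_cancer list of data.frames from [de_genes()], one per
#'   cancer type.
#' @param k minimum number of cancer types (default 13).
#' @return data.frame: gene_id, n_up.
#' @export
recurrent_genes <- function(de_by_cancer, k = 13) {
  if (k > length(de_by_cancer))
    stop_fmt("k = %d exceeds the %d cancer types analyzed", k,
             length(de_by_cancer))
  ups <- unlist(lapply(de_by_cancer,
                       function(d) unique(d$gene_id[d$direction == "up"])))
  if (!length(ups))
    return(data.frame(gene_id = character(), n_up = integer(),
                      stringsAsFactors = FALSE))
  counts <- table(ups)
  keep <- counts[counts >= k]
  out <- data.frame(gene_id = names(keep), n_up = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$n_up, out$gene_id), , drop = FALSE]
}

#' Rank candidate genes by correlation with the glycolysis score
#'
#' Per cancer type, Spearman correlation between each candidate's
#' expression and the glycolysis score; candidates are ranked by the
#' median rho across cancer types (descending), ties broken by gene name.
#' The per-gene min and max rho are reported alongside.
#'
#' @param expr_by_cancer named list of genes x samples matrices.
#' @param scores_by_cancer named list of per-sample score vectors
#'   (aligned names with `expr_by_cancer`).
#' @param candidates character vector of gene symbols.
#' @return data.frame: gene_id, median_rho, min_rho, max_rho, n_types,
#'   rank, status.
#' @export
candidate_rank <- function(expr_by_cancer, scores_by_cancer, candidates) {
  types <- names(expr_by_cancer)
  rows <- lapply(candidates, function(g) {
    rhos <- c()
    for (ct in types) {
      expr <- expr_by_cancer[[ct]]
      if (!g %in% rownames(expr)) next
      s <- scores_by_cancer[[ct]]
      ids <- intersect(colnames(expr), names(s))
      if (length(ids) < 3) next
      sp <- spearman(expr[g, ids], s[ids])
      if (!is.na(sp$rho)) rhos <- c(rhos, sp$rho)
    }
    if (!length(rhos))
      return(data.frame(gene_id = g, median_rho = NA_real_,
                        min_rho = NA_real_, max_rho = NA_real_,
                        n_types = 0L, status = "missing",
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, median_rho = stats::median(rhos),
               min_rho = min(rhos), max_rho = max(rhos),
               n_types = length(rhos), status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  o <- order(-ifelse(is.na(out$median_rho), -Inf, out$median_rho),
             out$gene_id)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

top_half <- function(values, ids) {
  # top floor(n/2) by (value, id) lexicographic order; deterministic ties
  n <- length(values)
  k <- floor(n / 2)
  o <- order(values, ids)
  ids[o[seq.int(n - k + 1, n)]]
}

#' Quadrant stratification by hypoxia score and one gene's expression
#'
#' Median split on the hypoxia score (top 50% = `H+`), then a median
#' split on the chosen gene's expression within each hypoxia stratum
#' (`G+` / `G-`). Emits quadrant labels, per-quadrant summaries of any
#' requested target variables (e.g., the glycolysis score, LDHA or PGK1
#' expression), and pairwise Welch t tests between quadrants on each
#' target.
#'
#' @param hyp_scores named numeric vector of hypoxia scores.
#' @param expr genes x samples matrix containing `gene`.
#' @param gene gene whose expression defines the second split.
#' @param targets named list of per-sample numeric vectors to summarize
#'   per quadrant.
#' @return list: `labels` (data.frame sample_id, quadrant), `summary`
#'   (per quadrant x target mean/median/n), `pairwise` (Welch t between
#'   quadrants per target).
#' @export
quadrant_stratify <- function(hyp_scores, expr, gene, targets = list()) {
  if (!gene %in% rownames(expr))
    stop_fmt("gene '%s' absent from expression matrix", gene)
  ids <- intersect(names(hyp_scores), colnames(expr))
  if (length(ids) < 4) stop_fmt("quadrant stratification needs n >= 4")
  hs <- hyp_scores[ids]
  gx <- expr[gene, ids]
  hplus <- top_half(hs, ids)
  hminus <- setdiff(ids, hplus)
  quad <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (stratum in list(c("H+", "hplus"), c("H-", "hminus"))) {
    sids <- if (stratum[2] == "hplus") hplus else hminus
    gplus <- top_half(gx[sids], sids)
    quad[sids] <- paste0(stratum[1], ifelse(sids %in% gplus, "G+", "G-"))
  }
  labels <- data.frame(sample_id = ids, quadrant = unname(quad),
                       stringsAsFactors = FALSE)
  qlev <- c("H+G+", "H+G-", "H-G+", "H-G-")
  summarize <- function(nm, v) {
    do.call(rbind, lapply(qlev, function(qq) {
      sel <- labels$sample_id[labels$quadrant == qq]
      data.frame(target = nm, quadrant = qq, n = length(sel),
                 mean = mean(v[sel]), median = stats::median(v[sel]),
                 stringsAsFactors = FALSE)
    }))
  }
  summary_tab <- if (length(targets))
    do.call(rbind, Map(summarize, names(targets), targets)) else NULL
  pairwise <- NULL
  if (length(targets)) {
    pairs <- utils::combn(qlev, 2)
    pairwise <- do.call(rbind, lapply(names(targets), function(nm) {
      v <- targets[[nm]]
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        q1 <- labels$sample_id[labels$quadrant == pairs[1, i]]
        q2 <- labels$sample_id[labels$quadrant == pairs[2, i]]
        if (length(q1) < 2 || length(q2) < 2)
          return(data.frame(target = nm, quadrant_a = pairs[1, i],
                            quadrant_b = pairs[2, i], statistic = NA_real_,
                            p_value = NA_real_, stringsAsFactors = FALSE))
        tr <- two_sample_test(v[q1], v[q2], "welch_t")
        data.frame(target = nm, quadrant_a = pairs[1, i],
                   quadrant_b = pairs[2, i], statistic = tr$statistic,
                   p_value = tr$p_value, stringsAsFactors = FALSE)
      }))
    }))
  }
  if (!is.null(summary_tab)) rownames(summary_tab) <- NULL
  if (!is.null(pairwise)) rownames(pairwise) <- NULL
  list(labels = labels, summary = summary_tab, pairwise = pairwise)
}
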