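# End-to-end pipeline driver. The stage graph is linear with explicit
# on-disk intermediates so each stage is independently inspectable; a
# manifest records every output with its dimensions and the resolved
# parameters.

#' Pipeline run configuration
#'
#' @param expr,cna,mutations,clinical,mtx,genes,cell_meta input paths
#'   (single-cell paths optional).
#' @param gmt optional extra GMT of signatures for differential
#'   enrichment (the built-in catalog is always scored).
#' @param q stratification quantile (default 0.30).
#' @param min_group minimum high/low group size per cancer type (30).
#' @param min_normals minimum normal count for tumor-normal tests (30).
#' @param fc_threshold,alpha DE thresholds (1.5, 0.05).
#' @param k_recurrence minimum cancer types for recurrent genes (13;
#'   capped at the number of eligible types at run time).
#' @param drivers named character vector gene -> role for the panorama.
#' @param quadrant_gene gene for quadrant stratification.
#' @param seed RNG seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(expr, clinical, cna = NULL, mutations = NULL,
                       mtx = NULL, genes = NULL, cell_meta = NULL,
                       gmt = NULL, q = 0.30, min_group = 30,
                       min_normals = 30, fc_threshold = 1.5, alpha = 0.05,
                       k_recurrence = 13, drivers = NULL,
                       quadrant_gene = "P4HA1", seed = 1L) {
  stopifnot(q > 0, fc_threshold > 0, alpha > 0)
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full pipeline
#'
#' Scores the built-in signatures per cancer type, stratifies tumors into
#' glycolysis-high/low groups, and runs the tumor-versus-normal, stage,
#' survival, copy-number / mutation association, driver panorama,
#' burden/ploidy, differential-enrichment, differential-expression,
#' recurrence, candidate-ranking, quadrant and (when single-cell inputs
#' are given) single-cell stages. Every output lands in `out_dir` as a
#' TSV plus a `manifest.tsv` listing each artifact with its row count and
#' the resolved parameters.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of all stage results; the manifest is also
#'   written to `out_dir/manifest.tsv`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list()
  note <- function(name, file, rows, cols) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = name, file = basename(file), rows = rows, cols = cols,
      stringsAsFactors = FALSE)
  }
  fail <- function(stage, msg) stop_fmt("stage '%s' failed: %s", stage, msg)

  expr <- read_matrix(config$expr, "expression")
  clinical <- read_clinical(config$clinical)
  sets <- list(glycolysis22 = builtin_signature("glycolysis22"),
               hypoxia14 = builtin_signature("hypoxia14"),
               glycolysis16 = builtin_signature("glycolysis16"))
  if (!is.null(config$gmt)) {
    extra <- read_gmt(config$gmt)
    sets <- c(sets, extra[setdiff(names(extra), names(sets))])
  }

  # --- score per cancer type (tumors and normals scored together) -----
  cl <- clinical[clinical$sample_id %in% colnames(expr), ]
  types <- sort(unique(cl$cancer_type))
  score_list <- list()
  for (ct in types) {
    ids <- cl$sample_id[cl$cancer_type == ct]
    score_list[[ct]] <- score_matrix(expr[, ids, drop = FALSE], sets)
  }
  scores <- do.call(rbind, score_list)
  rownames(scores) <- unlist(lapply(score_list, rownames), use.names = FALSE)
  sc_df <- data.frame(sample_id = rownames(scores), scores,
                      check.names = FALSE, row.names = NULL)
  note("score", write_tsv(sc_df, file.path(out_dir, "scores.tsv")),
       nrow(sc_df), ncol(sc_df))
  gly <- stats::setNames(scores[, "glycolysis22"], rownames(scores))
  hyp <- stats::setNames(scores[, "hypoxia14"], rownames(scores))

  # --- classify tumors per cancer type --------------------------------
  labels_list <- list()
  eligible <- character(0)
  for (ct in types) {
    ids <- cl$sample_id[cl$cancer_type == ct & cl$sample_type == "tumor"]
    lab <- classify_by_score(gly[ids], q = config$q,
                             min_group = config$min_group)
    lab$cancer_type <- ct
    labels_list[[ct]] <- lab
    if (attr(lab, "eligible")) eligible <- c(eligible, ct)
  }
  labels_all <- do.call(rbind, labels_list)
  rownames(labels_all) <- NULL
  note("classify", write_tsv(labels_all, file.path(out_dir, "labels.tsv")),
       nrow(labels_all), ncol(labels_all))
  if (!length(eligible)) fail("classify", "no eligible cancer types")

  # --- tumor vs normal, stage, correlation ----------------------------
  tn <- tumor_normal_compare(gly, clinical, min_normals = config$min_normals)
  note("tumor_normal", write_tsv(tn, file.path(out_dir, "tumor_normal.tsv")),
       nrow(tn), ncol(tn))
  st <- stage_association(gly, clinical)
  note("stage", write_tsv(st, file.path(out_dir, "stage.tsv")),
       nrow(st), ncol(st))
  ghc <- do.call(rbind, lapply(eligible, function(ct) {
    ids <- cl$sample_id[cl$cancer_type == ct & cl$sample_type == "tumor"]
    sp <- spearman(gly[ids], hyp[ids])
    sp16 <- spearman(scores[ids, "glycolysis16"], hyp[ids])
    data.frame(cancer_type = ct, rho_gly_hyp = sp$rho, p = sp$p_value,
               rho_gly16_hyp = sp16$rho, p16 = sp16$p_value, n = sp$n)
  }))
  note("hypoxia_correlation",
       write_tsv(ghc, file.path(out_dir, "hypoxia_correlation.tsv")),
       nrow(ghc), ncol(ghc))

  # --- survival per eligible type -------------------------------------
  surv_rows <- list()
  for (ct in eligible) {
    lab <- labels_list[[ct]]
    clt <- clinical[match(lab$sample_id, clinical$sample_id), ]
    tt <- stats::setNames(clt$os_time, clt$sample_id)
    ev <- stats::setNames(clt$os_event, clt$sample_id)
    kl <- tryCatch(km_logrank(lab, tt, ev), error = function(e) NULL)
    if (is.null(kl)) next
    cx <- tryCatch({
      keep <- lab$label %in% c("high", "low")
      cov <- data.frame(glycolysis_high =
                          as.integer(lab$label[keep] == "high"))
      cox_fit(cov, tt[lab$sample_id[keep]], ev[lab$sample_id[keep]])
    }, error = function(e) NULL)
    surv_rows[[ct]] <- data.frame(
      cancer_type = ct, logrank_chisq = kl$chisq, logrank_p = kl$p_value,
      cox_hr = if (!is.null(cx)) cx$hr[1] else NA_real_,
      cox_p = if (!is.null(cx)) cx$p_value[1] else NA_real_,
      status = kl$status, stringsAsFactors = FALSE)
  }
  surv <- do.call(rbind, surv_rows)
  if (!is.null(surv))
    note("survival", write_tsv(surv, file.path(out_dir, "survival.tsv")),
         nrow(surv), ncol(surv))

  # --- genomic association --------------------------------------------
  if (!is.null(config$cna)) {
    cna <- read_matrix(config$cna, "cna")
    calls <- do.call(rbind, lapply(eligible, function(ct) {
      ids <- intersect(cl$sample_id[cl$cancer_type == ct &
                                      cl$sample_type == "tumor"],
                       colnames(cna))
      cbind(cancer_type = ct, call_gain_loss(cna, ids))
    }))
    note("gain_loss", write_tsv(calls, file.path(out_dir, "gain_loss.tsv")),
         nrow(calls), ncol(calls))
    assoc <- cna_association(gly, cna, clinical)
    note("assoc_cna", write_tsv(assoc, file.path(out_dir, "assoc_cna.tsv")),
         nrow(assoc), ncol(assoc))
    if (!is.null(config$drivers)) {
      dassoc <- cna_association(gly, cna, clinical,
                                direction_map = config$drivers)
      pano <- driver_panorama(dassoc, config$drivers)
      note("drivers", write_tsv(pano, file.path(out_dir, "drivers.tsv")),
           nrow(pano), ncol(pano))
    }
  }
  if (!is.null(config$mutations)) {
    mut <- read_mutations(config$mutations)
    sassoc <- snv_association(gly, mut, clinical)
    note("assoc_snv", write_tsv(sassoc, file.path(out_dir, "assoc_snv.tsv")),
         nrow(sassoc), ncol(sassoc))
    bp <- burden_and_ploidy(gly, mut, clinical, q = config$q)
    note("burden", write_tsv(bp, file.path(out_dir, "burden.tsv")),
         nrow(bp), ncol(bp))
  }

  # --- transcriptome screens ------------------------------------------
  de_list <- list(); enrich_list <- list()
  expr_by_ct <- list(); gly_by_ct <- list()
  for (ct in eligible) {
    lab <- labels_list[[ct]]
    ids <- lab$sample_id
    expr_ct <- expr[, ids, drop = FALSE]
    expr_by_ct[[ct]] <- expr_ct
    gly_by_ct[[ct]] <- gly[ids]
    enrich_list[[ct]] <- diff_signature_enrichment(
      scores[ids, , drop = FALSE], lab, cancer_type = ct)
    de_list[[ct]] <- de_genes(expr_ct, lab, cancer_type = ct,
                              fc_threshold = config$fc_threshold,
                              alpha = config$alpha)
  }
  enrich <- do.call(rbind, enrich_list)
  rownames(enrich) <- NULL
  note("diff_enrich", write_tsv(enrich, file.path(out_dir, "diff_enrich.tsv")),
       nrow(enrich), ncol(enrich))
  de_all <- do.call(rbind, de_list)
  rownames(de_all) <- NULL
  note("de", write_tsv(de_all, file.path(out_dir, "de.tsv")),
       nrow(de_all), ncol(de_all))
  k_eff <- min(config$k_recurrence, length(de_list))
  rec <- recurrent_genes(de_list, k = k_eff)
  note("recurrent", write_tsv(rec, file.path(out_dir, "recurrent.tsv")),
       nrow(rec), ncol(rec))
  cand <- utils::head(rec$gene_id, 50)
  if (length(cand)) {
    cr <- candidate_rank(expr_by_ct, gly_by_ct, cand)
    note("candidates", write_tsv(cr, file.path(out_dir, "candidates.tsv")),
         nrow(cr), ncol(cr))
  }
  if (config$quadrant_gene %in% rownames(expr)) {
    qrows <- do.call(rbind, lapply(eligible, function(ct) {
      ids <- labels_list[[ct]]$sample_id
      qs <- quadrant_stratify(hyp[ids], expr[, ids, drop = FALSE],
                              config$quadrant_gene,
                              targets = list(glycolysis_score = gly[ids]))
      cbind(cancer_type = ct, qs$summary)
    }))
    note("quadrant", write_tsv(qrows, file.path(out_dir, "quadrant.tsv")),
         nrow(qrows), ncol(qrows))
  }

  # --- single-cell branch ---------------------------------------------
  if (!is.null(config$mtx)) {
    cells <- read_cells(config$mtx, config$genes, config$cell_meta)
    qc <- qc_filter(cells)
    norm <- normalize_cells(qc$cells)
    sc <- score_cells(norm, qc$cells$cell_meta)
    note("sc_scores", write_tsv(sc$table, file.path(out_dir, "cell_scores.tsv")),
         nrow(sc$table), ncol(sc$table))
    ra <- region_compare(sc$table)
    note("sc_region", write_tsv(ra, file.path(out_dir, "region_anova.tsv")),
         nrow(ra), ncol(ra))
  }

  man <- do.call(rbind, manifest)
  params <- data.frame(stage = "config", file = "",
                       rows = NA_integer_, cols = NA_integer_)
  man <- rbind(man, params)
  man$params <- ""
  man$params[man$stage == "config"] <- paste(
    sprintf("q=%s;min_group=%d;min_normals=%d;fc=%s;alpha=%s;k=%d;seed=%d",
            format(config$q), config$min_group, config$min_normals,
            format(config$fc_threshold), format(config$alpha),
            k_eff, as.integer(config$seed)))
  write_tsv(man, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = man, scores = scores, labels = labels_all,
                 eligible = eligible))
}
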