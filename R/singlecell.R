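# Single-cell branch: QC filtering, depth normalization, per-cell
# signature scoring, spatial-region comparison and top-30% overlay flags.

#' Single-cell QC thresholds
#'
#' Defaults: cells with fewer than 200 total counts, fewer than 200 or
#' more than 6000 expressed genes, or more than 10% mitochondrial counts
#' (genes with the `MT-` symbol prefix) are removed.
#'
#' @param min_counts minimum total RNA counts per cell.
#' @param min_genes,max_genes bounds on the number of expressed genes.
#' @param max_mito_fraction maximum mitochondrial count fraction.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_counts = 200, min_genes = 200,
                          max_genes = 6000, max_mito_fraction = 0.10,
                          mito_prefix = "MT-") {
  stopifnot(min_genes < max_genes,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_counts = min_counts, min_genes = min_genes,
                 max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter cells on QC thresholds
#'
#' Removes cells violating any rule of [qc_thresholds()] and reports, per
#' cell, which rules it failed. Filtering is idempotent: per-cell
#' statistics depend only on the cell's own counts.
#'
#' @param cells `cell_matrix` object.
#' @param thresholds [qc_thresholds()].
#' @return list: `cells` (filtered `cell_matrix`), `report` (data.frame
#'   cell_id, total_counts, n_genes, mito_fraction, pass, failed_rules).
#' @export
qc_filter <- function(cells, thresholds = qc_thresholds()) {
  counts <- cells$counts
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thresholds$mito_prefix)
  mito_counts <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  mito_frac <- ifelse(total > 0, mito_counts / total, 1)
  fails <- cbind(
    low_counts = total < thresholds$min_counts,
    few_genes = n_genes < thresholds$min_genes,
    many_genes = n_genes > thresholds$max_genes,
    high_mito = mito_frac > thresholds$max_mito_fraction)
  pass <- rowSums(fails) == 0
  failed_rules <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  report <- data.frame(cell_id = cells$cell_meta$cell_id,
                       total_counts = as.numeric(total),
                       n_genes = as.integer(n_genes),
                       mito_fraction = as.numeric(mito_frac),
                       pass = unname(pass),
                       failed_rules = unname(failed_rules),
                       stringsAsFactors = FALSE)
  if (!any(pass)) {
    tally <- colSums(fails)
    stop_fmt("no cells survive QC (removed: %s)",
             paste(sprintf("%s=%d", names(tally), tally), collapse = ", "))
  }
  out <- cell_matrix(counts[, pass, drop = FALSE],
                     cells$cell_meta[pass, , drop = FALSE])
  list(cells = out, report = report)
}

#' Depth-normalize single-cell counts
#'
#' Counts-per-10k log transform: log2(1 + 1e4 * count / total) per cell.
#' The downstream scoring engine is rank-based per gene, so the result is
#' invariant to each cell's sequencing depth.
#'
#' @param cells post-QC `cell_matrix`.
#' @return dense genes x cells numeric matrix (cells take the role of
#'   samples for scoring).
#' @export
normalize_cells <- function(cells) {
  total <- Matrix::colSums(cells$counts)
  if (any(total == 0)) stop_fmt("zero-total cell; run qc_filter first")
  m <- as.matrix(cells$counts)
  norm <- log2(1 + sweep(m, 2, 1e4 / total, `*`))
  dimnames(norm) <- dimnames(cells$counts)
  norm
}

top_fraction_flags <- function(values, ids, frac = 0.30) {
  k <- floor(frac * length(values))
  if (k == 0) return(stats::setNames(rep(FALSE, length(ids)), ids))
  o <- order(values, ids)
  flagged <- ids[o[seq.int(length(ids) - k + 1, length(ids))]]
  stats::setNames(ids %in% flagged, ids)
}

#' Score signatures per cell
#'
#' Runs the enrichment engine with cells as samples, reports the
#' cell-level Spearman correlation between the glycolysis and hypoxia
#' scores, and flags the top 30% of cells per score and per requested
#' gene's normalized expression (exactly floor(0.3 * n) cells; ties
#' resolved by (value, cell_id) order).
#'
#' @param norm normalized genes x cells matrix from [normalize_cells()].
#' @param cell_meta data.frame with `cell_id`, `patient_id`, `region`.
#' @param sets named list of gene sets; must contain `glycolysis` and
#'   `hypoxia` entries (defaults to the built-in signatures).
#' @param overlay_genes genes whose expression also gets top-30% flags
#'   (absent genes are skipped).
#' @param params [gsva_params()].
#' @return list: `table` (per-cell scores, metadata and overlay flags),
#'   `correlation` (Spearman rho/p between the two scores).
#' @export
score_cells <- function(norm, cell_meta,
                        sets = list(glycolysis = builtin_signature("glycolysis22"),
                                    hypoxia = builtin_signature("hypoxia14")),
                        overlay_genes = c("P4HA1", "HSPA8"),
                        params = gsva_params()) {
  if (ncol(norm) < 2) stop_fmt("score_cells needs >= 2 cells")
  if (!all(c("glycolysis", "hypoxia") %in% names(sets)))
    stop_fmt("sets must contain 'glycolysis' and 'hypoxia'")
  scores <- score_matrix(norm, sets, params)
  ids <- rownames(scores)
  meta <- cell_meta[match(ids, cell_meta$cell_id), ]
  tab <- data.frame(cell_id = ids, patient_id = meta$patient_id,
                    region = meta$region,
                    glycolysis_score = scores[, "glycolysis"],
                    hypoxia_score = scores[, "hypoxia"],
                    top30_glycolysis = top_fraction_flags(
                      scores[, "glycolysis"], ids),
                    top30_hypoxia = top_fraction_flags(
                      scores[, "hypoxia"], ids),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (g in intersect(overlay_genes, rownames(norm)))
    tab[[paste0("top30_", g)]] <- top_fraction_flags(norm[g, ids], ids)
  cor_gh <- spearman(tab$glycolysis_score, tab$hypoxia_score)
  list(table = tab, correlation = cor_gh)
}

#' Compare scores across tumor regions per patient
#'
#' One-way ANOVA of each score across the core / edge / middle regions,
#' run per patient; patients with fewer than 2 regions carrying at least
#' 2 cells are skipped. Significance stars: * <0.05, ** <0.01,
#' *** <0.001, **** <0.0001.
#'
#' @param cell_table per-cell table from [score_cells()].
#' @param score_cols columns to test.
#' @return data.frame: patient_id, score, per-region means, F statistic,
#'   p_value, stars, status.
#' @export
region_compare <- function(cell_table,
                           score_cols = c("glycolysis_score", "hypoxia_score")) {
  stars <- function(p) {
    if (is.na(p)) "" else if (p < 1e-4) "****" else if (p < 1e-3) "***"
    else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }
  rows <- list()
  for (pt in sort(unique(cell_table$patient_id))) {
    sub <- cell_table[cell_table$patient_id == pt, ]
    for (sc in score_cols) {
      groups <- split(sub[[sc]], sub$region)
      groups <- groups[lengths(groups) >= 2]
      means <- vapply(CELL_REGIONS, function(r) {
        v <- sub[[sc]][sub$region == r]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      rows[[length(rows) + 1]] <- if (length(groups) >= 2) {
        kt <- k_sample_test(groups, "anova")
        data.frame(patient_id = pt, score = sc,
                   mean_core = means["core"], mean_edge = means["edge"],
                   mean_middle = means["middle"],
                   statistic = kt$statistic, p_value = kt$p_value,
                   stars = stars(kt$p_value), status = "ok",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(patient_id = pt, score = sc,
                   mean_core = means["core"], mean_edge = means["edge"],
                   mean_middle = means["middle"],
                   statistic = NA_real_, p_value = NA_real_, stars = "",
                   status = "skipped: fewer than 2 regions with >= 2 cells",
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
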