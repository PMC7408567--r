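# Single-sample gene-set variation scoring, implemented from scratch:
# per-gene kernel CDF estimation -> per-sample symmetric rank statistic ->
# weighted Kolmogorov-Smirnov random walk. The hot loops live in src/.

#' Scoring engine parameters
#'
#' @param kernel `"gaussian"` (kernel-smoothed CDF, the default for
#'   log-scale expression) or `"none"` (plain empirical CDF; exactly
#'   invariant under per-gene monotone transforms).
#' @param bandwidth_factor per-gene bandwidth as a multiple of the
#'   across-sample standard deviation; the conventional value for
#'   log-transformed expression is 1/4.
#' @param tau weight exponent on the rank statistic in the walk.
#' @param statistic enrichment summary; `"max_diff"` (difference between
#'   the maximal positive and maximal absolute negative running deviation)
#'   is the only supported choice and bounds scores in \[-1, 1\].
#' @return list of class `gsva_params`.
#' @export
gsva_params <- function(kernel = c("gaussian", "none"),
                        bandwidth_factor = 0.25, tau = 1,
                        statistic = "max_diff") {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth_factor > 0, tau > 0, statistic == "max_diff")
  structure(list(kernel = kernel, bandwidth_factor = bandwidth_factor,
                 tau = tau, statistic = statistic),
            class = "gsva_params")
}

#' Kernel-smoothed empirical CDF of each gene
#'
#' Entry (i, j) is the estimated cumulative distribution of gene i
#' evaluated at sample j's expression value: the mean over samples k of
#' Phi((x_ij - x_ik) / h_i) for the Gaussian kernel with per-gene
#' bandwidth h_i = SD_i * bandwidth_factor, or the plain empirical CDF for
#' `kernel = "none"`. Genes with zero variance get a floored bandwidth
#' (1e-8) so constant rows degenerate to ties instead of NaN.
#'
#' @param expr genes x samples numeric matrix (log2(TPM+1) scale).
#' @param params [gsva_params()].
#' @return genes x samples matrix of CDF values in (0, 1].
#' @export
kernel_cdf <- function(expr, params = gsva_params()) {
  validate_expression_matrix(expr)
  if (ncol(expr) < 2) stop_fmt("kernel_cdf requires at least 2 samples")
  if (params$kernel == "none") {
    z <- t(apply(expr, 1, function(v) {
      vapply(v, function(x) mean(v <= x), numeric(1))
    }))
    dimnames(z) <- dimnames(expr)
    return(z)
  }
  h <- pmax(apply(expr, 1, stats::sd) * params$bandwidth_factor, 1e-8)
  z <- .kcdf_gauss(expr, h)
  dimnames(z) <- dimnames(expr)
  z
}

#' Per-sample gene ranking and symmetric rank statistic
#'
#' Genes are ranked within each sample by decreasing CDF value (rank 1 =
#' highest), ties broken by input gene order. The symmetric statistic
#' r_ij = |p/2 - rank_ij| gives mid-ranked genes weight near zero and
#' genes at either extreme large weight.
#'
#' @param cdf genes x samples matrix from [kernel_cdf()].
#' @return list with `rank` (integer matrix), `stat` (numeric matrix) and
#'   `order` (integer matrix: `order[l, j]` is the row index of the gene
#'   at walk position l in sample j).
#' @export
rank_statistic <- function(cdf) {
  p <- nrow(cdf)
  n <- ncol(cdf)
  ord <- matrix(0L, p, n)
  rnk <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    o <- order(-cdf[, j], seq_len(p))  # stable: ties by input gene order
    ord[, j] <- o
    rnk[o, j] <- seq_len(p)
  }
  list(rank = rnk, stat = abs(p / 2 - rnk), order = ord)
}

#' Weighted random-walk enrichment score for one sample
#'
#' Walks genes from the top of the per-sample ranking: in-set genes add
#' |r|^tau normalized by the in-set total, out-of-set genes subtract
#' 1/(p - k). The score is the maximal positive running deviation minus
#' the maximal absolute negative one, so it lies in \[-1, 1\].
#'
#' @param ord integer vector, gene indices in walk order (rank 1 first).
#' @param rstat numeric vector of rank-statistic values per gene.
#' @param set_mask logical vector, gene-set membership per gene.
#' @param tau weight exponent.
#' @return numeric score in \[-1, 1\].
#' @export
enrichment_walk <- function(ord, rstat, set_mask, tau = 1) {
  p <- length(ord)
  k <- sum(set_mask)
  if (k == 0) stop_fmt("gene set has no overlap with the matrix genes")
  if (k == p) stop_fmt("gene set covers all matrix genes; no background")
  drop(.walk_scores(matrix(as.integer(ord), ncol = 1),
                    matrix(rstat, ncol = 1),
                    matrix(set_mask, ncol = 1), tau))
}

#' Score gene sets per sample
#'
#' Composes [kernel_cdf()], [rank_statistic()] and the enrichment walk for
#' every sample and gene set. Signature genes absent from the matrix are
#' dropped with a warning; scoring proceeds while at least one gene
#' remains (and not all matrix genes are in the set).
#'
#' @param expr genes x samples numeric matrix, log2(TPM+1).
#' @param sets named list of character vectors (gene sets).
#' @param params [gsva_params()].
#' @return samples x signatures numeric matrix of scores in \[-1, 1\],
#'   with attribute `n_genes_used`: per-set count of signature genes found
#'   in the matrix.
#' @export
score_matrix <- function(expr, sets, params = gsva_params()) {
  validate_expression_matrix(expr)
  if (!length(sets) || is.null(names(sets)))
    stop_fmt("sets must be a non-empty named list")
  p <- nrow(expr)
  genes <- rownames(expr)
  mask <- matrix(FALSE, p, length(sets),
                 dimnames = list(genes, names(sets)))
  used <- integer(length(sets))
  names(used) <- names(sets)
  for (s in names(sets)) {
    present <- sets[[s]] %in% genes
    if (!all(present))
      warning(sprintf("set '%s': %d of %d genes absent from matrix", s,
                      sum(!present), length(present)), call. = FALSE)
    inset <- intersect(sets[[s]], genes)
    if (length(inset) == 0)
      stop_fmt("set '%s' shares no genes with the expression matrix", s)
    if (length(inset) == p)
      stop_fmt("set '%s' covers every matrix gene; no background", s)
    mask[inset, s] <- TRUE
    used[s] <- length(inset)
  }
  z <- kernel_cdf(expr, params)
  rs <- rank_statistic(z)
  scores <- .walk_scores(rs$order, rs$stat, mask, params$tau)
  dimnames(scores) <- list(colnames(expr), names(sets))
  attr(scores, "n_genes_used") <- used
  scores
}
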