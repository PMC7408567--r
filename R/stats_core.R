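# Statistical primitives shared by every pipeline stage. Thin, validated
# wrappers around the standard R tests so behavior is centralized, plus a
# vectorized Welch path for genome-wide association scans.

test_result <- function(statistic, p_value, n, direction, note = NA_character_) {
  list(statistic = unname(statistic), p_value = unname(min(max(p_value, 0), 1)),
       n = n, direction = direction, note = note)
}

direction_of <- function(delta, tol = 0) {
  if (is.na(delta) || abs(delta) <= tol) "0" else if (delta > 0) "+" else "-"
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p-value uses the t approximation t = rho * sqrt((n-2)/(1-rho^2))
#' with n-2 df, two-sided. Pairs with missing values are dropped
#' (pairwise-complete). If either ranked vector has zero variance the
#' result is an explicit NA, not 0.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_fmt("spearman needs >= 3 complete pairs (got %d)", n)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved. NA entries stay NA
#' and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample location test
#'
#' `welch_t`: unequal-variance t test with Welch-Satterthwaite df.
#' `rank_sum`: Wilcoxon rank-sum; exact enumeration when both arms have
#' <= 10 observations and no ties, otherwise the normal approximation with
#' tie and continuity correction. Degenerate inputs (both arms constant
#' and equal) return p = 1 with a note rather than an error.
#'
#' @param a,b numeric vectors.
#' @param method `"welch_t"` or `"rank_sum"`.
#' @return `test_result` list: statistic, p_value, n (per arm), direction
#'   (sign of mean difference a - b), note.
#' @export
two_sample_test <- function(a, b, method = c("welch_t", "rank_sum")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n <- c(length(a), length(b))
  delta <- mean(a) - mean(b)
  if (method == "welch_t") {
    if (any(n < 2)) stop_fmt("welch_t needs >= 2 observations per arm")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (delta == 0)
        return(test_result(0, 1, n, "0", "zero variance in both arms"))
      return(test_result(sign(delta) * Inf, 0, n, direction_of(delta),
                         "zero variance in both arms"))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    return(test_result(ht$statistic, ht$p.value, n, direction_of(delta)))
  }
  if (any(n < 1)) stop_fmt("rank_sum needs >= 1 observation per arm")
  exact <- all(n <= 10) && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  med_delta <- stats::median(a) - stats::median(b)
  test_result(ht$statistic, ht$p.value, n, direction_of(med_delta))
}

#' k-sample location test
#'
#' `anova`: classical one-way F test with (k-1, N-k) df. `kruskal_wallis`:
#' rank-based H statistic with tie correction against chi-square(k-1).
#' If every observation is identical the F statistic is undefined and
#' p = 1 is returned with a note.
#'
#' @param groups list of numeric vectors, each nonempty.
#' @param method `"anova"` or `"kruskal_wallis"`.
#' @return `test_result` list; `n` is the per-group size vector.
#' @export
k_sample_test <- function(groups, method = c("anova", "kruskal_wallis")) {
  method <- match.arg(method)
  if (length(groups) < 2) stop_fmt("k_sample_test needs >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop_fmt("k_sample_test: empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (stats::sd(values) == 0)
    return(test_result(NA_real_, 1, sizes, "0", "all observations identical"))
  if (method == "anova") {
    if (length(values) - length(groups) < 1)
      stop_fmt("anova needs residual degrees of freedom")
    ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
    return(test_result(ht$statistic, ht$p.value, sizes, NA_character_))
  }
  ht <- stats::kruskal.test(values, g)
  test_result(ht$statistic, ht$p.value, sizes, NA_character_)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the observed overlap
#' between a hit list and a pathway, drawing |hits| genes from the
#' universe. A pathway is reported as enriched only when overlap >=
#' `min_overlap` and p < `alpha` (both configurable).
#'
#' @param hits character vector of selected genes (subset of universe).
#' @param pathway character vector of pathway genes (intersected with the
#'   universe before testing).
#' @param universe character vector of all testable genes.
#' @param min_overlap minimum overlap for the enriched flag.
#' @param alpha p-value threshold for the enriched flag.
#' @return list: `p_value`, `overlap`, `enriched`, `n_pathway`, `n_hits`,
#'   `n_universe`.
#' @export
ora_test <- function(hits, pathway, universe, min_overlap = 3, alpha = 0.01) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_fmt("empty universe")
  hits <- intersect(unique(hits), universe)
  pathway <- intersect(unique(pathway), universe)
  ov <- length(intersect(hits, pathway))
  # P(X >= ov), X ~ Hypergeom(universe, pathway, draws = hits)
  p <- stats::phyper(ov - 1, length(pathway),
                     length(universe) - length(pathway),
                     length(hits), lower.tail = FALSE)
  list(p_value = p, overlap = ov,
       enriched = (ov >= min_overlap && p < alpha),
       n_pathway = length(pathway), n_hits = length(hits),
       n_universe = length(universe))
}

# Vectorized Welch t over rows defined by per-row group masks.
# alt_mask/ref_mask: genes x samples logical matrices; scores: length-n
# numeric. Returns data.frame with per-row delta, t, p, n_alt, n_ref.
# Used by the genome-wide association scans; agrees with two_sample_test.
welch_t_rows <- function(scores, alt_mask, ref_mask) {
  storage.mode(alt_mask) <- "double"
  storage.mode(ref_mask) <- "double"
  s <- as.numeric(scores)
  n1 <- drop(alt_mask %*% rep(1, length(s)))
  n2 <- drop(ref_mask %*% rep(1, length(s)))
  s1 <- drop(alt_mask %*% s);  s2 <- drop(ref_mask %*% s)
  q1 <- drop(alt_mask %*% s^2); q2 <- drop(ref_mask %*% s^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.na(p) & (m1 == m2)] <- 1  # zero variance, equal means
  data.frame(delta = m1 - m2, statistic = tstat, p_value = p,
             n_alt = n1, n_ref = n2)
}
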