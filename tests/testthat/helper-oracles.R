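# Independent reference implementations used as oracles. Deliberately
# naive (explicit double loops) and written without reference to the
# package internals they check.

oracle_kcdf <- function(x, bw_factor = 0.25, kernel = "gaussian") {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- max(sd(x[i, ]) * bw_factor, 1e-8)
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        acc <- acc + if (kernel == "gaussian")
          pnorm((x[i, j] - x[i, k]) / h) else as.numeric(x[i, k] <= x[i, j])
      }
      z[i, j] <- acc / n
    }
  }
  dimnames(z) <- dimnames(x)
  z
}

oracle_rank_stat <- function(z) {
  p <- nrow(z); n <- ncol(z)
  rnk <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    o <- order(-z[, j], seq_len(p))
    for (l in seq_len(p)) rnk[o[l], j] <- l
  }
  list(rank = rnk, stat = abs(p / 2 - rnk))
}

oracle_walk <- function(ord, rstat, inset, tau = 1) {
  p <- length(ord)
  k <- sum(inset)
  tot <- sum(abs(rstat[ord][inset[ord]])^tau)
  dev <- 0; mpos <- 0; mneg <- 0
  for (l in seq_len(p)) {
    g <- ord[l]
    if (inset[g]) {
      dev <- dev + if (tot > 0) abs(rstat[g])^tau / tot else 0
    } else {
      dev <- dev - 1 / (p - k)
    }
    mpos <- max(mpos, dev)
    mneg <- max(mneg, -dev)
  }
  mpos - mneg
}

# monolithic brute-force scorer, independent of the engine's composition
oracle_score <- function(x, sets, bw_factor = 0.25, tau = 1,
                         kernel = "gaussian") {
  z <- oracle_kcdf(x, bw_factor, kernel)
  rs <- oracle_rank_stat(z)
  p <- nrow(x); n <- ncol(x)
  out <- matrix(0, n, length(sets),
                dimnames = list(colnames(x), names(sets)))
  for (s in seq_along(sets)) {
    inset <- rownames(x) %in% sets[[s]]
    for (j in seq_len(n)) {
      o <- order(-z[, j], seq_len(p))
      out[j, s] <- oracle_walk(o, rs$stat[, j], inset, tau)
    }
  }
  out
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, sorted[i] * m / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_welch <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a); v2 <- var(b)
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# two-group log-rank via the observed-minus-expected tableau
oracle_logrank <- function(time, event, group) {
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (d in tt) {
    at_risk <- time >= d
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    dtot <- sum(time == d & event == 1)
    d1 <- sum(time == d & event == 1 & group == 1)
    e1 <- dtot * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + dtot * (n1 / n) * (1 - n1 / n) * (n - dtot) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

random_expr <- function(p, n, seed = NULL, prefix = "G") {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * n, 6), p, n,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                         sprintf("S%03d", seq_len(n))))
}
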