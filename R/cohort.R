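# Score-based stratification and clinical analyses. Survival machinery
# (Kaplan-Meier, log-rank, Cox partial likelihood) is delegated to the
# survival package, the standard tool for these fits.

#' Stratify samples into score-high / score-low / mid groups
#'
#' The top floor(q*n) samples by score are labeled `high`, the bottom
#' floor(q*n) `low`, the remainder `mid`. Ties at either boundary are
#' resolved deterministically by (score, sample_id) lexicographic order.
#' A cohort whose group size floor(q*n) falls below `min_group` is flagged
#' ineligible for downstream per-cancer analyses.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param q quantile fraction in (0, 0.5\]; default 0.30.
#' @param min_group minimum eligible group size; default 30.
#' @return data.frame (`sample_id`, `score`, `label`) with attributes
#'   `q`, `k` (group size) and `eligible`.
#' @export
classify_by_score <- function(scores, q = 0.30, min_group = 30) {
  if (length(scores) == 0) stop_fmt("no samples to classify")
  if (is.null(names(scores))) stop_fmt("scores must be named by sample id")
  if (!all(is.finite(scores))) stop_fmt("scores must be finite")
  if (q <= 0 || q > 0.5) stop_fmt("q must lie in (0, 0.5]")
  n <- length(scores)
  k <- floor(q * n)
  o <- order(scores, names(scores))  # ascending; ties by sample id
  label <- rep("mid", n)
  if (k > 0) {
    label[o[seq_len(k)]] <- "low"
    label[o[seq.int(n - k + 1, n)]] <- "high"
  }
  out <- data.frame(sample_id = names(scores), score = unname(scores),
                    label = factor(label, levels = c("low", "mid", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  attr(out, "k") <- k
  attr(out, "eligible") <- k >= min_group
  out
}

scores_by_type <- function(scores, clinical, sample_type = "tumor") {
  cl <- clinical[clinical$sample_id %in% names(scores), ]
  split(cl[cl$sample_type == sample_type, "sample_id"],
        cl[cl$sample_type == sample_type, "cancer_type"])
}

#' Tumor-versus-normal score comparison per cancer type
#'
#' Wilcoxon rank-sum test of tumor against normal scores, run only for
#' cancer types with at least `min_normals` scored normal samples (the
#' others are reported with status `skipped`).
#'
#' @param scores named numeric vector of per-sample signature scores.
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param min_normals minimum normal-sample count; default 30.
#' @return data.frame with one row per cancer type: n_tumor, n_normal,
#'   statistic, p_value, direction (tumor relative to normal), status.
#' @export
tumor_normal_compare <- function(scores, clinical, min_normals = 30) {
  cl <- clinical[clinical$sample_id %in% names(scores), ]
  types <- sort(unique(cl$cancer_type))
  rows <- lapply(types, function(ct) {
    sub <- cl[cl$cancer_type == ct, ]
    tum <- scores[sub$sample_id[sub$sample_type == "tumor"]]
    nor <- scores[sub$sample_id[sub$sample_type == "normal"]]
    if (length(nor) < min_normals)
      return(data.frame(cancer_type = ct, n_tumor = length(tum),
                        n_normal = length(nor), statistic = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        status = sprintf("skipped: %d normals < %d",
                                         length(nor), min_normals)))
    tr <- two_sample_test(tum, nor, "rank_sum")
    data.frame(cancer_type = ct, n_tumor = length(tum),
               n_normal = length(nor), statistic = tr$statistic,
               p_value = tr$p_value, direction = tr$direction,
               status = "ok")
  })
  do.call(rbind, rows)
}

#' Stage IV versus stage I score comparison per cancer type
#'
#' Welch t test of scores between stage IV and stage I tumors; stages II
#' and III are not part of the contrast. Cancer types missing either
#' stage (or with fewer than 2 samples in one) are skipped.
#'
#' @param scores named numeric vector.
#' @param clinical clinical data.frame.
#' @return data.frame, one row per cancer type.
#' @export
stage_association <- function(scores, clinical) {
  cl <- clinical[clinical$sample_id %in% names(scores) &
                   clinical$sample_type == "tumor" & !is.na(clinical$stage), ]
  types <- sort(unique(cl$cancer_type))
  rows <- lapply(types, function(ct) {
    sub <- cl[cl$cancer_type == ct, ]
    s1 <- scores[sub$sample_id[sub$stage == "I"]]
    s4 <- scores[sub$sample_id[sub$stage == "IV"]]
    if (length(s1) < 2 || length(s4) < 2)
      return(data.frame(cancer_type = ct, n_stage_iv = length(s4),
                        n_stage_i = length(s1), statistic = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        status = "skipped: a stage arm below 2 samples"))
    tr <- two_sample_test(s4, s1, "welch_t")
    data.frame(cancer_type = ct, n_stage_iv = length(s4),
               n_stage_i = length(s1), statistic = tr$statistic,
               p_value = tr$p_value, direction = tr$direction,
               status = "ok")
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per group and the two-sided log-rank
#' chi-square (1 df). Groups with zero events make the log-rank test
#' undefined; the fit is returned with status `no-events`.
#'
#' @param labels data.frame from [classify_by_score()], restricted to the
#'   `high` and `low` groups (mid samples are dropped here).
#' @param times numeric vector of follow-up times (days), named by sample.
#' @param events 0/1 event indicators, named by sample.
#' @return list: `km` (data.frame group/time/surv/n_risk/n_event),
#'   `chisq`, `df`, `p_value`, `n`, `status`.
#' @export
km_logrank <- function(labels, times, events) {
  keep <- labels$label %in% c("high", "low")
  ids <- labels$sample_id[keep]
  ids <- ids[ids %in% names(times) & ids %in% names(events)]
  grp <- factor(as.character(labels$label[match(ids, labels$sample_id)]),
                levels = c("low", "high"))
  tt <- as.numeric(times[ids]); ev <- as.numeric(events[ids])
  ok <- is.finite(tt) & !is.na(ev)
  tt <- tt[ok]; ev <- ev[ok]; grp <- droplevels(grp[ok])
  if (nlevels(grp) < 2) stop_fmt("km_logrank needs both high and low groups")
  sf <- survival::survfit(survival::Surv(tt, ev) ~ grp)
  strata_names <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  km <- data.frame(group = strata_names, time = sf$time, surv = sf$surv,
                   n_risk = sf$n.risk, n_event = sf$n.event)
  ev_per_group <- tapply(ev, grp, sum)
  if (any(ev_per_group == 0))
    return(list(km = km, chisq = NA_real_, df = 1L, p_value = NA_real_,
                n = table(grp), status = "no-events: log-rank skipped"))
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  list(km = km, chisq = unname(sd$chisq), df = length(sd$n) - 1L,
       p_value = stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE),
       n = table(grp), status = "ok")
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling. Reports, per
#' covariate, the coefficient, hazard ratio, 95% confidence interval from
#' the observed information, and the Wald p-value. Singular designs or
#' non-convergence produce an explicit error, never silent zeros.
#'
#' @param covariates data.frame (rows = samples) of numeric or factor
#'   covariates.
#' @param times numeric follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame, one row per model term: coef, hr, lower95,
#'   upper95, se, p_value; attribute `n` and `n_events`.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times) || length(times) != length(events))
    stop_fmt("covariates, times and events must have matching lengths")
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const))
    stop_fmt("constant covariate(s): %s",
             paste(names(covariates)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow",
                         control = survival::coxph.control(iter.max = 50,
                                                           eps = 1e-9))
  if (anyNA(stats::coef(fit)))
    stop_fmt("singular design: coefficient(s) not estimable (%s)",
             paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                   collapse = ", "))
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    se = sm$coefficients[, "se(coef)"],
                    lower95 = sm$conf.int[, "lower .95"],
                    upper95 = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- sm$n
  attr(out, "n_events") <- sm$nevent
  out
}
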