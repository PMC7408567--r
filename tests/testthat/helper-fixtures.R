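make_scores <- function(n, seed = 1) {
  set.seed(seed)
  setNames(rnorm(n), sprintf("S%04d", seq_len(n)))
}

make_clinical <- function(n_tumor, n_normal, ct = "CT01", seed = 2) {
  set.seed(seed)
  n <- n_tumor + n_normal
  data.frame(
    sample_id = sprintf("%s_S%04d", ct, 1:n), cancer_type = ct,
    sample_type = c(rep("tumor", n_tumor), rep("normal", n_normal)),
    stage = c(sample(c("I", "II", "III", "IV"), n_tumor, TRUE),
              rep(NA, n_normal)),
    os_time = round(rexp(n, 1 / 500), 1), os_event = rbinom(n, 1, 0.6),
    aneuploidy_score = rpois(n, 8), genome_doublings = sample(0:2, n, TRUE),
    stringsAsFactors = FALSE)
}
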