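# Latent-variable multi-omics simulator. Generates cohorts and single-cell
# datasets with the statistical structure the analysis assumes (correlated
# glycolysis/hypoxia programs, planted driver effects, score-linked
# survival), together with the ground truth needed for recovery tests.

#' Simulation configuration
#'
#' Defaults describe a compact cohort that still triggers every
#' eligibility rule of the pipeline: 4 cancer types with 300 tumors and
#' 50 normals each, a 300-gene universe containing the built-in
#' signatures, latent glycolysis-hypoxia correlation 0.8, signature
#' loading 1 log2 unit per latent SD, and planted gain / loss / mutation
#' drivers shifting the glycolysis latent of carriers.
#'
#' @param n_cancer_types number of synthetic cancer types.
#' @param n_tumor,n_normal samples per type.
#' @param n_genes total gene universe (signature genes included).
#' @param rho latent glycolysis-hypoxia correlation, |rho| <= 1.
#' @param sig_effect loading of the latent on its signature genes
#'   (log2 units per latent SD).
#' @param tumor_shift mean of the tumor latent relative to the normal
#'   baseline (latent-SD units).
#' @param noise_sd residual expression noise SD (log2 units).
#' @param driver_spec data.frame with columns `gene`, `alteration`
#'   (gain / loss / mutation), `carrier_fraction`, `score_shift` (latent
#'   shift for carriers).
#' @param background_alt_rate per-gene background rate of incidental
#'   gains and of losses in the CNA matrix.
#' @param background_mut_rate per-gene-sample background nonsynonymous
#'   mutation rate.
#' @param hazard_beta log-hazard per unit glycolysis latent.
#' @param stage_beta ordered-logit shift of tumor stage per unit latent.
#' @param aneuploidy_rho correlation of the aneuploidy latent with g.
#' @param n_patients,cells_per_patient,n_cell_genes,nb_dispersion,
#'   region_shift,cell_rho,qc_fail_fraction single-cell branch settings;
#'   `region_shift` is the hypoxia-latent elevation of core over edge
#'   (middle halfway).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cancer_types = 4, n_tumor = 300, n_normal = 50,
                       n_genes = 300, rho = 0.8, sig_effect = 1,
                       tumor_shift = 1, noise_sd = 1,
                       driver_spec = default_driver_spec(),
                       background_alt_rate = 0.05,
                       background_mut_rate = 0.01,
                       hazard_beta = log(2), stage_beta = 0.5,
                       aneuploidy_rho = 0.4,
                       n_patients = 8, cells_per_patient = 150,
                       n_cell_genes = 400, nb_dispersion = 2,
                       region_shift = 0.6, cell_rho = 0.8,
                       qc_fail_fraction = 0.05, seed = NULL) {
  if (is.null(seed)) stop_fmt("a seed is mandatory for simulation")
  stopifnot(abs(rho) <= 1, n_tumor > 0, n_genes > 40,
            qc_fail_fraction >= 0, qc_fail_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted drivers
#'
#' One oncogene gain, one tumor-suppressor loss and one mutated driver,
#' plus inert decoy drivers used to test the panorama ranking.
#' @return data.frame driver specification.
#' @export
default_driver_spec <- function() {
  data.frame(
    gene = c("DRV_GAIN1", "DRV_LOSS1", "DRV_MUT1",
             "DECOY1", "DECOY2", "DECOY3"),
    alteration = c("gain", "loss", "mutation", "gain", "loss", "gain"),
    carrier_fraction = c(0.3, 0.3, 0.2, 0.3, 0.3, 0.3),
    score_shift = c(0.4, -0.4, 0.5, 0, 0, 0),
    stringsAsFactors = FALSE)
}

rbvn <- function(n, rho) {
  # standard bivariate normal with correlation rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

sim_gene_universe <- function(cfg) {
  gly <- builtin_signature("glycolysis22")
  hyp <- builtin_signature("hypoxia14")
  sig_genes <- union(gly, hyp)
  drv <- cfg$driver_spec$gene
  n_extra <- cfg$n_genes - length(sig_genes) - length(drv)
  if (n_extra < 0) stop_fmt("n_genes too small for signatures and drivers")
  extras <- sprintf("GENE%04d", seq_len(n_extra))
  list(genes = c(sig_genes, drv, extras), gly = gly, hyp = hyp,
       overlap = overlap_genes(gly, hyp))
}

#' Simulate a multi-omics cohort
#'
#' Tumor samples draw a latent (g, h) pair from a bivariate normal with
#' correlation `rho`, shifted by `tumor_shift`; normals sit at the
#' baseline. Glycolysis-signature genes load on g, hypoxia-signature
#' genes on h, the shared genes on both; all other genes are noise except
#' planted driver targets, whose carriers get `score_shift` added to g
#' before expression is generated. Survival times are exponential with
#' hazard proportional to exp(hazard_beta * g) under independent
#' censoring; stage is an ordered split of a latent shifted by
#' stage_beta * g; the aneuploidy score discretizes a latent correlated
#' with g.
#'
#' @param config [sim_config()].
#' @return list: `expr`, `cna`, `mutations`, `clinical`, `truth` (per
#'   sample latents, carrier lists and the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  uni <- sim_gene_universe(config)
  genes <- uni$genes
  types <- sprintf("CT%02d", seq_len(config$n_cancer_types))
  n_t <- config$n_tumor; n_n <- config$n_normal
  per_type <- n_t + n_n
  n_all <- per_type * config$n_cancer_types

  sample_id <- character(n_all); cancer_type <- character(n_all)
  sample_type <- character(n_all)
  g <- numeric(n_all); h <- numeric(n_all)
  idx <- 0
  for (ct in types) {
    lat <- rbvn(n_t, config$rho) + config$tumor_shift
    rng <- idx + seq_len(per_type)
    sample_id[rng] <- sprintf("%s_S%04d", ct, seq_len(per_type))
    cancer_type[rng] <- ct
    sample_type[rng] <- c(rep("tumor", n_t), rep("normal", n_n))
    g[rng] <- c(lat[, 1], rep(0, n_n))
    h[rng] <- c(lat[, 2], rep(0, n_n))
    idx <- idx + per_type
  }
  tumor <- sample_type == "tumor"

  # planted drivers: carriers among tumors, latent shift applied to g
  carriers <- list()
  cna <- matrix(0L, length(genes), n_all,
                dimnames = list(genes, sample_id))
  mut_rows <- list()
  for (i in seq_len(nrow(config$driver_spec))) {
    d <- config$driver_spec[i, ]
    car <- rep(FALSE, n_all)
    car[tumor] <- stats::runif(sum(tumor)) < d$carrier_fraction
    carriers[[d$gene]] <- sample_id[car]
    g[car] <- g[car] + d$score_shift
    if (d$alteration == "gain") cna[d$gene, car] <- 1L
    else if (d$alteration == "loss") cna[d$gene, car] <- -1L
    else mut_rows[[d$gene]] <- data.frame(sample_id = sample_id[car],
                                          gene_id = d$gene,
                                          nonsynonymous = TRUE,
                                          stringsAsFactors = FALSE)
  }
  # incidental background alterations on non-driver genes
  bg_genes <- setdiff(genes, config$driver_spec$gene)
  r <- matrix(stats::runif(length(bg_genes) * n_all), length(bg_genes))
  bg <- matrix(0L, length(bg_genes), n_all)
  bg[r < config$background_alt_rate] <- 1L
  bg[r > 1 - config$background_alt_rate] <- -1L
  cna[bg_genes, ] <- bg

  # background mutations (plus synonymous records to exercise filtering)
  n_bg_mut <- stats::rpois(1, config$background_mut_rate *
                              length(bg_genes) * n_all)
  if (n_bg_mut > 0) {
    mut_rows[["background"]] <- data.frame(
      sample_id = sample(sample_id, n_bg_mut, replace = TRUE),
      gene_id = sample(bg_genes, n_bg_mut, replace = TRUE),
      nonsynonymous = stats::runif(n_bg_mut) < 0.7,
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, mut_rows)
  if (is.null(mutations))
    mutations <- data.frame(sample_id = character(), gene_id = character(),
                            nonsynonymous = logical())
  rownames(mutations) <- NULL

  # expression: baseline + signature loadings + noise
  baseline <- stats::rnorm(length(genes), mean = 6, sd = 1)
  expr <- matrix(stats::rnorm(length(genes) * n_all, sd = config$noise_sd),
                 length(genes), n_all,
                 dimnames = list(genes, sample_id))
  expr <- expr + baseline
  gly_only <- setdiff(uni$gly, uni$overlap)
  hyp_only <- setdiff(uni$hyp, uni$overlap)
  expr[gly_only, ] <- expr[gly_only, ] +
    config$sig_effect * matrix(g, length(gly_only), n_all, byrow = TRUE)
  expr[hyp_only, ] <- expr[hyp_only, ] +
    config$sig_effect * matrix(h, length(hyp_only), n_all, byrow = TRUE)
  expr[uni$overlap, ] <- expr[uni$overlap, ] +
    config$sig_effect * matrix((g + h) / 2, length(uni$overlap), n_all,
                               byrow = TRUE)
  expr <- pmax(expr, 0)  # log2(TPM+1) is nonnegative

  # survival: exponential hazard prop. to exp(beta * g), indep. censoring
  base_rate <- 1 / 1000  # median survival ~693 days at g = 0
  ev_time <- stats::rexp(n_all, base_rate * exp(config$hazard_beta * g))
  cens <- stats::rexp(n_all, base_rate / 2)
  os_time <- round(pmin(ev_time, cens), 1)
  os_event <- as.integer(ev_time <= cens)

  # stage: ordered split of stage_beta * g + logistic noise (tumors only)
  st_lat <- config$stage_beta * g + stats::rlogis(n_all)
  cuts <- stats::quantile(st_lat[tumor], c(0.3, 0.6, 0.85))
  stage <- cut(st_lat, c(-Inf, cuts, Inf), labels = c("I", "II", "III", "IV"))
  stage <- as.character(stage)
  stage[!tumor] <- NA

  an_lat <- config$aneuploidy_rho * scale(g)[, 1] +
    sqrt(1 - config$aneuploidy_rho^2) * stats::rnorm(n_all)
  aneuploidy <- pmax(0L, as.integer(round(8 + 4 * an_lat)))
  aneuploidy[!tumor] <- NA
  gd_lat <- 0.4 * scale(g)[, 1] + stats::rnorm(n_all)
  genome_doublings <- as.integer(cut(gd_lat, c(-Inf, 0.5, 1.5, Inf))) - 1L
  genome_doublings[!tumor] <- NA

  clinical <- data.frame(sample_id = sample_id, cancer_type = cancer_type,
                         sample_type = sample_type, stage = stage,
                         os_time = os_time, os_event = os_event,
                         aneuploidy_score = aneuploidy,
                         genome_doublings = genome_doublings,
                         stringsAsFactors = FALSE)
  truth <- list(sample_id = sample_id, g = g, h = h, carriers = carriers,
                config = config)
  list(expr = expr, cna = cna, mutations = mutations, clinical = clinical,
       truth = truth)
}

#' Simulate a spatially annotated single-cell dataset
#'
#' Per patient, cells carry a latent (g, h) pair with correlation
#' `cell_rho`; the hypoxia latent is elevated in core cells relative to
#' middle and edge by `region_shift`. Counts are negative binomial with
#' mean exp(baseline + loading * latent); mitochondrial genes (`MT-`
#' prefix) are included so QC is exercised, and a `qc_fail_fraction` of
#' cells is deliberately generated to fail QC (low depth or high
#' mitochondrial load).
#'
#' @param config [sim_config()].
#' @return list: `cells` (`cell_matrix`), `truth` (per-cell latents,
#'   regions, planted QC failures).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  uni <- sim_gene_universe(config)
  gly <- uni$gly; hyp <- uni$hyp; overlap <- uni$overlap
  n_extra <- max(0, config$n_cell_genes - length(union(gly, hyp)) - 5)
  genes <- c(union(gly, hyp), paste0("MT-", c("ND1", "ND2", "CO1", "CYB", "ATP6")),
             sprintf("CGENE%04d", seq_len(n_extra)))
  n_cells_tot <- config$n_patients * config$cells_per_patient
  patient <- rep(sprintf("P%02d", seq_len(config$n_patients)),
                 each = config$cells_per_patient)
  region <- unlist(lapply(seq_len(config$n_patients), function(i)
    sample(CELL_REGIONS, config$cells_per_patient, replace = TRUE)))
  cell_id <- sprintf("CELL%05d", seq_len(n_cells_tot))

  lat <- rbvn(n_cells_tot, config$cell_rho)
  reg_shift <- c(core = config$region_shift,
                 middle = config$region_shift / 2, edge = 0)
  g <- lat[, 1]
  h <- lat[, 2] + reg_shift[region]

  baseline <- stats::rnorm(length(genes), mean = 1.0, sd = 0.8)
  names(baseline) <- genes
  baseline[startsWith(genes, "MT-")] <- 2.5  # mito genes are high-expressed
  loading <- numeric(length(genes)); names(loading) <- genes
  loading[setdiff(gly, overlap)] <- config$sig_effect * 0.8
  loading[setdiff(hyp, overlap)] <- 0
  loading[overlap] <- config$sig_effect * 0.4
  lat_g <- outer(loading, g)
  loading_h <- numeric(length(genes)); names(loading_h) <- genes
  loading_h[setdiff(hyp, overlap)] <- config$sig_effect * 0.8
  loading_h[overlap] <- config$sig_effect * 0.4
  lat_h <- outer(loading_h, h)
  mu <- exp(log(2) * (lat_g + lat_h) + baseline)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, cell_id))

  # planted QC failures: half low-depth, half mitochondrial overload
  n_fail <- floor(config$qc_fail_fraction * n_cells_tot)
  fail_ids <- character(0)
  if (n_fail > 0) {
    fail_idx <- sample(n_cells_tot, n_fail)
    half <- fail_idx[seq_len(ceiling(n_fail / 2))]
    rest <- setdiff(fail_idx, half)
    for (j in half) {  # starve the cell below the count threshold
      v <- counts[, j]
      keep <- sample(length(v), 50)
      counts[, j] <- 0L
      counts[keep, j] <- pmin(v[keep], 3L)
    }
    mito <- startsWith(genes, "MT-")
    for (j in rest)  # overload mitochondrial reads past 10%
      counts[mito, j] <- counts[mito, j] + as.integer(
        0.3 * sum(counts[, j]) / sum(mito))
    fail_ids <- cell_id[fail_idx]
  }
  meta <- data.frame(cell_id = cell_id, patient_id = patient,
                     region = region, stringsAsFactors = FALSE)
  cells <- cell_matrix(counts, meta)
  truth <- list(cell_id = cell_id, g = g, h = unname(h), region = region,
                patient = patient, planted_qc_fail = fail_ids,
                config = config)
  list(cells = cells, truth = truth)
}

#' Write a simulated bundle to disk in the pipeline's file dialects
#'
#' Produces `expr.tsv`, `cna.tsv`, `mutations.tsv`, `clinical.tsv`,
#' `counts.mtx`, `genes.tsv`, `cells.tsv` and `truth.json` (requires the
#' jsonlite package for the truth file). Output is deterministic given
#' the bundle: the same seed yields byte-identical files.
#'
#' @param bundle result of [simulate_cohort()], optionally with elements
#'   `cells`/`cell_truth` from [simulate_cells()].
#' @param dir output directory.
#' @param force overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop_fmt("directory %s exists; use force = TRUE to overwrite", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(bundle$expr, file.path(dir, "expr.tsv"))
  write_matrix(bundle$cna, file.path(dir, "cna.tsv"))
  write_mutations(bundle$mutations, file.path(dir, "mutations.tsv"))
  write_clinical(bundle$clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(bundle$cells))
    write_cells(bundle$cells, file.path(dir, "counts.mtx"),
                file.path(dir, "genes.tsv"), file.path(dir, "cells.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- bundle$truth
    truth$config <- unclass(truth$config)
    truth$config$driver_spec <- as.list(truth$config$driver_spec)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
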