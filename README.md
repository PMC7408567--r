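# glycoscape

Pan-cancer quantification of tumor glycolysis from bulk and single-cell
transcriptomes, and association of that activity with the genome, the
clinic and the tumor microenvironment.

Tumors that ferment glucose even in the presence of oxygen (the Warburg
effect) behave differently: they are more hypoxic, more aneuploid, and
their patients fare worse. glycoscape turns a genes × samples expression
matrix (log2(TPM+1)) into a per-sample **glycolysis score** and **hypoxia
score**, stratifies each cancer-type cohort into score-high and score-low
tumors, and provides the full battery of downstream analyses around that
stratification: tumor-versus-normal and stage contrasts, Kaplan–Meier /
log-rank / Cox survival analysis, copy-number and mutation association
scans with per-cohort FDR control, a pan-cancer driver panorama,
differential enrichment and expression screens, cross-cancer recurrence,
candidate-regulator ranking, quadrant stratification, and a single-cell
branch (QC, depth normalization, per-cell scoring, spatial region
comparison). A latent-variable multi-omics simulator with known ground
truth backs every stage's tests.

## The score

For each gene, expression is re-expressed as a kernel-smoothed empirical
CDF across samples,

z_ij = (1/n) Σ_k Φ((x_ij − x_ik)/h_i),  h_i = SD_i / 4,

genes are ranked within each sample by decreasing z and weighted by the
symmetric rank statistic |p/2 − rank|, and a weighted Kolmogorov–Smirnov
random walk down the ranking (in-set genes add normalized weight,
out-of-set genes subtract 1/(p−k)) yields the score: the maximum positive
running deviation minus the maximum absolute negative one. Scores are
bounded in [−1, 1]; a sample whose signature genes crowd the top of its
ranking approaches +1. Three signatures ship built in: the 22-gene
glycolysis signature (SLC2A1, HK1–HK3, GPI, PFKL/M/P, ALDOA/B/C, TPI1,
GAPDH, PGK1, PGAM1/4, ENO1–3, PKLR, PKM, LDHA), a 14-gene hypoxia
signature, and the 16-gene overlap-free glycolysis variant used to show
that the glycolysis–hypoxia correlation is not driven by the six shared
genes.

## Worked example

Simulate a default study (4 cancer types × 300 tumors + 50 normals,
latent glycolysis–hypoxia correlation 0.8), score one cohort, stratify
it, and test the clinical endpoints:

```r
library(glycoscape)
cfg <- sim_config(seed = 2026)
b   <- simulate_cohort(cfg)
cl  <- b$clinical

sets <- list(glycolysis22 = builtin_signature("glycolysis22"),
             hypoxia14    = builtin_signature("hypoxia14"))
ids <- cl$sample_id[cl$cancer_type == "CT01"]
sc  <- score_matrix(b$expr[, ids], sets)
head(sc, 3)
#>            glycolysis22 hypoxia14
#> CT01_S0001        0.081     0.102
#> CT01_S0002       -0.729    -0.445
#> CT01_S0003        0.104    -0.070
```

Each row is a sample, each score in [−1, 1]: sample 2 sits deep in the
glycolysis-low, hypoxia-low corner. Stratify the 300 tumors at the top
and bottom 30% and check the hypoxia coupling:

```r
gly <- setNames(sc[, "glycolysis22"], rownames(sc))
tum <- intersect(ids, cl$sample_id[cl$sample_type == "tumor"])
lab <- classify_by_score(gly[tum], q = 0.30, min_group = 30)
table(lab$label)
#>  low  mid high
#>   90  120   90

spearman(sc[tum, "glycolysis22"], sc[tum, "hypoxia14"])$rho
#> [1] 0.8193464
```

The recovered score-level correlation (0.82) tracks the planted latent
correlation (0.8). Tumor-versus-normal and survival endpoints:

```r
tumor_normal_compare(gly, cl, min_normals = 30)[, c("n_tumor", "n_normal",
                                                    "p_value", "direction")]
#>   n_tumor n_normal      p_value direction
#> 1     300       50 1.137265e-14         +

clt <- cl[match(lab$sample_id, cl$sample_id), ]
km_logrank(lab, setNames(clt$os_time, clt$sample_id),
           setNames(clt$os_event, clt$sample_id))[c("chisq", "p_value")]
#> $chisq   45.69
#> $p_value 1.39e-11
```

Tumors score significantly above normals, and the glycolysis-high group
carries significantly worse survival (hazard is generated proportional to
exp(log 2 · latent)). `run_all()` wires every stage together over on-disk
TSVs and writes a manifest; see `?run_all`.

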