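---
title: "Scoring tumor glycolysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumor glycolysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glycoscape quantifies the glycolytic activity of tumor samples — bulk or
single cell — from their transcriptomes, stratifies cohorts on that
activity, and asks which genomic, clinical and microenvironmental features
travel with it. This vignette explains the model behind each stage, the
parameters that matter, and the design choices made where more than one
defensible option existed.

## The scoring model

The core statistic is a single-sample, rank-based enrichment score of a
gene signature, computed in three steps on a genes × samples matrix of
log2(TPM+1) values.

**1. Kernel CDF.** For gene $i$ with values $x_{i1},\dots,x_{in}$ across
samples, the expression of sample $j$ is re-expressed as its estimated
cumulative position

$$z_{ij} = \frac{1}{n}\sum_{k=1}^{n}
  \Phi\!\left(\frac{x_{ij}-x_{ik}}{h_i}\right),
  \qquad h_i = \tfrac{1}{4}\,\mathrm{SD}_i ,$$

a Gaussian-kernel smoothed empirical CDF. The SD/4 bandwidth is the
conventional choice for log-scale expression. Setting `kernel = "none"`
replaces $\Phi$ with the indicator and yields the plain ECDF.

**2. Symmetric rank statistic.** Within each sample, genes are ranked by
decreasing $z_{ij}$ (rank 1 = relatively most expressed) and weighted by
$r_{ij} = |p/2 - \mathrm{rank}_{ij}|$, so genes near the middle of a
sample's distribution carry almost no weight and genes at either extreme
carry the most.

**3. Weighted random walk.** Walking the ranking from the top, in-set
genes add $|r|^{\tau}$ (normalized by the in-set total, $\tau = 1$ by
default) and out-of-set genes subtract $1/(p-k)$. The score is the
maximum positive running deviation minus the maximum absolute negative
one. Both deviations lie in $[0,1]$, so scores are bounded in $[-1,1]$: a
sample whose signature genes sit at the top of its ranking approaches
$+1$, at the bottom $-1$.

Two properties matter in practice. The score depends on the data only
through within-gene comparisons followed by within-sample rank
comparisons, so it is insensitive to per-gene location/scale differences.
Under the ECDF variant it is *exactly* invariant to any strictly
increasing per-gene transform; under the Gaussian kernel the invariance is
only approximate, because the bandwidth and the smoothed CDF both change
with the transform (the package's invariance checks therefore use the
ECDF path). Genes with zero variance get a floored bandwidth ($10^{-8}$)
so constant housekeeping rows degenerate to ties rather than NaN; ranking
ties are broken by input gene order, making results deterministic.

## The signatures

Three signatures ship with the package as a GMT resource (a single source
of truth users can replace): a 22-gene glycolysis signature covering the
canonical glycolytic enzymes (transporter SLC2A1 through LDHA), a 14-gene
hypoxia response signature, and a 16-gene glycolysis variant with the six
genes shared with the hypoxia signature (ALDOA, ENO1, LDHA, PGAM1,
SLC2A1, TPI1) removed. The 16-gene variant exists to show that a
glycolysis–hypoxia score correlation is not a bookkeeping artifact of the
shared members: if the biology is real, the overlap-free score must stay
correlated with the hypoxia score, and in both the simulated studies and
the motivating data it does.

## Stratification and downstream tests

Cohorts are split per cancer type into score-high / score-low groups at
the top and bottom 30% (`q = 0.30`), with `floor(q*n)` samples per group
and ties at the boundary resolved by (score, sample id) lexicographic
order for determinism. Cancer types whose groups would fall below 30
samples are flagged ineligible. Downstream, the package uses:

* Wilcoxon rank-sum for tumor-versus-normal score shifts (run only where
  at least 30 normals exist), exact enumeration when both arms have at
  most 10 untied observations, normal approximation with tie and
  continuity correction otherwise;
* Welch's unequal-variance t wherever two mean scores are compared
  (stage IV vs I, CNA/SNV carrier vs neutral, signature enrichment high
  vs low) — group sizes and variances differ wildly between, say,
  copy-number-altered and neutral arms, so the pooled-variance t is never
  used;
* Benjamini–Hochberg adjustment always within one cancer-type cohort,
  never pooled across types, matching how per-cohort discovery lists are
  consumed;
* Kaplan–Meier / log-rank / Cox (Breslow ties) via the survival package,
  which is the standard implementation of these estimators; the test
  suite cross-checks the log-rank statistic against a hand-computed
  observed-minus-expected tableau and Cox against planted-coefficient
  recovery;
* one-way ANOVA across genome-doubling classes (0/1/2) and across tumor
  regions — a three-group comparison, for which a two-sample t test is
  not defined;
* the hypergeometric upper tail for over-representation, reported as
  enriched only when the overlap is at least 3 genes *and* p < 0.01.

Copy-number calling at cohort level uses the gain–loss ratio rule: a gene
with more than twice as many gain as loss carriers is a cohort-level
gain, the symmetric rule gives losses, everything else (including the
exact ratio 2 and the no-alteration case) is ambiguous; a zero
denominator with a nonzero numerator counts as exceeding the ratio.
Differential expression between score groups uses a rank-sum test on
log2(TPM+1) with fold change computed on the linear TPM+1 scale (the
pseudocount retained for stability at zero); a gene is "up" only when
fold change ≥ 1.5 *and* BH-adjusted p < 0.05, jointly. A
negative-binomial count model would be inappropriate here because the
input is TPM-scale, not raw counts. Signature-level differences use Welch
t on the enrichment scores, which are near-normal around zero. Recurrence
asks for the same direction in at least 13 cancer types (configurable);
candidate regulators are ranked by their median per-cancer Spearman
correlation with the glycolysis score (the per-gene min/max range is
reported alongside; the median was chosen as the ranking key because only
per-gene ranges, not a rule, were available to match). Quadrant
stratification is a double median split — top 50% of hypoxia score, then
top 50% of a chosen gene's expression within each hypoxia stratum — with
quadrant sizes differing by at most one inside each stratum.

## Single-cell branch

Cells are filtered on four rules: at least 200 total counts, between 200
and 6000 expressed genes, and at most 10% mitochondrial counts (genes
with the `MT-` prefix; all thresholds configurable). Surviving cells are
depth-normalized as log2(1 + 10⁴·count/total) and scored exactly like
bulk samples, with cells in the sample role. Because the scoring engine
is rank-based per gene, the choice of variance-stabilizing transform is
immaterial to the scores — which is why a simple counts-per-10k log
transform is used rather than a heavier model-based normalization.
Per-cell top-30% overlay flags (exactly `floor(0.3·n)` cells, ties by
cell id) are emitted for each score and for selected genes, joinable to
any embedding. Spatial comparisons run a one-way ANOVA of each score
across core / edge / middle regions per patient.

## The simulator

Every downstream claim is tested against data with known truth. The
generator draws, per tumor, a latent (glycolysis, hypoxia) pair from a
bivariate normal with correlation `rho` (default 0.8, the regime of
strong coupling the pipeline is designed to detect); normal tissue sits
at the baseline, tumors are shifted by one latent SD. Signature genes
load on their latent at `sig_effect` = 1 log2 unit per latent SD — a
2-fold expression swing per SD of program activity, typical of strongly
regulated metabolic genes — with the six shared genes loading on the
average of both latents, deliberately reproducing the overlap confounding
that the 16-gene signature addresses. Planted drivers shift the
glycolysis latent of their carriers (gain +0.4, loss −0.4, mutation +0.5
by default, 20–30% carriers) before expression is generated; inert decoy
drivers exercise the panorama ranking. Survival times are exponential
with hazard ∝ exp(log 2 · g) under independent exponential censoring;
stage is an ordered split of a latent shifted by 0.5·g; the aneuploidy
score discretizes a latent correlated 0.4 with g. The default cohort is
4 cancer types × (300 tumors + 50 normals) with a 300-gene universe —
compact enough for routine testing while keeping every ≥30-sample
eligibility rule binding.

Single-cell data are negative binomial (dispersion 2) around
exp(baseline + loading·latent), 8 patients × 150 cells over a 400-gene
panel including five high-expressed mitochondrial genes, with the hypoxia
latent elevated in core over middle over edge cells (0.6 latent SD
core-to-edge) and 5% of cells deliberately generated to fail QC (half
starved of counts, half overloaded with mitochondrial reads).

What the simulator does *not* emulate: gene–gene co-expression beyond the
two latent programs, segment-level copy-number structure, batch effects,
and realistic mutational signatures. Passing tests therefore demonstrate
that the machinery recovers planted structure of the assumed form at
realistic sizes — not that real tumors satisfy the model.

## Numerical choices and edge cases

* Walk scores are clamped to $[-1, 1]$: the running sum accumulates
  $1/(p-k)$ terms whose floating-point total can overshoot the
  theoretical bound by ~1e−16.
* Two constant equal arms give p = 1 with an explanatory note rather
  than an error; an all-identical k-sample input likewise.
* Spearman correlation returns an explicit NA (never 0) when either
  ranked vector is constant; p-values use the t approximation on
  Pearson-of-mid-ranks.
* Cox fits fail loudly on singular or constant designs — no silent
  zero coefficients.
* Signature genes absent from a matrix are dropped with a warning and a
  reported per-set overlap count; scoring proceeds while at least one
  in-set and one out-of-set gene remain.
* Matrix TSVs are written with 17 significant digits so write–read round
  trips reproduce doubles exactly.
* Whether scoring runs per cancer type or pooled is the caller's choice;
  the pipeline driver scores per cancer type, which matches how the
  stratification thresholds are defined.
* On a measured-scale note: with latent correlation 0.8, the *score*-level
  Spearman correlation is expected slightly below 0.8 even for a perfect
  scorer (rank correlation of a bivariate normal is
  $\tfrac{6}{\pi}\arcsin(\rho/2) \approx 0.786$ at $\rho = 0.8$, minus
  attenuation from finite signature size); the shared-gene loadings pull
  it back up. Observed recovery in the test suite sits within ±0.05 of
  the latent value.

## Problem sizes used in the checks

The packaged checks run the engine-versus-oracle comparison on 200 small
random matrices, boundedness on 1000 random matrices, null centering on a
5000-gene × 100-sample i.i.d. matrix with 1000 random 22-gene sets,
correlation recovery on 100 cohorts of 500 tumors, association
calibration on 200 replicates of 2000-gene scans at n = 500, log-rank
size on 5000 null replicates, and the full pipeline twice on the default
simulated study for byte-identical manifests. These sizes were chosen so
the whole suite completes in minutes on a laptop while keeping Monte-Carlo
error well inside each asserted tolerance.

## Known limitations

* The engine implements the Gaussian-kernel and ECDF paths only; a
  Poisson kernel for raw-count bulk data is out of scope.
* Over-representation runs against user-supplied GMT collections; no
  pathway database is bundled.
* The pipeline consumes GISTIC-style thresholded copy-number calls and
  MAF-lite mutation tables; it does not call alterations from raw data.
* Clustering, embedding and cell-type annotation of single cells are out
  of scope; overlay flags are emitted as tables to join onto any
  embedding computed elsewhere.
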