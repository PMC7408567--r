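Package: glycoscape
Title: Pan-Cancer Glycolysis Signature Scoring and Multi-Omics Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor glycolytic activity from bulk and single-cell
    transcriptomes with a rank-based single-sample enrichment engine
    (kernel-CDF random-walk scoring of a 22-gene glycolysis signature and a
    14-gene hypoxia signature), stratifies cohorts into score-high and
    score-low groups, and associates the scores with copy-number
    alterations, somatic mutations, tumor mutation burden, aneuploidy,
    survival, differential expression and spatial single-cell structure.
    Ships a latent-variable multi-omics simulator that provides ground
    truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
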