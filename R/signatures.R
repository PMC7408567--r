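# Built-in signatures are shipped as a GMT resource so there is a single
# source of truth and users can substitute their own catalog.

.sig_env <- new.env(parent = emptyenv())

signature_catalog <- function() {
  if (is.null(.sig_env$catalog)) {
    path <- system.file("extdata", "signatures.gmt", package = "glycoscape")
    if (!nzchar(path))
      path <- file.path("inst", "extdata", "signatures.gmt")
    .sig_env$catalog <- read_gmt(path)
  }
  .sig_env$catalog
}

#' Built-in gene signatures
#'
#' Returns one of the packaged signatures: `glycolysis22`, the 22 core
#' glycolytic-enzyme genes used to score glycolytic activity; `hypoxia14`,
#' a 14-gene hypoxia response signature; or `glycolysis16`, the glycolysis
#' signature with the 6 genes shared with the hypoxia signature removed
#' (used to show that the glycolysis-hypoxia score correlation is not an
#' artifact of shared members).
#'
#' @param name one of `"glycolysis22"`, `"hypoxia14"`, `"glycolysis16"`.
#' @return character vector of gene symbols (a copy; the catalog is
#'   immutable).
#' @examples
#' length(builtin_signature("glycolysis22"))  # 22
#' @export
builtin_signature <- function(name) {
  cat <- signature_catalog()
  if (!name %in% names(cat))
    stop_fmt("unknown signature '%s'; available: %s", name,
             paste(names(cat), collapse = ", "))
  cat[[name]]
}

#' Genes shared between two signatures
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted character vector of the intersection.
#' @export
overlap_genes <- function(a, b) {
  sort(intersect(a, b))
}
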