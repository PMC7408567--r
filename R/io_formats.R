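#' @useDynLib glycoscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- validation helpers ------------------------------------------------

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_fmt("duplicate %s: %s", what, paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(ids)
}

#' Validate a genes x samples expression matrix
#'
#' Checks the invariants assumed throughout the pipeline: unique gene and
#' sample identifiers, all values finite, and dimnames present. Values are
#' expected on the log2(TPM+1) scale but the scale itself is not checked.
#'
#' @param x numeric matrix, genes in rows, samples in columns, with dimnames.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fmt("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_fmt("expression matrix requires gene rownames and sample colnames")
  check_unique_ids(rownames(x), "gene ids")
  check_unique_ids(colnames(x), "sample ids")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop_fmt("non-finite expression value at gene '%s', sample '%s'",
             rownames(x)[bad[1]], colnames(x)[bad[2]])
  }
  invisible(x)
}

#' Validate a GISTIC-style thresholded copy-number matrix
#'
#' Entries must lie in \{-1, 0, 1\} (loss / neutral / gain).
#'
#' @param x integer matrix with gene rownames and sample colnames.
#' @return `x`, invisibly, if valid.
#' @export
validate_cna_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fmt("CNA matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_fmt("CNA matrix requires gene rownames and sample colnames")
  check_unique_ids(rownames(x), "gene ids")
  check_unique_ids(colnames(x), "sample ids")
  ok <- x %in% c(-1L, 0L, 1L)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(x)), arr.ind = TRUE)[1, ]
    stop_fmt("CNA call %s at gene '%s', sample '%s' is outside {-1, 0, 1}",
             format(x[bad[1], bad[2]]), rownames(x)[bad[1]], colnames(x)[bad[2]])
  }
  invisible(x)
}

# ---- GMT ---------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded. Duplicate genes within a line are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   gene symbols, names are the set names.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_fmt("malformed GMT line %d: fewer than 3 tab-separated fields", i)
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes removed", name),
              call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) == 0)
      stop_fmt("GMT set '%s' (line %d) has no genes", name, i)
    if (name %in% names(sets))
      stop_fmt("duplicate gene-set name '%s' in %s", name, path)
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors of gene symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_fmt("gene sets must be a named list")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- TSV matrices ------------------------------------------------------

#' Read a genes x samples matrix from TSV
#'
#' Canonical dialect: header row of sample ids, first column gene ids,
#' tab-separated. `kind = "expression"` requires finite numeric values;
#' `kind = "cna"` requires integer entries in \{-1, 0, 1\}.
#'
#' @param path TSV file path.
#' @param kind `"expression"` or `"cna"`.
#' @return validated numeric matrix (integer storage for CNA).
#' @export
read_matrix <- function(path, kind = c("expression", "cna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_fmt("matrix file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("matrix file %s has no sample columns", path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_fmt("non-numeric values in matrix file %s", path)
  rownames(m) <- genes
  if (kind == "expression") {
    validate_expression_matrix(m)
  } else {
    validate_cna_matrix(m)
    storage.mode(m) <- "integer"
  }
  m
}

#' Write a genes x samples matrix as TSV
#'
#' Values are written with 17 significant digits so numeric round trips are
#' exact to the double representation.
#'
#' @param x matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param digits significant digits for numeric formatting.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, digits = 17) {
  fmt <- function(v) {
    if (is.integer(v) || all(v == round(v))) format(as.integer(v))
    else formatC(v, digits = digits, format = "g")
  }
  body <- apply(x, 1, fmt)
  body <- if (is.matrix(body)) t(body) else matrix(body, nrow = nrow(x))
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], body[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---- clinical / mutation tables ---------------------------------------

CLINICAL_COLS <- c("sample_id", "cancer_type", "sample_type", "stage",
                   "os_time", "os_event", "aneuploidy_score",
                   "genome_doublings")

#' Read the clinical table
#'
#' Fixed-header TSV with columns `sample_id`, `cancer_type`, `sample_type`
#' (tumor/normal), `stage` (I--IV or missing), `os_time` (days), `os_event`
#' (0/1), `aneuploidy_score`, `genome_doublings`. Empty strings on disk
#' become `NA` in memory.
#'
#' @param path TSV path.
#' @return data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_fmt("clinical file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing_cols))
    stop_fmt("clinical table missing columns: %s",
             paste(missing_cols, collapse = ", "))
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  check_unique_ids(df$sample_id, "sample ids")
  if (!all(df$sample_type %in% c("tumor", "normal")))
    stop_fmt("sample_type must be 'tumor' or 'normal'")
  st <- df$stage[!is.na(df$stage)]
  if (!all(st %in% c("I", "II", "III", "IV")))
    stop_fmt("stage must be I, II, III, IV or missing")
  if (any(df$os_time < 0, na.rm = TRUE)) stop_fmt("os_time must be >= 0")
  ev <- df$os_event[!is.na(df$os_event)]
  if (!all(ev %in% c(0, 1))) stop_fmt("os_event must be 0 or 1")
  gd <- df$genome_doublings[!is.na(df$genome_doublings)]
  if (!all(gd %in% 0:2)) stop_fmt("genome_doublings must be 0, 1 or 2")
  invisible(df)
}

#' Write the clinical table
#' @param df clinical data.frame (see [read_clinical()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  validate_clinical(df)
  utils::write.table(df[, CLINICAL_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a MAF-lite mutation table
#'
#' TSV with columns `sample_id`, `gene_id`, `nonsynonymous` (TRUE/FALSE).
#' A sample may carry several records for one gene; records are collapsed
#' to presence/absence at association time.
#'
#' @param path TSV path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop_fmt("mutation file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "nonsynonymous")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_fmt("mutation table missing columns: %s",
             paste(missing_cols, collapse = ", "))
  df$nonsynonymous <- as.logical(df$nonsynonymous)
  if (anyNA(df$nonsynonymous))
    stop_fmt("nonsynonymous column must be TRUE/FALSE")
  df
}

#' Write a MAF-lite mutation table
#' @param df data.frame with `sample_id`, `gene_id`, `nonsynonymous`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(df, path) {
  utils::write.table(df[, c("sample_id", "gene_id", "nonsynonymous")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- single-cell counts ------------------------------------------------

CELL_REGIONS <- c("core", "edge", "middle")

#' Read a single-cell counts bundle
#'
#' MatrixMarket coordinate counts (genes x cells), a gene list (one symbol
#' per line), and a cell metadata TSV with columns `cell_id`, `patient_id`,
#' `region` (core / edge / middle).
#'
#' @param mtx_path MatrixMarket file of nonnegative integer counts.
#' @param genes_path text file of gene symbols, one per line.
#' @param meta_path cell metadata TSV.
#' @return list with `counts` (dgCMatrix, genes x cells) and `cell_meta`
#'   (data.frame), an object of class `cell_matrix`.
#' @export
read_cells <- function(mtx_path, genes_path, meta_path) {
  for (p in c(mtx_path, genes_path, meta_path))
    if (!file.exists(p)) stop_fmt("file not found: %s", p)
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readLines(genes_path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (nrow(meta) == 0) stop_fmt("empty cell metadata file: %s", meta_path)
  need <- c("cell_id", "patient_id", "region")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop_fmt("cell metadata missing columns: %s",
             paste(missing_cols, collapse = ", "))
  if (nrow(counts) != length(genes))
    stop_fmt("MTX has %d rows but gene list has %d entries",
             nrow(counts), length(genes))
  if (ncol(counts) != nrow(meta))
    stop_fmt("MTX has %d columns but metadata has %d rows",
             ncol(counts), nrow(meta))
  rownames(counts) <- genes
  colnames(counts) <- meta$cell_id
  cell_matrix(counts, meta)
}

#' Construct a validated cell matrix
#'
#' @param counts genes x cells matrix of nonnegative integer counts
#'   (dense or sparse).
#' @param cell_meta data.frame with `cell_id`, `patient_id`, `region`.
#' @return object of class `cell_matrix`: list(counts, cell_meta).
#' @export
cell_matrix <- function(counts, cell_meta) {
  check_unique_ids(cell_meta$cell_id, "cell ids")
  check_unique_ids(rownames(counts), "gene ids")
  if (ncol(counts) != nrow(cell_meta))
    stop_fmt("counts have %d cells but metadata has %d rows",
             ncol(counts), nrow(cell_meta))
  bad_region <- setdiff(unique(cell_meta$region), CELL_REGIONS)
  if (length(bad_region))
    stop_fmt("unknown region label(s) %s; allowed: %s",
             paste(sQuote(bad_region), collapse = ", "),
             paste(CELL_REGIONS, collapse = ", "))
  if (anyNA(cell_meta$patient_id) || anyNA(cell_meta$region))
    stop_fmt("every cell needs patient and region labels")
  v <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(v < 0) || any(v != round(v)))
    stop_fmt("counts must be nonnegative integers")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_matrix")
}

#' Write a single-cell counts bundle
#'
#' @param cells `cell_matrix` object.
#' @param mtx_path,genes_path,meta_path output paths.
#' @return invisible NULL.
#' @export
write_cells <- function(cells, mtx_path, genes_path, meta_path) {
  m <- methods::as(methods::as(Matrix::Matrix(cells$counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, mtx_path)
  writeLines(rownames(cells$counts), genes_path)
  utils::write.table(cells$cell_meta[, c("cell_id", "patient_id", "region")],
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
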