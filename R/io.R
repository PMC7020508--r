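#' @keywords internal
qc_stop <- function(..., class = "qc_runtime_error") {
  stop(structure(
    class = c(class, "qc_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
qc_validation_stop <- function(...) qc_stop(..., class = "qc_validation_error")

strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Read a sample phenotype sheet
#'
#' Reads the tab-delimited per-sample metadata table. Two columns are required
#' (header match is case-insensitive): `sample`, holding unique sample names
#' that correspond to count-matrix columns, and `group`, the phenotype label.
#' Every additional column is kept, in order, as a categorical covariate
#' (batch, flow cell, library protocol, ...).
#'
#' Removing a sample from this sheet removes it from the whole analysis: counts
#' columns without a phenotype row are dropped at assembly time, so outlier
#' exclusion is a one-line edit of this file, with no change to the count
#' matrix.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @return A `data.frame` with columns `sample`, `group`, then covariates, of
#'   class `qc_pheno`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) qc_validation_stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  as_phenotype(df)
}

#' Validate a data frame as a phenotype sheet
#'
#' @param df A data frame with `sample` and `group` columns (case-insensitive)
#'   and optional covariate columns.
#' @return A validated `qc_pheno` data frame.
#' @export
as_phenotype <- function(df) {
  lc <- tolower(names(df))
  i_sample <- which(lc == "sample")[1]
  i_group  <- which(lc == "group")[1]
  if (is.na(i_sample)) qc_validation_stop("phenotype sheet lacks required column 'sample'")
  if (is.na(i_group))  qc_validation_stop("phenotype sheet lacks required column 'group'")
  cov_idx <- setdiff(seq_along(df), c(i_sample, i_group))
  out <- data.frame(sample = as.character(df[[i_sample]]),
                    group  = as.character(df[[i_group]]),
                    stringsAsFactors = FALSE)
  for (j in cov_idx) out[[names(df)[j]]] <- as.character(df[[j]])
  if (any(!nzchar(out$sample)) || anyNA(out$sample))
    qc_validation_stop("phenotype sheet contains empty sample names")
  dup <- unique(out$sample[duplicated(out$sample)])
  if (length(dup))
    qc_validation_stop("duplicate sample ids in phenotype sheet: ",
                       paste(dup, collapse = ", "))
  if (nrow(out) < 2)
    qc_validation_stop("phenotype sheet must list at least 2 samples")
  if (any(!nzchar(out$group)) || anyNA(out$group))
    qc_validation_stop("phenotype sheet contains empty group labels")
  covs <- covariate_names(out)
  for (cv in covs) {
    if (any(!nzchar(out[[cv]])) || anyNA(out[[cv]]))
      qc_validation_stop("covariate column '", cv, "' has empty cells")
  }
  class(out) <- c("qc_pheno", "data.frame")
  out
}

covariate_names <- function(pheno) setdiff(names(pheno), c("sample", "group"))

#' Read a gene-by-sample count matrix
#'
#' Reads a tab-delimited expression table as produced by RSEM, HTSeq,
#' featureCounts, Kallisto or Salmon: first column gene identifiers or symbols
#' (the first header cell may be empty or carry any label), remaining columns
#' one numeric column per sample. Values may be raw counts or pre-normalized
#' expression; the matrix is tagged `is_raw = TRUE` only when every value is
#' integral.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param strip_versions Strip Ensembl-style version suffixes (".N") from gene
#'   identifiers before use. Default `TRUE`.
#' @return A numeric matrix (genes x samples) of class `qc_counts` with
#'   attribute `is_raw`.
#' @export
read_counts <- function(path, strip_versions = TRUE) {
  if (!file.exists(path)) qc_validation_stop("count matrix file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, sep = "\t", header = FALSE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          colClasses = "character")
  # a trailing empty header (or one fewer header field than data columns)
  # means the first header cell labelled the gene-id column or was blank
  sample_names <- if (length(header) == ncol(df)) header[-1] else header
  if (length(sample_names) != ncol(df) - 1L)
    qc_validation_stop("count matrix header has ", length(header),
                       " fields but rows have ", ncol(df), " columns")
  ids <- df[[1]]
  if (strip_versions) ids <- strip_version(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    qc_validation_stop("duplicate gene ids in count matrix: ",
                       paste(utils::head(dup, 10), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  if (nrow(bad))
    qc_validation_stop("non-numeric value at gene '", ids[bad[1, 1]],
                       "', sample '", sample_names[bad[1, 2]], "'")
  dimnames(vals) <- list(ids, sample_names)
  as_counts(vals)
}

#' Validate a matrix as a count matrix
#'
#' @param x Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample names).
#' @return `x` with class `qc_counts` and attribute `is_raw`.
#' @export
as_counts <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) qc_validation_stop("count matrix must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    qc_validation_stop("count matrix needs gene row names and sample column names")
  if (nrow(x) < 2L) qc_validation_stop("count matrix must have at least 2 genes")
  if (ncol(x) < 2L) qc_validation_stop("count matrix must have at least 2 samples")
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg))
    qc_validation_stop("negative value at gene '", rownames(x)[neg[1, 1]],
                       "', sample '", colnames(x)[neg[1, 2]], "'")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    qc_validation_stop("duplicate gene ids in count matrix: ",
                       paste(utils::head(dup, 10), collapse = ", "))
  attr(x, "is_raw") <- all(abs(x - round(x)) < 1e-8)
  class(x) <- c("qc_counts", class(matrix()))
  x
}

is_raw_counts <- function(x) isTRUE(attr(x, "is_raw"))

#' Read a gene annotation table
#'
#' Reads per-gene length and GC content, required for TPM normalization and the
#' GC-bias metric. Three tab-separated columns: `gene_id`, `length_bp`
#' (positive integer, bp), `gc_fraction` (in \[0, 1\]). The annotation may
#' cover only part of the count matrix; metrics intersect gene sets as needed.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param strip_versions Strip ".N" version suffixes from gene ids.
#' @return A `data.frame` with columns `gene_id`, `length_bp`, `gc_fraction`,
#'   of class `qc_annotation`.
#' @export
read_annotation <- function(path, strip_versions = TRUE) {
  if (!file.exists(path)) qc_validation_stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 3L)
    qc_validation_stop("annotation needs columns gene_id, length_bp, gc_fraction")
  names(df)[1:3] <- c("gene_id", "length_bp", "gc_fraction")
  df$gene_id <- as.character(df$gene_id)
  if (strip_versions) df$gene_id <- strip_version(df$gene_id)
  as_annotation(df[, 1:3])
}

#' Validate a data frame as a gene annotation
#'
#' @param df Data frame with columns `gene_id`, `length_bp`, `gc_fraction`.
#' @return A validated `qc_annotation` data frame.
#' @export
as_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "gc_fraction")
  if (!all(need %in% names(df)))
    qc_validation_stop("annotation needs columns ", paste(need, collapse = ", "))
  df <- df[, need]
  df$gene_id <- as.character(df$gene_id)
  df$length_bp <- as.numeric(df$length_bp)
  df$gc_fraction <- as.numeric(df$gc_fraction)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    qc_validation_stop("duplicate gene ids in annotation: ",
                       paste(utils::head(dup, 10), collapse = ", "))
  if (anyNA(df$length_bp) || any(df$length_bp < 1))
    qc_validation_stop("annotation length_bp must be >= 1")
  if (anyNA(df$gc_fraction) || any(df$gc_fraction < 0 | df$gc_fraction > 1))
    qc_validation_stop("annotation gc_fraction must lie in [0, 1]")
  class(df) <- c("qc_annotation", "data.frame")
  df
}

#' Assemble a QC dataset
#'
#' Matches the phenotype sheet to the count matrix: counts columns are
#' restricted and reordered to the phenotype sample order. Samples present in
#' the counts but absent from the phenotype sheet are dropped with a warning —
#' this is the outlier-exclusion mechanism: edit the phenotype sheet, rerun. A
#' phenotype sample missing from the counts is an error.
#'
#' @param counts A `qc_counts` matrix (or path; see [read_counts()]).
#' @param pheno A `qc_pheno` sheet (or path; see [read_phenotype()]).
#' @param annotation Optional `qc_annotation` (or path), needed for TPM and
#'   GC-bias metrics.
#' @param organism One of `"human"`, `"mouse"`, `"other"`. Human/mouse selects
#'   TPM normalization and enables the housekeeping metric; other organisms use
#'   the variance-stabilizing transform.
#' @return A `qc_dataset` list with elements `counts`, `pheno`, `annotation`,
#'   `organism`.
#' @export
qc_dataset <- function(counts, pheno, annotation = NULL,
                       organism = c("human", "mouse", "other")) {
  organism <- match.arg(organism)
  if (is.character(counts) && length(counts) == 1L) counts <- read_counts(counts)
  if (is.character(pheno) && length(pheno) == 1L) pheno <- read_phenotype(pheno)
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- read_annotation(annotation)
  if (!inherits(counts, "qc_counts")) counts <- as_counts(counts)
  if (!inherits(pheno, "qc_pheno")) pheno <- as_phenotype(pheno)
  if (!is.null(annotation) && !inherits(annotation, "qc_annotation"))
    annotation <- as_annotation(annotation)

  missing_samples <- setdiff(pheno$sample, colnames(counts))
  if (length(missing_samples))
    qc_validation_stop("phenotype samples absent from count matrix: ",
                       paste(missing_samples, collapse = ", "))
  extra <- setdiff(colnames(counts), pheno$sample)
  if (length(extra))
    warning("dropping count-matrix samples not in phenotype sheet: ",
            paste(extra, collapse = ", "), call. = FALSE)
  raw <- is_raw_counts(counts)
  counts <- counts[, pheno$sample, drop = FALSE]
  attr(counts, "is_raw") <- raw
  class(counts) <- c("qc_counts", class(matrix()))
  structure(list(counts = counts, pheno = pheno, annotation = annotation,
                 organism = organism),
            class = "qc_dataset")
}

#' @export
print.qc_dataset <- function(x, ...) {
  cat("QC dataset: ", nrow(x$counts), " genes x ", ncol(x$counts), " samples (",
      x$organism, ")\n", sep = "")
  cat("Groups:", paste(sprintf("%s (n=%d)", names(table(x$pheno$group)),
                               as.integer(table(x$pheno$group))), collapse = ", "), "\n")
  covs <- covariate_names(x$pheno)
  cat("Covariates:", if (length(covs)) paste(covs, collapse = ", ") else "none", "\n")
  cat("Annotation:", if (is.null(x$annotation)) "none" else
    paste0(nrow(x$annotation), " genes"), "\n")
  cat("Raw counts:", is_raw_counts(x$counts), "\n")
  invisible(x)
}

#' Write phenotype / counts / annotation to tab-separated files
#'
#' Round-trip companions to the readers; used by the simulator and the demo
#' presets to materialize inputs on disk.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_input <- function(x, path) {
  if (inherits(x, "qc_counts") || (is.matrix(x) && !is.null(rownames(x)))) {
    df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
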