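#' Transcripts-per-million normalization
#'
#' For each sample, every gene's count is divided by its length to give a read
#' rate, and rates are rescaled so the sample totals one million:
#' `TPM(g, s) = (c(g,s) / l(g)) / sum_g'(c(g',s) / l(g')) * 1e6`,
#' with `c` the reads mapped to a gene and `l` the gene length in bp. Columns
#' therefore sum to 1e6 by construction. Genes without an annotation entry are
#' excluded before the computation (and reported via the `dropped_genes`
#' attribute); the remaining rates are renormalized over the annotated set.
#'
#' @param counts A raw `qc_counts` matrix.
#' @param annotation A `qc_annotation` with `length_bp` for the counted genes.
#' @return Numeric matrix of TPM values over the annotated genes, with
#'   attributes `method = "tpm"` and `dropped_genes`.
#' @export
tpm <- function(counts, annotation) {
  if (!inherits(counts, "qc_counts")) counts <- as_counts(counts)
  if (!inherits(annotation, "qc_annotation")) annotation <- as_annotation(annotation)
  if (!is_raw_counts(counts))
    qc_validation_stop("TPM requires raw (integer) counts")
  keep <- intersect(rownames(counts), annotation$gene_id)
  dropped <- setdiff(rownames(counts), keep)
  if (length(keep) < 1L)
    qc_validation_stop("no count-matrix gene has an annotation entry")
  len <- annotation$length_bp[match(keep, annotation$gene_id)]
  x <- unclass(counts)[keep, , drop = FALSE]
  rate <- x / len
  tot <- colSums(rate)
  zero <- colnames(x)[tot == 0]
  if (length(zero))
    qc_validation_stop("sample(s) with zero total rate (all-zero over annotated genes): ",
                       paste(zero, collapse = ", "))
  out <- sweep(rate, 2, tot, "/") * 1e6
  attr(out, "method") <- "tpm"
  attr(out, "dropped_genes") <- dropped
  out
}

#' Variance-stabilizing count transform for organisms without TPM annotation
#'
#' A depth-normalizing, variance-flattening transform used when the organism is
#' neither human nor mouse (so no bundled annotation route exists): per-sample
#' size factors are the median-of-ratios of counts to per-gene geometric means
#' across samples (computed over genes positive in every sample), and the
#' output is `log2(count / size_factor + 1)`. The full dispersion-trend VST is
#' deliberately not reproduced; this transform keeps its two properties that
#' matter here — depth removal and log-scale compression — and is deterministic.
#'
#' @param counts A raw `qc_counts` matrix.
#' @return Matrix of log2-scale normalized values with attributes
#'   `method = "vst_like"` and `size_factors`.
#' @export
vst_counts <- function(counts) {
  if (!inherits(counts, "qc_counts")) counts <- as_counts(counts)
  if (!is_raw_counts(counts))
    qc_validation_stop("size-factor normalization requires raw (integer) counts")
  x <- unclass(counts)[, , drop = FALSE]
  loggeo <- rowMeans(log(x))            # -Inf when any sample has a zero
  usable <- is.finite(loggeo)
  if (!any(usable))
    qc_validation_stop("no gene is positive in all samples; size factors undefined")
  sf <- apply(x, 2, function(col) exp(stats::median(log(col[usable]) - loggeo[usable])))
  out <- log2(sweep(x, 2, sf, "/") + 1)
  attr(out, "method") <- "vst_like"
  attr(out, "size_factors") <- sf
  out
}

#' Row-wise z-score standardization
#'
#' Transforms each gene row to `(x - mu) / sigma` with `mu` the row mean and
#' `sigma` the population standard deviation (divisor n), so every non-constant
#' row has mean 0 and variance 1. Constant rows (sigma = 0) become all-zero
#' rather than being dropped, keeping the matrix shape stable for PCA; their
#' count is reported in the `n_constant` attribute.
#'
#' @param x Numeric matrix, genes in rows.
#' @return Matrix of the same shape with attributes `method = "zscore"` and
#'   `n_constant`.
#' @export
zscore_rows <- function(x) {
  x <- unclass(as.matrix(x))
  if (ncol(x) < 2L) qc_validation_stop("z-scoring requires at least 2 samples")
  mu <- rowMeans(x)
  centred <- x - mu
  sigma <- sqrt(rowMeans(centred^2))    # population sd, divisor n
  const <- sigma == 0
  sigma[const] <- 1
  out <- centred / sigma
  out[const, ] <- 0
  attr(out, "method") <- "zscore"
  attr(out, "n_constant") <- sum(const)
  out
}

#' Elementwise log2(x + 1)
#'
#' The shared "normally distributed" transform behind the counts-distribution,
#' clustering and correlation views.
#'
#' @param x Non-negative numeric matrix or vector.
#' @return `log2(x + 1)`, same shape, attribute `method = "log2p1"`.
#' @export
log2p1 <- function(x) {
  if (any(x < 0)) qc_validation_stop("log2(x+1) requires non-negative input")
  out <- log2(unclass(as.matrix(x)) + 1)
  attr(out, "method") <- "log2p1"
  out
}

# The matrix feeding mapped-read density and normalized-scale gene profiles:
# TPM when human/mouse with annotation, the VST-like transform otherwise.
# Returns values plus the scale they are on ("linear" needs log2(x+1) before
# plotting; "log2" is used as-is).
normalized_expression <- function(dataset) {
  stopifnot(inherits(dataset, "qc_dataset"))
  if (dataset$organism %in% c("human", "mouse") && !is.null(dataset$annotation)) {
    list(values = tpm(dataset$counts, dataset$annotation), scale = "linear",
         method = "tpm")
  } else if (is_raw_counts(dataset$counts)) {
    v <- vst_counts(dataset$counts)
    list(values = v, scale = "log2", method = "vst_like")
  } else {
    # pre-normalized input: no further depth correction, just compress
    list(values = unclass(dataset$counts)[, , drop = FALSE], scale = "linear",
         method = "none")
  }
}
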