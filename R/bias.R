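#' Mapped-read density curves
#'
#' Gaussian kernel density of each sample's expression on a shared grid, used
#' to spot samples with little or no usable signal (their mass piles up near
#' zero). Input values are TPM for human/mouse with annotation, the
#' variance-stabilized transform otherwise; either way the density is taken on
#' a log2 scale. Bandwidth is Silverman's rule per sample; the evaluation grid
#' is 512 points spanning the global range padded by three bandwidths, shared
#' by all samples so curves are directly comparable.
#'
#' @param dataset A `qc_dataset`.
#' @return An object of class `qc_density`: `grid` (shared abscissae),
#'   `density` (grid x samples matrix), `method` (normalization used),
#'   `flat_samples` (all-zero samples rendered as flat curves).
#' @export
mapped_density <- function(dataset) {
  stopifnot(inherits(dataset, "qc_dataset"))
  ne <- normalized_expression(dataset)
  v <- if (ne$scale == "linear") log2(ne$values + 1) else ne$values
  n_grid <- 512L
  bws <- apply(v, 2, function(col) {
    if (stats::sd(col) == 0) NA_real_ else stats::bw.nrd0(col)
  })
  pad <- 3 * max(bws, na.rm = TRUE)
  if (!is.finite(pad)) pad <- 1
  lo <- min(v) - pad
  hi <- max(v) + pad
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- vapply(seq_len(ncol(v)), function(j) {
    if (is.na(bws[j])) return(rep(0, n_grid))
    stats::density(v[, j], bw = bws[j], from = lo, to = hi, n = n_grid)$y
  }, numeric(n_grid))
  colnames(dens) <- colnames(v)
  structure(list(grid = grid, density = dens, method = ne$method,
                 flat_samples = colnames(v)[is.na(bws)]),
            class = "qc_density")
}

#' @export
print.qc_density <- function(x, ...) {
  cat("Mapped-read density (", x$method, " input): ", ncol(x$density),
      " samples, ", length(x$grid), "-point grid\n", sep = "")
  if (length(x$flat_samples))
    cat("Flat (all-zero) samples:", paste(x$flat_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample GC-bias curves
#'
#' For each sample, a LOWESS fit (tricube-weighted local linear regression,
#' Cleveland's algorithm) of `log2(count + 1)` against gene GC fraction,
#' evaluated at the observed GC values of the genes shared between the count
#' matrix and the annotation. A sample whose curve sits below the others on the
#' high-GC side points to amplification/library-preparation trouble. Counts are
#' fit on the log scale to keep the smoother stable against the heavy right
#' tail of raw counts.
#'
#' @param dataset A `qc_dataset` with annotation.
#' @param f LOWESS smoother span (fraction of points in each window);
#'   default 2/3.
#' @param iter Robustness iterations; default 3.
#' @param delta Interpolation speedup passed to [stats::lowess()]; `NULL`
#'   (default) uses lowess's own 1% -of-range default, `0` forces an exact fit
#'   at every point.
#' @return An object of class `qc_gc` — list with `gc` (sorted abscissae,
#'   shared) and `fit` (matrix, length(gc) x samples) — or a `qc_skip` marker
#'   when no annotation is available.
#' @export
gc_bias <- function(dataset, f = 2/3, iter = 3L, delta = NULL) {
  stopifnot(inherits(dataset, "qc_dataset"))
  if (is.null(dataset$annotation))
    return(structure(list(metric = "gc_bias",
                          reason = "no gene annotation (gene length/GC) supplied"),
                     class = "qc_skip"))
  ann <- dataset$annotation
  keep <- intersect(rownames(dataset$counts), ann$gene_id)
  if (length(keep) < 20L)
    return(structure(list(metric = "gc_bias",
                          reason = sprintf("only %d genes shared with annotation (need >= 20)",
                                           length(keep))),
                     class = "qc_skip"))
  gc <- ann$gc_fraction[match(keep, ann$gene_id)]
  y <- log2(unclass(dataset$counts)[keep, , drop = FALSE] + 1)
  ord <- order(gc)
  gc_sorted <- gc[ord]
  if (is.null(delta)) delta <- 0.01 * diff(range(gc_sorted))
  fit <- vapply(seq_len(ncol(y)), function(j) {
    stats::lowess(gc_sorted, y[ord, j], f = f, iter = iter, delta = delta)$y
  }, numeric(length(keep)))
  colnames(fit) <- colnames(y)
  structure(list(gc = gc_sorted, fit = fit, f = f, iter = iter,
                 genes = keep[ord]),
            class = "qc_gc")
}

#' @export
print.qc_gc <- function(x, ...) {
  cat("GC-bias LOWESS curves: ", ncol(x$fit), " samples over ", length(x$gc),
      " genes (span f = ", round(x$f, 3), ", ", x$iter,
      " robustness iterations)\n", sep = "")
  invisible(x)
}

#' @export
print.qc_skip <- function(x, ...) {
  cat("Metric '", x$metric, "' skipped: ", x$reason, "\n", sep = "")
  invisible(x)
}

# near-matches for friendlier gene-not-found errors
suggest_genes <- function(gene, ids, n = 5L) {
  hits <- utils::head(agrep(gene, ids, max.distance = 0.2, ignore.case = TRUE,
                            value = TRUE), n)
  if (length(hits)) paste0("; near matches: ", paste(hits, collapse = ", ")) else ""
}

#' Expression profile of a single gene
#'
#' Per-sample expression of one gene of interest on the log2 scale. The default
#' source is the input count matrix (`log2(count + 1)`), which keeps the
#' profile sensitive to library-depth collapse — the signature a housekeeping
#' check is after; `values = "normalized"` uses the depth-normalized matrix
#' from [normalized_expression()] instead. Versioned Ensembl ids resolve after
#' suffix stripping.
#'
#' @param dataset A `qc_dataset`.
#' @param gene Gene identifier or symbol as used in the count matrix rows
#'   (".N" version suffix tolerated).
#' @param values `"counts"` (default) or `"normalized"`.
#' @return An object of class `qc_gene_profile`: `gene`, `expression` (named
#'   per-sample vector, log2 scale), `source`.
#' @export
gene_profile <- function(dataset, gene, values = c("counts", "normalized")) {
  stopifnot(inherits(dataset, "qc_dataset"))
  values <- match.arg(values)
  ids <- rownames(dataset$counts)
  g <- strip_version(gene)
  i <- match(g, ids)
  if (is.na(i)) i <- match(g, strip_version(ids))
  if (is.na(i))
    qc_validation_stop("gene '", gene, "' not found in count matrix",
                       suggest_genes(g, ids))
  if (values == "counts") {
    expr <- log2(unclass(dataset$counts)[i, ] + 1)
    src <- "log2(count+1)"
  } else {
    ne <- normalized_expression(dataset)
    j <- match(ids[i], rownames(ne$values))
    if (is.na(j))
      qc_validation_stop("gene '", gene, "' dropped by normalization (no annotation)")
    expr <- if (ne$scale == "linear") log2(ne$values[j, ] + 1) else ne$values[j, ]
    src <- paste0("log2(", ne$method, "+1)")
  }
  structure(list(gene = ids[i], expression = expr, source = src),
            class = "qc_gene_profile")
}

#' @export
print.qc_gene_profile <- function(x, ...) {
  cat("Expression profile of ", x$gene, " [", x$source, "]\n", sep = "")
  print(round(x$expression, 3))
  invisible(x)
}

# Bundled housekeeping identifiers (Ensembl gene ids + symbols); reference
# data, human GRCh38 / mouse GRCm38.
housekeeping_table <- function() {
  data.frame(
    organism = c("human", "human", "mouse", "mouse"),
    symbol = c("GAPDH", "ACTB", "Gapdh", "Actb"),
    ensembl = c("ENSG00000111640", "ENSG00000075624",
                "ENSMUSG00000057666", "ENSMUSG00000029580"),
    stringsAsFactors = FALSE
  )
}

#' Housekeeping-gene expression profiles
#'
#' GAPDH and ACTB are expressed stably and highly across nearly all tissues and
#' conditions, so a sample in which both sit clearly below its peers signals a
#' technical problem rather than biology. Resolves the two genes by Ensembl id
#' or symbol (case-insensitive) for human or mouse; when either cannot be
#' resolved — e.g. a non-Ensembl annotation — the metric is skipped with a
#' pointer to [gene_profile()] for a manual lookup.
#'
#' @param dataset A `qc_dataset` with organism `"human"` or `"mouse"`.
#' @param values Passed to [gene_profile()].
#' @return A list of two `qc_gene_profile`s (GAPDH, ACTB) of class
#'   `qc_housekeeping`, or a `qc_skip` marker.
#' @export
housekeeping_profile <- function(dataset, values = c("counts", "normalized")) {
  stopifnot(inherits(dataset, "qc_dataset"))
  values <- match.arg(values)
  if (!dataset$organism %in% c("human", "mouse"))
    return(structure(list(metric = "housekeeping",
                          reason = "housekeeping lookup only bundled for human and mouse"),
                     class = "qc_skip"))
  hk <- housekeeping_table()
  hk <- hk[hk$organism == dataset$organism, ]
  ids <- strip_version(rownames(dataset$counts))
  resolve <- function(row) {
    i <- match(row$ensembl, ids)
    if (is.na(i)) i <- match(toupper(row$symbol), toupper(ids))
    i
  }
  idx <- vapply(seq_len(nrow(hk)), function(k) resolve(hk[k, ]), integer(1))
  if (anyNA(idx)) {
    missing <- hk$symbol[is.na(idx)]
    return(structure(list(
      metric = "housekeeping",
      reason = paste0("could not resolve ", paste(missing, collapse = " and "),
                      " in the count matrix; use gene_profile() with your ",
                      "annotation's identifier")),
      class = "qc_skip"))
  }
  profiles <- lapply(idx, function(i)
    gene_profile(dataset, rownames(dataset$counts)[i], values = values))
  names(profiles) <- toupper(hk$symbol)
  structure(profiles, class = "qc_housekeeping")
}

#' @export
print.qc_housekeeping <- function(x, ...) {
  cat("Housekeeping expression profiles:\n")
  for (nm in names(x)) {
    cat(" ", nm, "(", x[[nm]]$gene, "):",
        paste(round(x[[nm]]$expression, 2), collapse = " "), "\n")
  }
  invisible(x)
}
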