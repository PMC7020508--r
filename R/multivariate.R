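# Fix component signs so the loading of largest magnitude is positive; makes
# score tables reproducible across BLAS/LAPACK builds.
fix_signs <- function(scores, rotation) {
  for (k in seq_len(ncol(rotation))) {
    j <- which.max(abs(rotation[, k]))
    if (rotation[j, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, rotation = rotation)
}

#' Principal component analysis over samples
#'
#' Samples are the observations, genes the variables; gene columns are centered
#' (never rescaled — rescaling is the z-score step's job) and decomposed. Two
#' modes mirror the two diagnostic views: `"zscored"` expects a row z-scored
#' matrix and shows biology-dominated structure; `"unnormalized"` takes raw
#' counts, where library-size differences dominate the first component — which
#' is exactly how a depth-collapsed outlier separates.
#'
#' @param x Numeric matrix, genes x samples (a z-scored matrix or raw counts
#'   according to `mode`).
#' @param mode `"zscored"` or `"unnormalized"`; recorded in the result.
#' @return An object of class `qc_pca`: list with `scores` (samples x
#'   components), `loadings`, `variance_explained` (fraction per component) and
#'   `mode`.
#' @export
pca_samples <- function(x, mode = c("zscored", "unnormalized")) {
  mode <- match.arg(mode)
  x <- unclass(as.matrix(x))
  if (ncol(x) < 2L) qc_validation_stop("PCA requires at least 2 samples")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ncomp <- min(ncol(x) - 1L, nrow(x))
  scores <- p$x[, seq_len(ncomp), drop = FALSE]
  rot <- p$rotation[, seq_len(ncomp), drop = FALSE]
  fs <- fix_signs(scores, rot)
  ve <- p$sdev[seq_len(ncomp)]^2 / sum(p$sdev^2)
  structure(list(scores = fs$scores, loadings = fs$rotation,
                 variance_explained = ve, mode = mode),
            class = "qc_pca")
}

#' @export
print.qc_pca <- function(x, ...) {
  cat("Sample PCA (", x$mode, "): ", nrow(x$scores), " samples, ",
      ncol(x$scores), " components\n", sep = "")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat("Variance explained (%):", paste(ve, collapse = ", "), "...\n")
  invisible(x)
}

# One standardized MCA-style block per categorical covariate: centered one-hot
# indicators, each level column scaled by 1/sqrt(level frequency).
indicator_block <- function(values, name) {
  f <- factor(values)
  z <- stats::model.matrix(~ f - 1)
  colnames(z) <- paste0(name, "=", levels(f))
  p <- colMeans(z)
  sweep(sweep(z, 2, p, "-"), 2, sqrt(p), "/")
}

block_first_eigenvalue <- function(block) {
  sv <- svd(scale(block, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  sv[1]^2 / (nrow(block) - 1)
}

#' Multiple factor analysis of expression and covariates
#'
#' Attributes between-sample variance to variable groups: the expression block
#' (z-scored genes) and one indicator block per categorical covariate from the
#' phenotype sheet. Each group is balanced by weighting its variables with the
#' inverse of the group's own first eigenvalue (equivalently, dividing the
#' block by `sqrt(lambda1)` so no single group can dominate the global
#' analysis), then a global PCA of the concatenated weighted blocks yields
#' sample scores and, from squared loadings, each group's contribution to each
#' component. A covariate whose group contribution tops component 1 is the
#' leading source of variation — the signature of a batch/protocol effect.
#'
#' When the phenotype sheet has no covariate columns the analysis is skipped
#' (class `qc_mfa_skip`), mirroring a design with no confounding factor to
#' test.
#'
#' @param dataset A `qc_dataset`.
#' @param expression Optional genes x samples matrix for the expression block;
#'   defaults to row z-scored `log2(count + 1)`. Ignored when
#'   `include_expression = FALSE`.
#' @param include_expression Include the expression block as a variable group
#'   (default `TRUE`).
#' @return An object of class `qc_mfa`: `scores`, `variance_explained`,
#'   `group_weights` (1/lambda1 per group), `group_contributions` (groups x
#'   components, columns sum to 1) — or a `qc_mfa_skip` marker.
#' @export
mfa_covariates <- function(dataset, expression = NULL, include_expression = TRUE) {
  stopifnot(inherits(dataset, "qc_dataset"))
  covs <- covariate_names(dataset$pheno)
  if (length(covs) == 0L)
    return(structure(list(reason = "no covariate columns in phenotype sheet"),
                     class = "qc_mfa_skip"))
  n <- ncol(dataset$counts)
  blocks <- list()
  if (include_expression) {
    if (is.null(expression)) expression <- zscore_rows(log2p1(dataset$counts))
    blocks$expression <- t(unclass(as.matrix(expression)))
  }
  for (cv in covs) {
    vals <- dataset$pheno[[cv]]
    if (length(unique(vals)) < 2L) {
      warning("covariate '", cv, "' is constant; dropped from MFA", call. = FALSE)
      next
    }
    blocks[[cv]] <- indicator_block(vals, cv)
  }
  if (length(blocks) == 0L)
    return(structure(list(reason = "no usable (non-constant) variable group"),
                     class = "qc_mfa_skip"))

  lambda1 <- vapply(blocks, block_first_eigenvalue, numeric(1))
  if (any(lambda1 <= 0))
    return(structure(list(reason = "a variable group has zero variance"),
                     class = "qc_mfa_skip"))
  weighted <- mapply(function(b, l1) b / sqrt(l1), blocks, lambda1,
                     SIMPLIFY = FALSE)
  gmat <- do.call(cbind, weighted)
  gmat <- scale(gmat, center = TRUE, scale = FALSE)
  sv <- svd(gmat)
  ncomp <- min(n - 1L, ncol(gmat))
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(scores) <- colnames(dataset$counts)
  colnames(scores) <- paste0("Dim", seq_len(ncomp))
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  fs <- fix_signs(scores, loadings)
  scores <- fs$scores; loadings <- fs$rotation
  grp <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  contrib <- t(vapply(names(blocks), function(g) {
    colSums(loadings[grp == g, , drop = FALSE]^2)
  }, numeric(ncomp)))
  if (ncomp == 1L) contrib <- matrix(contrib, ncol = 1L,
                                     dimnames = list(names(blocks), "Dim1"))
  colnames(contrib) <- paste0("Dim", seq_len(ncomp))
  ve <- sv$d[seq_len(ncomp)]^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 variance_explained = ve,
                 group_weights = 1 / lambda1,
                 group_contributions = contrib,
                 groups = names(blocks)),
            class = "qc_mfa")
}

#' @export
print.qc_mfa <- function(x, ...) {
  cat("Multiple factor analysis:", nrow(x$scores), "samples,",
      length(x$groups), "variable groups\n")
  cat("Component-1 contributions:\n")
  print(round(x$group_contributions[, 1, drop = FALSE], 3))
  invisible(x)
}

#' @export
print.qc_mfa_skip <- function(x, ...) {
  cat("Multiple factor analysis skipped:", x$reason, "\n")
  invisible(x)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Pairwise Euclidean distances between samples over genes (expected input:
#' the log2(count + 1) matrix), agglomerated bottom-up. Complete linkage by
#' default; any `stats::hclust` linkage may be supplied. Replicates of a clean
#' phenotypic group merge early and low; an outlier joins last and high.
#'
#' @param x Numeric matrix, genes x samples, typically on log2(count+1) scale.
#' @param linkage Linkage criterion passed to [stats::hclust()].
#' @return An `hclust` object (merge sequence, heights, leaf order).
#' @export
hcluster_samples <- function(x, linkage = "complete") {
  x <- unclass(as.matrix(x))
  if (ncol(x) < 2L) qc_validation_stop("clustering requires at least 2 samples")
  stats::hclust(stats::dist(t(x), method = "euclidean"), method = linkage)
}

#' Pairwise sample correlation matrix
#'
#' All pairwise Pearson (linear association) or Spearman (rank-based,
#' average-rank ties) coefficients between samples. A heatmap leaf order is
#' derived from Ward linkage on the correlation distance `1 - r`. Zero-variance
#' samples yield undefined coefficients; they are flagged and their entries set
#' to `NA` (diagonal stays 1).
#'
#' @param x Numeric matrix, genes x samples (default pipeline feeds
#'   log2(count + 1)).
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `qc_correlation`: `r` (sample x sample matrix),
#'   `method`, `order` (heatmap leaf order), `undefined` (samples with zero
#'   variance).
#' @export
correlate_samples <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- unclass(as.matrix(x))
  if (ncol(x) < 2L) qc_validation_stop("correlation requires at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  undefined <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x, method = method))
  diag(r) <- 1
  ord <- seq_len(ncol(x))
  if (!anyNA(r)) {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "ward.D2")
    ord <- hc$order
  }
  structure(list(r = r, method = method, order = ord, undefined = undefined),
            class = "qc_correlation")
}

#' @export
print.qc_correlation <- function(x, ...) {
  cat(tools::toTitleCase(x$method), "correlation over", ncol(x$r), "samples\n")
  off <- x$r[upper.tri(x$r)]
  cat("Off-diagonal range: [", round(min(off, na.rm = TRUE), 3), ", ",
      round(max(off, na.rm = TRUE), 3), "]\n", sep = "")
  if (length(x$undefined))
    cat("Undefined (zero-variance) samples:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
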