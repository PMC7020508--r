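#' Run the full expression-based QC analysis
#'
#' The central entry point: assembles the inputs and computes the whole QC
#' surface — per-sample summary statistics, counts-distribution box
#' statistics, mapped-read density (TPM for human/mouse with annotation, the
#' variance-stabilized transform otherwise), housekeeping profiles, PCA on the
#' z-scored and on the un-normalized matrix, multiple factor analysis when
#' covariates exist, hierarchical clustering, Pearson and Spearman correlation
#' matrices, per-sample GC-bias curves, an optional single-gene expression
#' profile, and the advisory outlier flags. Metrics whose prerequisites are
#' missing (no annotation, unresolvable housekeeping genes, no covariates, too
#' few samples) are recorded as skips with reasons, never silent holes.
#'
#' The result is deterministic given inputs and configuration.
#'
#' @param counts Count matrix: a `qc_counts`, a plain matrix, or a file path.
#' @param pheno Phenotype sheet: a `qc_pheno`, data frame, or file path.
#' @param annotation Optional gene annotation (object or path).
#' @param organism `"human"`, `"mouse"` or `"other"`.
#' @param gene Optional gene of interest for an expression profile.
#' @param linkage Hierarchical-clustering linkage (default `"complete"`).
#' @param lowess_f LOWESS span for the GC-bias fit (default 2/3).
#' @param corr_input Matrix feeding the correlation step: `"log"`
#'   (log2(count+1), default), `"raw"`, or `"tpm"`.
#' @param skip Character vector of metric names to skip (any of
#'   `"summary"`, `"distribution"`, `"density"`, `"housekeeping"`, `"pca"`,
#'   `"mfa"`, `"clustering"`, `"correlation"`, `"gc"`, `"flags"`).
#' @param seed RNG seed recorded in the config (the pipeline itself is
#'   deterministic; the seed is kept for provenance and for demo simulation).
#' @return An object of class `qc_report`; see [print.qc_report()],
#'   [summary.qc_report()], [plot.qc_report()], [write_qc_report()].
#' @export
run_qc <- function(counts, pheno, annotation = NULL,
                   organism = c("human", "mouse", "other"),
                   gene = NULL, linkage = "complete", lowess_f = 2/3,
                   corr_input = c("log", "raw", "tpm"),
                   skip = character(), seed = NULL) {
  organism <- match.arg(organism)
  corr_input <- match.arg(corr_input)
  known <- c("summary", "distribution", "density", "housekeeping", "pca",
             "mfa", "clustering", "correlation", "gc", "flags")
  bad <- setdiff(skip, known)
  if (length(bad))
    qc_validation_stop("unknown metric(s) in skip: ", paste(bad, collapse = ", "))

  stage <- "input assembly"
  res <- list()
  skips <- list()
  run_stage <- function(what, expr) {
    stage <<- what
    tryCatch(expr, qc_error = function(e) {
      stop(structure(class = class(e),
                     list(message = paste0("[", what, "] ", conditionMessage(e)),
                          call = NULL)))
    })
  }

  dataset <- run_stage("input assembly",
                       qc_dataset(counts, pheno, annotation, organism))
  lx <- log2p1(dataset$counts)

  if (!"summary" %in% skip)
    res$summary <- run_stage("summary statistics", sample_summary(dataset))
  else skips$summary <- "disabled by configuration"

  if (!"distribution" %in% skip)
    res$distribution <- run_stage("counts distribution", count_distribution(dataset))
  else skips$distribution <- "disabled by configuration"

  if (!"density" %in% skip)
    res$density <- run_stage("mapped-read density", mapped_density(dataset))
  else skips$density <- "disabled by configuration"

  if (!"housekeeping" %in% skip) {
    hk <- run_stage("housekeeping profile", housekeeping_profile(dataset))
    if (inherits(hk, "qc_skip")) skips$housekeeping <- hk$reason
    else res$housekeeping <- hk
  } else skips$housekeeping <- "disabled by configuration"

  if (!"pca" %in% skip) {
    res$pca_zscored <- run_stage("PCA (z-scored)",
                                 pca_samples(zscore_rows(lx), "zscored"))
    res$pca_unnormalized <- run_stage("PCA (un-normalized)",
                                      pca_samples(dataset$counts, "unnormalized"))
  } else skips$pca <- "disabled by configuration"

  if (!"mfa" %in% skip) {
    m <- run_stage("multiple factor analysis", mfa_covariates(dataset))
    if (inherits(m, "qc_mfa_skip")) skips$mfa <- m$reason
    else res$mfa <- m
  } else skips$mfa <- "disabled by configuration"

  if (!"clustering" %in% skip)
    res$clustering <- run_stage("hierarchical clustering",
                                hcluster_samples(lx, linkage = linkage))
  else skips$clustering <- "disabled by configuration"

  if (!"correlation" %in% skip) {
    cmat <- switch(corr_input,
                   log = lx,
                   raw = unclass(dataset$counts)[, , drop = FALSE],
                   tpm = {
                     if (is.null(dataset$annotation))
                       qc_validation_stop("corr_input='tpm' needs an annotation")
                     tpm(dataset$counts, dataset$annotation)
                   })
    res$pearson <- run_stage("Pearson correlation",
                             correlate_samples(cmat, "pearson"))
    res$spearman <- run_stage("Spearman correlation",
                              correlate_samples(cmat, "spearman"))
  } else skips$correlation <- "disabled by configuration"

  if (!"gc" %in% skip) {
    g <- run_stage("GC bias", gc_bias(dataset, f = lowess_f))
    if (inherits(g, "qc_skip")) skips$gc <- g$reason
    else res$gc <- g
  } else skips$gc <- "disabled by configuration"

  if (!is.null(gene))
    res$gene_profile <- run_stage("gene expression profile",
                                  gene_profile(dataset, gene))

  if (!"flags" %in% skip && !is.null(res$summary) &&
      !is.null(res$pca_unnormalized)) {
    fl <- run_stage("outlier flags",
                    flag_outliers(res$summary, res$pca_unnormalized,
                                  res$housekeeping, res$gc))
    if (!is.null(attr(fl, "skipped"))) skips$flags <- attr(fl, "skipped")
    res$flags <- fl
  } else if ("flags" %in% skip) skips$flags <- "disabled by configuration"
  else skips$flags <- "requires summary and PCA metrics"

  config <- list(organism = organism, gene = gene, linkage = linkage,
                 lowess_f = lowess_f, corr_input = corr_input, skip = skip,
                 seed = seed)
  structure(list(dataset = dataset, results = res, skips = skips,
                 config = config,
                 versions = list(exprqc = as.character(utils::packageVersion("exprqc")),
                                 R = paste(R.version$major, R.version$minor, sep = "."))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Expression QC report\n")
  print(x$dataset)
  cat("Computed metrics:", paste(names(x$results), collapse = ", "), "\n")
  if (length(x$skips)) {
    cat("Skipped:\n")
    for (nm in names(x$skips)) cat("  ", nm, ": ", x$skips[[nm]], "\n", sep = "")
  }
  fl <- x$results$flags
  if (!is.null(fl) && nrow(fl)) {
    cat("Outlier flags (advisory):\n")
    print(fl, row.names = FALSE)
  } else if (!is.null(fl)) cat("Outlier flags: none\n")
  invisible(x)
}

#' Summarize a QC report
#'
#' Prints the per-sample summary-statistics table and the flag ensemble, the
#' two things a reader checks first.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return The summary-statistics data frame, invisibly.
#' @export
summary.qc_report <- function(object, ...) {
  s <- object$results$summary
  if (is.null(s)) {
    cat("Summary statistics were skipped.\n")
    return(invisible(NULL))
  }
  print(cbind(s[, "sample", drop = FALSE],
              round(s[, c("mean", "sd", "median", "max", "skewness", "kurtosis")], 2),
              s[, c("library_size", "expressed_genes")]),
        row.names = FALSE)
  fl <- object$results$flags
  if (!is.null(fl) && nrow(fl))
    cat("\nFlagged samples:", paste(unique(fl$sample), collapse = ", "), "\n")
  invisible(s)
}

group_palette <- function(groups) {
  g <- factor(groups)
  cols <- grDevices::hcl.colors(max(3L, nlevels(g)), "Dark 3")[seq_len(nlevels(g))]
  list(col = cols[as.integer(g)], levels = levels(g), palette = cols)
}

#' Plot QC report panels
#'
#' Renders one or all of the report's diagnostic panels on the current
#' graphics device: counts-distribution box plot, mapped-read density,
#' housekeeping profiles, PCA (both modes), MFA factor map, dendrogram,
#' correlation heatmaps, GC-bias curves and the optional gene profile.
#'
#' @param x A `qc_report`.
#' @param which Panel name(s); default all computed panels.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.qc_report <- function(x, which = NULL, ...) {
  panels <- available_panels(x)
  if (is.null(which)) which <- panels
  bad <- setdiff(which, panels)
  if (length(bad))
    qc_validation_stop("unavailable panel(s): ", paste(bad, collapse = ", "))
  for (p in which) draw_panel(x, p)
  invisible(x)
}

available_panels <- function(report) {
  r <- report$results
  p <- character()
  if (!is.null(r$distribution)) p <- c(p, "distribution")
  if (!is.null(r$density)) p <- c(p, "density")
  if (!is.null(r$housekeeping)) p <- c(p, "housekeeping")
  if (!is.null(r$pca_zscored)) p <- c(p, "pca_zscored", "pca_unnormalized")
  if (!is.null(r$mfa)) p <- c(p, "mfa")
  if (!is.null(r$clustering)) p <- c(p, "dendrogram")
  if (!is.null(r$pearson)) p <- c(p, "pearson", "spearman")
  if (!is.null(r$gc)) p <- c(p, "gc")
  if (!is.null(r$gene_profile)) p <- c(p, "gene")
  p
}

draw_panel <- function(report, panel) {
  r <- report$results
  pheno <- report$dataset$pheno
  pal <- group_palette(pheno$group)
  old <- graphics::par(no.readonly = TRUE)[c("mar", "las")]
  on.exit(graphics::par(old), add = TRUE)
  switch(panel,
    distribution = {
      d <- r$distribution
      z <- list(stats = t(as.matrix(d[, c("min", "q1", "median", "q3", "max")])),
                n = rep(1, nrow(d)), conf = NULL, out = numeric(),
                names = d$sample)
      graphics::par(las = 2, mar = c(7, 4, 3, 1))
      graphics::bxp(z, boxfill = pal$col, main = "Counts distribution",
                    ylab = "log2(count + 1)")
    },
    density = {
      de <- r$density
      graphics::matplot(de$grid, de$density, type = "l", lty = 1, col = pal$col,
                        xlab = paste0("log2 expression (", de$method, ")"),
                        ylab = "density", main = "Mapped-read density")
      graphics::legend("topright", legend = pheno$sample, col = pal$col,
                       lty = 1, cex = 0.7, bty = "n")
    },
    housekeeping = {
      hk <- r$housekeeping
      m <- vapply(hk, function(p) p$expression[pheno$sample],
                  numeric(nrow(pheno)))
      graphics::par(las = 2, mar = c(7, 4, 3, 1))
      graphics::barplot(t(m), beside = TRUE, names.arg = pheno$sample,
                        col = c("grey30", "grey70"),
                        main = "Housekeeping expression",
                        ylab = hk[[1]]$source)
      graphics::legend("topright", legend = names(hk),
                       fill = c("grey30", "grey70"), bty = "n", cex = 0.8)
    },
    pca_zscored = draw_pca(r$pca_zscored, pheno, pal, "PCA (z-scored)"),
    pca_unnormalized = draw_pca(r$pca_unnormalized, pheno, pal,
                                "PCA (un-normalized)"),
    mfa = {
      m <- r$mfa
      draw_pca(m, pheno, pal, "Multiple factor analysis")
    },
    dendrogram = {
      graphics::plot(r$clustering, main = "Sample clustering (Euclidean)",
                     xlab = "", sub = "")
    },
    pearson = draw_corr(r$pearson, "Pearson correlation"),
    spearman = draw_corr(r$spearman, "Spearman correlation"),
    gc = {
      g <- r$gc
      graphics::matplot(g$gc, g$fit, type = "l", lty = 1, col = pal$col,
                        xlab = "GC fraction", ylab = "LOWESS log2(count + 1)",
                        main = "GC bias")
      graphics::legend("topleft", legend = pheno$sample, col = pal$col,
                       lty = 1, cex = 0.7, bty = "n")
    },
    gene = {
      gp <- r$gene_profile
      graphics::par(las = 2, mar = c(7, 4, 3, 1))
      graphics::barplot(gp$expression[pheno$sample], names.arg = pheno$sample,
                        col = pal$col, main = paste("Expression of", gp$gene),
                        ylab = gp$source)
    },
    qc_stop("unknown panel: ", panel)
  )
  invisible(NULL)
}

draw_pca <- function(p, pheno, pal, main) {
  s <- p$scores
  ve <- p$variance_explained
  lab <- function(k) sprintf("%s (%.1f%%)",
                             colnames(s)[k] %||% paste0("PC", k), 100 * ve[k])
  if (ncol(s) < 2L) {
    graphics::plot(s[, 1], rep(0, nrow(s)), col = pal$col, pch = 19,
                   xlab = lab(1), ylab = "", main = main)
  } else {
    graphics::plot(s[, 1], s[, 2], col = pal$col, pch = 19,
                   xlab = lab(1), ylab = lab(2), main = main)
  }
  graphics::text(s[, 1], if (ncol(s) < 2L) rep(0, nrow(s)) else s[, 2],
                 labels = rownames(s) %||% pheno$sample, pos = 3, cex = 0.7)
  graphics::legend("topright", legend = pal$levels, col = pal$palette,
                   pch = 19, bty = "n", cex = 0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_corr <- function(cr, main) {
  r <- cr$r[cr$order, cr$order]
  n <- ncol(r)
  graphics::par(las = 2, mar = c(7, 7, 3, 2))
  graphics::image(seq_len(n), seq_len(n), t(r[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blue-Red 2", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  zlim = c(min(r, na.rm = TRUE), 1))
  graphics::axis(1, seq_len(n), colnames(r), cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(r)), cex.axis = 0.7)
  graphics::box()
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a QC report to disk
#'
#' Serializes every computed metric as a tab-separated table, renders the plot
#' catalogue as one figure file per panel, and writes a `report.json` manifest
#' with configuration (and its hash), package versions, skip reasons and the
#' outlier-flag list. Output is byte-stable given the same inputs and
#' configuration.
#'
#' @param report A `qc_report`.
#' @param outdir Output directory (created if needed).
#' @param format `"png"` or `"pdf"` figures.
#' @return `outdir`, invisibly.
#' @export
write_qc_report <- function(report, outdir, format = c("png", "pdf")) {
  format <- match.arg(format)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  r <- report$results
  pheno <- report$dataset$pheno

  if (!is.null(r$summary))
    write_tsv(r$summary, file.path(outdir, "summary_statistics.tsv"))
  if (!is.null(r$distribution))
    write_tsv(r$distribution, file.path(outdir, "count_distribution.tsv"))
  if (!is.null(r$density)) {
    de <- r$density
    long <- data.frame(sample = rep(colnames(de$density), each = length(de$grid)),
                       x = rep(de$grid, ncol(de$density)),
                       y = as.vector(de$density))
    write_tsv(long, file.path(outdir, "mapped_read_density.tsv"))
  }
  if (!is.null(r$housekeeping)) {
    hk <- r$housekeeping
    df <- data.frame(sample = pheno$sample,
                     vapply(hk, function(p) p$expression[pheno$sample],
                            numeric(nrow(pheno))),
                     check.names = FALSE)
    write_tsv(df, file.path(outdir, "housekeeping_expression.tsv"))
  }
  for (mode in c("pca_zscored", "pca_unnormalized")) {
    if (is.null(r[[mode]])) next
    p <- r[[mode]]
    df <- data.frame(sample = rownames(p$scores), p$scores, check.names = FALSE)
    write_tsv(df, file.path(outdir, paste0(mode, "_scores.tsv")))
    write_tsv(data.frame(component = seq_along(p$variance_explained),
                         variance_explained = p$variance_explained),
              file.path(outdir, paste0(mode, "_variance.tsv")))
  }
  if (!is.null(r$mfa)) {
    m <- r$mfa
    write_tsv(data.frame(sample = rownames(m$scores), m$scores,
                         check.names = FALSE),
              file.path(outdir, "mfa_scores.tsv"))
    write_tsv(data.frame(group = rownames(m$group_contributions),
                         m$group_contributions, check.names = FALSE),
              file.path(outdir, "mfa_group_contributions.tsv"))
  }
  if (!is.null(r$clustering)) {
    hc <- r$clustering
    write_tsv(data.frame(step = seq_len(nrow(hc$merge)),
                         left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height),
              file.path(outdir, "clustering_merges.tsv"))
  }
  for (meth in c("pearson", "spearman")) {
    if (is.null(r[[meth]])) next
    write_tsv(data.frame(sample = rownames(r[[meth]]$r), r[[meth]]$r,
                         check.names = FALSE),
              file.path(outdir, paste0(meth, "_correlation.tsv")))
  }
  if (!is.null(r$gc)) {
    g <- r$gc
    long <- data.frame(sample = rep(colnames(g$fit), each = length(g$gc)),
                       x = rep(g$gc, ncol(g$fit)), y = as.vector(g$fit))
    write_tsv(long, file.path(outdir, "gc_bias.tsv"))
  }
  if (!is.null(r$gene_profile)) {
    gp <- r$gene_profile
    write_tsv(data.frame(sample = names(gp$expression),
                         expression = gp$expression, gene = gp$gene),
              file.path(outdir, "gene_expression.tsv"))
  }
  if (!is.null(r$flags))
    write_tsv(r$flags, file.path(outdir, "outlier_flags.tsv"))

  for (panel in available_panels(report)) {
    fp <- file.path(outdir, paste0(panel, ".", format))
    ok <- tryCatch({
      if (format == "png") grDevices::png(fp, width = 900, height = 700)
      else grDevices::pdf(fp, width = 8, height = 6.5)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      warning("could not open ", format, " device for panel ", panel,
              call. = FALSE)
      next
    }
    tryCatch(draw_panel(report, panel), finally = grDevices::dev.off())
  }
  if (length(report$skips))
    writeLines(paste0(names(report$skips), ": ", unlist(report$skips)),
               file.path(outdir, "skipped_metrics.txt"))

  cfg_json <- jsonlite::toJSON(report$config, auto_unbox = TRUE, null = "null")
  tf <- tempfile()
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- list(
    config = report$config,
    config_hash = cfg_hash,
    versions = report$versions,
    samples = pheno$sample,
    groups = pheno$group,
    computed = names(r),
    skipped = report$skips,
    flags = if (!is.null(r$flags)) r$flags else list()
  )
  jsonlite::write_json(manifest, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
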