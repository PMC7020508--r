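# Robust z-scores: (x - median) / max(MAD, floor). The floor is a
# technical-tolerance width per statistic: when all samples agree to within it,
# nobody can be flagged no matter how small the MAD gets.
robust_z <- function(x, floor) {
  s <- max(stats::mad(x), floor)
  (x - stats::median(x)) / s
}

#' Advisory outlier flags from the QC ensemble
#'
#' Codifies the "read the metrics as a whole" judgment into four independent
#' rules, each a robust z-score (median/MAD) on one per-sample statistic:
#'
#' * `low_library_size` — `log2(library size)` below -2.5 (MAD floored at 0.2,
#'   i.e. ~15% depth variation is normal);
#' * `low_housekeeping` — mean log2 housekeeping (GAPDH/ACTB) expression below
#'   -2.5 (floor 0.5: two genes are noisy);
#' * `pc1_leverage` — the fraction of the *total* between-sample variance the
#'   sample carries along un-normalized PC1 (`score_i1^2 / sum(all scores^2)`)
#'   above +2.5 (floor 0.1). Normalizing by total variance rather than by the
#'   PC1 sum of squares matters: in a homogeneous experiment PC1 always points
#'   at whichever sample happens to be most variable, so that sample's share
#'   *of PC1* is large by construction, while its share of the total variance
#'   stays small; only a genuine depth/scale outlier concentrates a large part
#'   of all variance on one component of one sample;
#' * `gc_depressed` — mean of the sample's GC-bias curve below -2.5 (floor
#'   0.25).
#'
#' Rules are evaluated independently and the union reported. Flags are
#' advisory only: they never remove a sample — a flagged sample should be
#' inspected, and excluded (if at all) by editing the phenotype sheet. With
#' fewer than 4 samples the MAD is too unstable and the heuristic is skipped.
#'
#' @param summary Output of [sample_summary()].
#' @param pca_raw Output of `pca_samples(counts, "unnormalized")`.
#' @param housekeeping Optional [housekeeping_profile()] result.
#' @param gc Optional [gc_bias()] result.
#' @param threshold Robust z cutoff; default 2.5.
#' @return A `data.frame` with columns `sample`, `rule`, `statistic`,
#'   `robust_z`, `threshold`; zero rows when nothing is flagged. Attribute
#'   `skipped` carries a reason when the heuristic could not run.
#' @export
flag_outliers <- function(summary, pca_raw, housekeeping = NULL, gc = NULL,
                          threshold = 2.5) {
  empty <- data.frame(sample = character(), rule = character(),
                      statistic = numeric(), robust_z = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  n <- nrow(summary)
  if (n < 4L) {
    attr(empty, "skipped") <- "fewer than 4 samples: median/MAD rules unstable"
    return(empty)
  }
  samples <- summary$sample
  flags <- list()
  add <- function(rule, stat, z, hit) {
    if (!any(hit)) return()
    flags[[length(flags) + 1L]] <<- data.frame(
      sample = samples[hit], rule = rule, statistic = stat[hit],
      robust_z = z[hit], threshold = threshold, stringsAsFactors = FALSE)
  }

  libsize <- log2(summary$library_size + 1)
  z <- robust_z(libsize, floor = 0.2)
  add("low_library_size", libsize, z, z < -threshold)

  if (inherits(housekeeping, "qc_housekeeping")) {
    hk <- rowMeans(vapply(housekeeping, function(p) p$expression[samples],
                          numeric(n)))
    z <- robust_z(hk, floor = 0.5)
    add("low_housekeeping", hk, z, z < -threshold)
  }

  sc <- pca_raw$scores[samples, , drop = FALSE]
  share <- sc[, 1]^2 / sum(sc^2)
  z <- robust_z(share, floor = 0.1)
  add("pc1_leverage", share, z, z > threshold)

  if (inherits(gc, "qc_gc")) {
    gcmean <- colMeans(gc$fit)[samples]
    z <- robust_z(gcmean, floor = 0.25)
    add("gc_depressed", gcmean, z, z < -threshold)
  }

  if (length(flags) == 0L) return(empty)
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
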