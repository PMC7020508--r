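moment_skewness <- function(x) {
  m <- mean(x); c2 <- mean((x - m)^2)
  if (c2 == 0) return(0)
  mean((x - m)^3) / c2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x); c2 <- mean((x - m)^2)
  if (c2 == 0) return(0)
  mean((x - m)^4) / c2^2 - 3
}

#' Per-sample summary statistics
#'
#' One row per sample, computed on the raw count scale: number of detected
#' genes (rows of the matrix), mean, standard deviation, median, minimum,
#' maximum and range of expression, skewness (symmetry of the expression
#' distribution), kurtosis (heaviness of its tails), library size (column sum)
#' and number of expressed genes (count > 0). A sample whose values sit far
#' below its group's — low library size, few expressed genes, depressed mean —
#' is the first sign of an outlier.
#'
#' Skewness is the population moment coefficient `m3 / m2^1.5` and kurtosis the
#' population excess `m4 / m2^2 - 3`; both are defined as 0 for zero-spread
#' columns. The standard deviation uses the usual n-1 divisor.
#'
#' @param dataset A `qc_dataset`.
#' @return A `data.frame`, one row per sample, columns `sample`,
#'   `detected_genes`, `mean`, `sd`, `median`, `min`, `max`, `range`,
#'   `skewness`, `kurtosis`, `library_size`, `expressed_genes`.
#' @export
sample_summary <- function(dataset) {
  stopifnot(inherits(dataset, "qc_dataset"))
  x <- unclass(dataset$counts)[, , drop = FALSE]
  out <- data.frame(
    sample = colnames(x),
    detected_genes = nrow(x),
    mean = apply(x, 2, mean),
    sd = apply(x, 2, stats::sd),
    median = apply(x, 2, stats::median),
    min = apply(x, 2, min),
    max = apply(x, 2, max),
    range = apply(x, 2, function(v) max(v) - min(v)),
    skewness = apply(x, 2, moment_skewness),
    kurtosis = apply(x, 2, moment_kurtosis),
    library_size = colSums(x),
    expressed_genes = colSums(x > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Counts-distribution box statistics
#'
#' Five-number summary (min, Q1, median, Q3, max) of each sample's expression
#' on the log2(count + 1) scale — the numbers behind the counts-distribution
#' box plot. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7), which differs from Tukey box-plot hinges.
#'
#' @param dataset A `qc_dataset`.
#' @return A `data.frame` with columns `sample`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
count_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "qc_dataset"))
  lx <- log2p1(dataset$counts)
  q <- t(apply(lx, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
               names = FALSE, type = 7))
  data.frame(sample = colnames(lx), min = q[, 1], q1 = q[, 2], median = q[, 3],
             q3 = q[, 4], max = q[, 5], row.names = NULL,
             stringsAsFactors = FALSE)
}
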