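#' Define a count-simulation scenario
#'
#' Parameters of the negative-binomial RNA-seq count generator used to exercise
#' every QC metric with known ground truth. Per-gene baseline means are
#' lognormal; each sample's expected counts are
#' `L_s * mu_g * exp(beta_g * x_group + sum_c gamma_{g, level_c(s)} +
#' gc_slope_s * (gc_g - 0.5) + eps)`, with `L_s` a per-sample library scale,
#' `beta_g` group (phenotype) effects on a subset of genes, `gamma` gene-level
#' effects of categorical covariates (protocol, flow cell, ...), a per-sample
#' linear GC artifact on the log-mean, and optional extra per-sample
#' "biological" lognormal noise. Counts are drawn NB(mean, size = 1/dispersion).
#'
#' @param n_genes Number of genes.
#' @param groups Character vector, one phenotype label per sample.
#' @param mu_meanlog,mu_sdlog Lognormal parameters of per-gene baseline means.
#' @param dispersion NB dispersion (1/size), shared across genes by default;
#'   may be a per-gene vector.
#' @param frac_de Fraction of genes carrying a group effect.
#' @param de_sd SD of the (log-scale) group effects.
#' @param library_scale Per-sample library scale factors (default all 1).
#' @param gc_slope Per-sample slope of the GC artifact on the log-mean
#'   (default all 0).
#' @param biological_noise Per-sample SD of extra gene-level lognormal noise
#'   (default all 0) — inflates within-group variability without any technical
#'   defect.
#' @param covariates Named list: each element a character vector of per-sample
#'   covariate levels.
#' @param covariate_sd Named numeric: SD of gene-level log effects per
#'   covariate.
#' @param length_meanlog,length_sdlog Lognormal parameters of gene lengths
#'   (bp, floored at 200).
#' @param seed Default RNG seed used by [simulate_counts()].
#' @return A `qc_scenario` list.
#' @export
qc_scenario <- function(n_genes = 2000L,
                        groups = rep(c("control", "diseased"), each = 4L),
                        mu_meanlog = 3, mu_sdlog = 1.2,
                        dispersion = 0.1,
                        frac_de = 0.1, de_sd = 0.7,
                        library_scale = rep(1, length(groups)),
                        gc_slope = rep(0, length(groups)),
                        biological_noise = rep(0, length(groups)),
                        covariates = list(),
                        covariate_sd = numeric(),
                        length_meanlog = log(1500), length_sdlog = 0.7,
                        seed = 1L) {
  n_samples <- length(groups)
  stopifnot(n_genes >= 2L, n_samples >= 2L,
            length(library_scale) == n_samples,
            length(gc_slope) == n_samples,
            length(biological_noise) == n_samples)
  if (any(library_scale <= 0)) qc_validation_stop("library_scale must be > 0")
  if (any(dispersion <= 0)) qc_validation_stop("dispersion must be > 0")
  if (length(covariates)) {
    stopifnot(!is.null(names(covariates)),
              all(lengths(covariates) == n_samples),
              all(names(covariates) %in% names(covariate_sd)))
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 dispersion = dispersion, frac_de = frac_de, de_sd = de_sd,
                 library_scale = library_scale, gc_slope = gc_slope,
                 biological_noise = biological_noise,
                 covariates = covariates, covariate_sd = covariate_sd,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 seed = as.integer(seed)),
            class = "qc_scenario")
}

#' Simulate a count matrix, phenotype sheet and gene annotation
#'
#' Draws one dataset from a scenario (see [qc_scenario()]): NB counts with the
#' scenario's planted artifacts, a phenotype sheet carrying group and covariate
#' columns, and an annotation with lognormal gene lengths and Beta(5, 5) GC
#' fractions. Gene ids are `gene0001`... plus two rows named after the human
#' housekeeping genes (GAPDH, ACTB) drawn from the top of the baseline
#' distribution, so housekeeping and TPM metrics are exercisable. Output is
#' byte-reproducible given the seed.
#'
#' @param scenario A `qc_scenario`.
#' @param seed RNG seed; defaults to the scenario's.
#' @return List with `counts` (`qc_counts`), `pheno` (`qc_pheno`),
#'   `annotation` (`qc_annotation`).
#' @export
simulate_counts <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "qc_scenario"))
  set.seed(seed)
  ng <- scenario$n_genes
  ns <- length(scenario$groups)
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  sample_ids <- paste0(scenario$groups, ave(seq_len(ns), scenario$groups,
                                            FUN = seq_along))

  mu <- stats::rlnorm(ng, scenario$mu_meanlog, scenario$mu_sdlog)
  # plant the two human housekeeping genes among the most abundant baselines
  hk_rows <- order(mu, decreasing = TRUE)[1:2]
  gene_ids[hk_rows] <- c("GAPDH", "ACTB")

  gc <- stats::rbeta(ng, 5, 5)
  len <- pmax(200, round(stats::rlnorm(ng, scenario$length_meanlog,
                                       scenario$length_sdlog)))

  beta <- numeric(ng)
  n_de <- round(scenario$frac_de * ng)
  if (n_de > 0) {
    de_idx <- sample.int(ng, n_de)
    beta[de_idx] <- stats::rnorm(n_de, 0, scenario$de_sd)
  }
  glev <- scenario$groups
  ref_group <- glev[1]

  # gene x level effect tables per covariate
  cov_eff <- lapply(names(scenario$covariates), function(cv) {
    levs <- unique(scenario$covariates[[cv]])
    eff <- matrix(stats::rnorm(ng * length(levs), 0, scenario$covariate_sd[[cv]]),
                  nrow = ng, dimnames = list(NULL, levs))
    eff
  })
  names(cov_eff) <- names(scenario$covariates)

  size <- 1 / scenario$dispersion
  counts <- matrix(0L, nrow = ng, ncol = ns, dimnames = list(gene_ids, sample_ids))
  for (s in seq_len(ns)) {
    logfc <- ifelse(glev[s] == ref_group, 0, 1) * beta
    for (cv in names(cov_eff))
      logfc <- logfc + cov_eff[[cv]][, scenario$covariates[[cv]][s]]
    logfc <- logfc + scenario$gc_slope[s] * (gc - 0.5)
    if (scenario$biological_noise[s] > 0)
      logfc <- logfc + stats::rnorm(ng, 0, scenario$biological_noise[s])
    m <- scenario$library_scale[s] * mu * exp(logfc)
    counts[, s] <- stats::rnbinom(ng, mu = m, size = size)
  }

  pheno <- data.frame(sample = sample_ids, group = scenario$groups,
                      stringsAsFactors = FALSE)
  for (cv in names(scenario$covariates)) pheno[[cv]] <- scenario$covariates[[cv]]

  list(counts = as_counts(counts),
       pheno = as_phenotype(pheno),
       annotation = as_annotation(data.frame(gene_id = gene_ids,
                                             length_bp = len,
                                             gc_fraction = gc,
                                             stringsAsFactors = FALSE)))
}

#' Named demonstration scenarios
#'
#' Four presets with the planted structures the QC surface is meant to detect:
#'
#' * `A` — clean two-group design (2 x 4 samples), no artifacts: the negative
#'   control.
#' * `B` — same design, but one control sample has its library collapsed to 5%
#'   of the others and a depressed high-GC response (`gc_slope = -1.5`),
#'   emulating a failed library prep; one diseased sample carries extra
#'   biological noise (sd 0.35) so it wanders within its group without any
#'   technical defect. The QC ensemble should flag the first and not the
#'   second.
#' * `C` — three growth conditions across 12 samples with `protocol` (2
#'   levels, gene-effect sd 0.5) and `flow_cell` (3 levels, sd 0.15)
#'   covariates dominating a weak condition effect: MFA should attribute
#'   component 1 to protocol.
#' * `D` — two cell types crossed with an RNA `extraction` covariate (sd 0.6)
#'   that overwhelms the cell-type effect (sd 0.2): samples cluster by
#'   extraction method, not biology.
#'
#' @return Named list of `qc_scenario` objects.
#' @export
scenario_presets <- function() {
  base_groups <- rep(c("control", "diseased"), each = 4L)
  list(
    A = qc_scenario(groups = base_groups),
    B = qc_scenario(groups = base_groups,
                    library_scale = c(1, 1, 1, 0.05, 1, 1, 1, 1),
                    gc_slope = c(0, 0, 0, -1.5, 0, 0, 0, 0),
                    biological_noise = c(0, 0, 0, 0, 0, 0, 0.35, 0)),
    C = qc_scenario(groups = rep(c("YPD", "Delft", "YPGly"), each = 4L),
                    frac_de = 0.05, de_sd = 0.3,
                    covariates = list(
                      protocol = rep(c("prep1", "prep2"), 6L),
                      flow_cell = rep(c("fc1", "fc2", "fc3"), each = 4L)),
                    covariate_sd = c(protocol = 0.5, flow_cell = 0.15)),
    D = qc_scenario(groups = rep(c("Bcell", "monocyte"), each = 4L),
                    frac_de = 0.1, de_sd = 0.2,
                    covariates = list(
                      extraction = rep(c("PolyA+", "PolyA+", "PolyA-", "PolyA-"), 2L)),
                    covariate_sd = c(extraction = 0.6))
  )
}
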