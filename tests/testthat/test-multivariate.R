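test_that("sample PCA matches the covariance-eigendecomposition oracle", {
  set.seed(101)
  for (rep in 1:3) {
    m <- matrix(rnorm(20 * 5, sd = 3), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("S", 1:5)))
    p <- pca_samples(m, "zscored")
    ncomp <- ncol(p$scores)
    expect_equal(ncomp, 4L)  # min(n-1, p)
    oracle <- oracle_pca_scores(m, ncomp)
    expect_lt(max(abs(unname(p$scores) - unname(oracle))), 1e-8)
    expect_true(all(p$variance_explained >= 0))
    expect_lt(sum(p$variance_explained), 1 + 1e-9)
    expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  }
})

test_that("PCA collapses duplicated samples and is gene-order invariant", {
  set.seed(7)
  m <- matrix(rpois(30 * 4, 40), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("S", 1:4)))
  m <- cbind(m, S5 = m[, "S2"])  # duplicate sample
  p <- pca_samples(m, "unnormalized")
  expect_equal(unname(p$scores["S2", ]), unname(p$scores["S5", ]),
               tolerance = 1e-10)
  # relabeling genes changes nothing (scores fixed up to the sign rule)
  perm <- sample(nrow(m))
  p2 <- pca_samples(m[perm, ], "unnormalized")
  expect_equal(unname(p2$scores), unname(p$scores), tolerance = 1e-8)
  expect_error(pca_samples(m[, 1, drop = FALSE]), "2 samples")
})

test_that("MFA skips without covariates and recovers duplicate-group symmetry", {
  ds <- tiny_dataset(n_genes = 30, n_samples = 6)
  m <- mfa_covariates(ds)
  expect_s3_class(m, "qc_mfa_skip")
  expect_match(m$reason, "covariate")

  # two identical copies of the same variable group: equal weights, scores
  # proportional to single-group PCA scores
  set.seed(31)
  expr <- matrix(rnorm(40 * 6), nrow = 40,
                 dimnames = list(paste0("g", 1:40), paste0("S", 1:6)))
  ph <- data.frame(sample = paste0("S", 1:6),
                   group = rep(c("a", "b"), 3),
                   batch = rep(c("x", "y"), each = 3),
                   stringsAsFactors = FALSE)
  ds2 <- qc_dataset(as_counts(matrix(rpois(40 * 6, 20), 40,
                                     dimnames = dimnames(expr))),
                    as_phenotype(ph), organism = "other")
  z <- zscore_rows(expr)
  m1 <- mfa_covariates(ds2, expression = z, include_expression = TRUE)
  expect_s3_class(m1, "qc_mfa")
  expect_equal(unname(colSums(m1$group_contributions)),
               rep(1, ncol(m1$group_contributions)), tolerance = 1e-9)
  expect_true(all(m1$group_weights > 0))

  # duplicated block: build a dataset whose only covariates are two copies
  ph3 <- data.frame(sample = paste0("S", 1:6),
                    group = rep(c("a", "b"), 3),
                    cov1 = rep(c("x", "y"), each = 3),
                    cov2 = rep(c("x", "y"), each = 3),
                    stringsAsFactors = FALSE)
  ds3 <- qc_dataset(ds2$counts, as_phenotype(ph3), organism = "other")
  m3 <- mfa_covariates(ds3, include_expression = FALSE)
  expect_equal(unname(m3$group_weights[1]), unname(m3$group_weights[2]))
  single <- mfa_covariates(
    qc_dataset(ds2$counts, as_phenotype(ph3[, c("sample", "group", "cov1")]),
               organism = "other"),
    include_expression = FALSE)
  r1 <- m3$scores[, 1] / sqrt(sum(m3$scores[, 1]^2))
  r2 <- single$scores[, 1] / sqrt(sum(single$scores[, 1]^2))
  expect_lt(min(max(abs(r1 - r2)), max(abs(r1 + r2))), 1e-9)

  # constant covariate is dropped with a warning
  ph4 <- ph
  ph4$batch <- "same"
  ds4 <- qc_dataset(ds2$counts, as_phenotype(ph4), organism = "other")
  expect_warning(m4 <- mfa_covariates(ds4, expression = z), "constant")
  expect_false("batch" %in% m4$groups)
})

test_that("hierarchical clustering agrees with exhaustive agglomeration", {
  # 2 samples: single merge at their Euclidean distance
  m <- cbind(A = c(0, 0), B = c(3, 4))
  rownames(m) <- c("g1", "g2")
  hc <- hcluster_samples(m)
  expect_equal(hc$height, 5)

  # two tight pairs far apart: first two merges join the pairs
  set.seed(5)
  base <- matrix(rnorm(20), nrow = 10)
  m4 <- cbind(A1 = base[, 1], A2 = base[, 1] + rnorm(10, 0, .01),
              B1 = base[, 2] + 50, B2 = base[, 2] + 50 + rnorm(10, 0, .01))
  rownames(m4) <- paste0("g", 1:10)
  hc4 <- hcluster_samples(m4)
  members <- hclust_merge_members(hc4)
  expect_setequal(lapply(members[1:2], identity), list(c(1L, 2L), c(3L, 4L)))
  # heights monotone non-decreasing for complete linkage
  expect_true(all(diff(hc4$height) >= 0))
  # full agreement with the brute-force oracle
  oracle <- oracle_agglomerate(t(m4), "complete")
  expect_equal(members, oracle$members)
  expect_equal(hc4$height, oracle$heights, tolerance = 1e-12)

  # duplicated sample merges first at height zero
  m5 <- cbind(m4, A1bis = m4[, "A1"])
  hc5 <- hcluster_samples(m5)
  expect_equal(hc5$height[1], 0)
  expect_equal(hclust_merge_members(hc5)[[1]], c(1L, 5L))
})

test_that("correlation matrices match closed forms and rank invariances", {
  set.seed(8)
  m <- matrix(rlnorm(30 * 3), nrow = 30,
              dimnames = list(paste0("g", 1:30), c("A", "B", "C")))
  cr <- correlate_samples(m, "pearson")
  expect_equal(diag(cr$r), c(A = 1, B = 1, C = 1))
  expect_identical(cr$r, t(cr$r))
  # entrywise closed-form oracle: cov / (sd * sd)
  for (i in 1:3) for (j in 1:3) {
    num <- mean((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j])))
    expect_equal(cr$r[i, j],
                 num / (sqrt(mean((m[, i] - mean(m[, i]))^2)) *
                          sqrt(mean((m[, j] - mean(m[, j]))^2))),
                 tolerance = 1e-12)
  }

  # monotone nonlinear transform: Spearman 1, Pearson < 1
  m2 <- cbind(A = m[, 1], B = m[, 1]^3)
  rownames(m2) <- rownames(m)
  expect_equal(correlate_samples(m2, "spearman")$r["A", "B"], 1)
  expect_lt(correlate_samples(m2, "pearson")$r["A", "B"], 1)
  # Spearman invariant under strictly monotone per-sample transforms
  m3 <- m; m3[, 2] <- exp(m3[, 2]); m3[, 3] <- sqrt(m3[, 3])
  expect_equal(correlate_samples(m3, "spearman")$r,
               correlate_samples(m, "spearman")$r)

  # zero-variance sample flagged with NA coefficients
  m4 <- cbind(m, flat = rep(2, 30))
  cr4 <- correlate_samples(m4, "pearson")
  expect_equal(cr4$undefined, "flat")
  expect_true(anyNA(cr4$r["flat", c("A", "B", "C")]))
  expect_equal(cr4$r["flat", "flat"], 1)
})
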