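test_that("density curves integrate to ~1, are deterministic and permutation-invariant", {
  cm <- tiny_counts(n_genes = 80, n_samples = 4, seed = 17)
  ph <- tiny_pheno(colnames(cm))
  ds <- qc_dataset(cm, ph, organism = "other")
  de <- mapped_density(ds)
  expect_equal(de$method, "vst_like")
  trap <- apply(de$density, 2, function(y)
    sum(diff(de$grid) * (head(y, -1) + tail(y, -1)) / 2))
  expect_true(all(trap >= 0.95 & trap <= 1.05))
  expect_true(all(de$density >= 0))
  # identical samples produce identical curves; gene order irrelevant
  perm <- sample(nrow(cm))
  ds_perm <- qc_dataset(as_counts(unclass(cm)[perm, , drop = FALSE]), ph,
                        organism = "other")
  expect_equal(mapped_density(ds_perm)$density, de$density)

  cm2 <- unclass(cm); cm2 <- cbind(cm2, S4bis = cm2[, 4])
  ds2 <- qc_dataset(as_counts(cm2), tiny_pheno(colnames(cm2)), organism = "other")
  de2 <- mapped_density(ds2)
  expect_equal(de2$density[, "S4"], de2$density[, "S4bis"],
               ignore_attr = TRUE)
})

test_that("a library-collapsed sample's density mode shifts left", {
  presets <- scenario_presets()
  sim <- simulate_counts(presets$B, seed = 2)
  ds <- qc_dataset(sim$counts, sim$pheno, sim$annotation, "human")
  de <- mapped_density(ds)
  expect_equal(de$method, "tpm")
  modes <- setNames(de$grid[apply(de$density, 2, which.max)],
                    colnames(de$density))
  expect_lt(modes["control4"], min(modes[setdiff(names(modes), "control4")]))
})

test_that("LOWESS GC curves match the local weighted least-squares oracle", {
  set.seed(23)
  n <- 50
  gc <- sort(runif(n, 0.25, 0.75))
  counts <- matrix(rpois(2 * n, exp(3 + 2 * gc)), ncol = 2,
                   dimnames = list(sprintf("g%03d", 1:n), c("S1", "S2")))
  ds <- qc_dataset(as_counts(counts),
                   tiny_pheno(c("S1", "S2")),
                   as_annotation(data.frame(gene_id = rownames(counts),
                                            length_bp = 1000,
                                            gc_fraction = gc)),
                   organism = "other")
  g <- gc_bias(ds, f = 2/3, iter = 0L, delta = 0)
  for (s in 1:2) {
    oracle <- oracle_lowess(g$gc, log2(counts[g$genes, s] + 1), f = 2/3)
    expect_lt(max(abs(g$fit[, s] - oracle)), 1e-8)
  }
})

test_that("GC curves are flat for constant counts and track planted trends", {
  n <- 60
  gc <- seq(0.2, 0.8, length.out = n)
  const <- matrix(7, nrow = n, ncol = 2,
                  dimnames = list(sprintf("g%03d", 1:n), c("S1", "S2")))
  ann <- as_annotation(data.frame(gene_id = rownames(const), length_bp = 500,
                                  gc_fraction = gc))
  ds <- qc_dataset(as_counts(const), tiny_pheno(c("S1", "S2")), ann, "other")
  g <- gc_bias(ds, delta = 0)
  expect_lt(max(abs(g$fit - log2(8))), 1e-6)

  # exponential-in-GC counts: fitted curve monotone increasing (rank corr ~ 1)
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    gcr <- sort(runif(200, 0.2, 0.8))
    y <- matrix(rpois(2 * 200, exp(2 + 3 * gcr)), ncol = 2,
                dimnames = list(sprintf("g%03d", 1:200), c("S1", "S2")))
    dsr <- qc_dataset(as_counts(y), tiny_pheno(c("S1", "S2")),
                      as_annotation(data.frame(gene_id = rownames(y),
                                               length_bp = 500,
                                               gc_fraction = gcr)), "other")
    gr <- gc_bias(dsr)
    hits <- hits + (cor(gr$fit[, 1], gr$gc, method = "spearman") > 0.99)
  }
  expect_gte(hits, 19L)
})

test_that("a GC-suppressed sample's curve drops below the others at high GC", {
  sim <- simulate_counts(scenario_presets()$B, seed = 4)
  ds <- qc_dataset(sim$counts, sim$pheno, sim$annotation, "human")
  g <- gc_bias(ds)
  high <- g$gc > 0.6
  out_curve <- g$fit[high, "control4"]
  others <- g$fit[high, setdiff(colnames(g$fit), "control4")]
  expect_true(all(out_curve < apply(others, 1, min)))
})

test_that("GC bias is skipped without annotation or with tiny intersections", {
  ds <- tiny_dataset(n_genes = 30, n_samples = 4)
  expect_s3_class(gc_bias(ds), "qc_skip")
  cm <- tiny_counts(n_genes = 30, n_samples = 4)
  ann <- tiny_annotation(rownames(cm)[1:5])
  ds2 <- qc_dataset(cm, tiny_pheno(colnames(cm)), ann, "other")
  sk <- gc_bias(ds2)
  expect_s3_class(sk, "qc_skip")
  expect_match(sk$reason, "20")
})

test_that("gene profiles recompute log2(x+1) and resolve versioned ids", {
  cm <- tiny_counts(n_genes = 10, n_samples = 4, seed = 2)
  rn <- rownames(unclass(cm))
  rn[1] <- "ENSG000001"
  m <- unclass(cm)[, , drop = FALSE]
  rownames(m) <- rn
  ds <- qc_dataset(as_counts(m), tiny_pheno(colnames(m)), organism = "other")
  gp <- gene_profile(ds, "ENSG000001.7")   # versioned query, unversioned row
  expect_equal(gp$expression, log2(m["ENSG000001", ] + 1))
  expect_error(gene_profile(ds, "nosuchgene"), "not found")

  zero <- m; zero["g02", ] <- 0
  ds0 <- qc_dataset(as_counts(zero), tiny_pheno(colnames(m)), organism = "other")
  expect_equal(unname(gene_profile(ds0, "g02")$expression), rep(0, 4))
})

test_that("housekeeping profiles resolve by symbol or Ensembl id, else skip", {
  sim <- simulate_counts(scenario_presets()$A, seed = 6)
  ds <- qc_dataset(sim$counts, sim$pheno, sim$annotation, "human")
  hk <- housekeeping_profile(ds)
  expect_s3_class(hk, "qc_housekeeping")
  expect_named(hk, c("GAPDH", "ACTB"))
  expect_length(hk$GAPDH$expression, 8L)

  # matrix keyed by Ensembl ids resolves too
  m <- unclass(sim$counts)[, , drop = FALSE]
  rownames(m)[match(c("GAPDH", "ACTB"), rownames(m))] <-
    c("ENSG00000111640", "ENSG00000075624")
  ds2 <- qc_dataset(as_counts(m), sim$pheno, organism = "human")
  hk2 <- housekeeping_profile(ds2)
  expect_equal(unname(hk2$GAPDH$expression), unname(hk$GAPDH$expression))

  # remove ACTB: metric skips with instructions
  m3 <- m[rownames(m) != "ENSG00000075624", ]
  ds3 <- qc_dataset(as_counts(m3), sim$pheno, organism = "human")
  expect_s3_class(housekeeping_profile(ds3), "qc_skip")
  # non-human/mouse organisms have no bundled lookup
  expect_s3_class(housekeeping_profile(
    qc_dataset(sim$counts, sim$pheno, organism = "other")), "qc_skip")
})

test_that("the planted outlier has the minimal housekeeping profile", {
  hits <- 0L
  for (seed in 1:25) {
    sim <- simulate_counts(scenario_presets()$B, seed = seed + 300)
    ds <- qc_dataset(sim$counts, sim$pheno, sim$annotation, "human")
    hk <- housekeeping_profile(ds)
    lows <- vapply(hk, function(p) names(which.min(p$expression)), "")
    hits <- hits + all(lows == "control4")
  }
  expect_gte(hits, 24L)
})
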