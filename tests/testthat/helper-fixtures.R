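# Small in-code fixtures shared across test files.

tiny_counts <- function(n_genes = 6L, n_samples = 4L, seed = 42L,
                        groups = NULL) {
  set.seed(seed)
  x <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 10),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(n_samples))))
  as_counts(x)
}

tiny_pheno <- function(samples, groups = rep(c("A", "B"),
                                             length.out = length(samples))) {
  as_phenotype(data.frame(sample = samples, group = groups,
                          stringsAsFactors = FALSE))
}

tiny_annotation <- function(gene_ids, seed = 7L) {
  set.seed(seed)
  as_annotation(data.frame(gene_id = gene_ids,
                           length_bp = sample(300:3000, length(gene_ids)),
                           gc_fraction = runif(length(gene_ids), 0.2, 0.8),
                           stringsAsFactors = FALSE))
}

tiny_dataset <- function(n_genes = 6L, n_samples = 4L, seed = 42L,
                         organism = "other", with_annotation = FALSE) {
  cm <- tiny_counts(n_genes, n_samples, seed)
  ann <- if (with_annotation) tiny_annotation(rownames(cm)) else NULL
  qc_dataset(cm, tiny_pheno(colnames(cm)), ann, organism)
}

write_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
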