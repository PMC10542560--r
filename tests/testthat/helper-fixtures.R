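# Small fixture builders shared across test files.

# Two-tissue toy configuration (one reward CNS tissue, one non-reward CNS)
toy_tissue_sets <- function() {
  tissue_sets(cns = c("nucleus_accumbens", "cerebellum"),
              reward = "nucleus_accumbens")
}

# Deterministic panel from explicit per-(tissue, sex) means; `means` is a
# named list gene -> matrix [tissue x sex] or a single number (flat).
build_panel <- function(gene_means, tissues, sets,
                        n_per_cell = 2, age = 60, jitter = 0) {
  meta <- expand.grid(tissue = tissues, sex = c("male", "female"),
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("S%03d", seq_len(nrow(meta)))
  meta$age <- age
  genes <- names(gene_means)
  tpm <- matrix(0, nrow(meta), length(genes),
                dimnames = list(meta$sample_id, genes))
  for (g in genes) {
    spec <- gene_means[[g]]
    for (i in seq_len(nrow(meta))) {
      m <- if (is.matrix(spec)) spec[meta$tissue[i], meta$sex[i]] else spec
      tpm[i, g] <- m
    }
  }
  if (jitter > 0) {
    tpm <- tpm * matrix(exp(rnorm(length(tpm), 0, jitter)), nrow(tpm))
  }
  expression_panel(tpm, meta[c("sample_id", "tissue", "sex", "age")], sets)
}

write_tsv <- function(df, path, na = "NA") {
  write.table(df, path, sep = "\t", quote = FALSE, na = na,
              row.names = FALSE)
  path
}
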