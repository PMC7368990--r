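# Small shared fixtures built in code.

# A random NB count matrix with uneven library sizes.
random_counts <- function(n_genes = 200, n_samples = 6, mean_range = c(5, 500),
                          phi = 0.1, seed = 1) {
  set.seed(seed)
  mu <- runif(n_genes, mean_range[1], mean_range[2])
  libfac <- runif(n_samples, 0.5, 2)
  m <- sapply(libfac, function(f) rnbinom(n_genes, size = 1 / phi, mu = mu * f))
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(n_samples)))
  m
}

# Two-condition, two-assay count_matrix pair with no planted effects.
null_joint <- function(n_genes = 500, seed = 1, dispersion = 0.05,
                       library_size_range = c(2e6, 4e6)) {
  generate_joint_counts(simulation_config(
    n_genes = n_genes,
    class_proportions = c(null = 1, transcriptional = 0, te_up = 0, te_down = 0),
    dispersion = dispersion, library_size_range = library_size_range,
    seed = seed))
}

# Build a minimal de_table by hand (for pure-rule tests of downstream code).
fake_de <- function(gene_id, logFC, FDR, fdr_cut = 0.01, lfc_cut = 1) {
  tab <- data.frame(gene_id = gene_id, logFC = logFC, meanCPM = 100,
                    pvalue = FDR, FDR = FDR, stringsAsFactors = FALSE)
  tab$significant <- call_de(tab, fdr_cut, lfc_cut)
  class(tab) <- c("de_table", "data.frame")
  tab
}
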