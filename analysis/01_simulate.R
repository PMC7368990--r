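#!/usr/bin/env Rscript
# Stage 1: simulate the study data.
#
# Generates the joint RNA / RPF count matrices (3 cell-line conditions x 3
# biological replicates x 2 assays, NB counts) with planted regulatory
# classes, a gene-set collection containing one set drawn from the planted
# TE-up genes, and a polysome-gradient qPCR Cq table with known
# polysome/monosome ratios. Everything downstream reads from results/data/.

library(ribodecouple)

seed <- 101
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_genes = 3000, seed = seed)
sim <- generate_joint_counts(cfg)

write_count_matrix(sim$rna, "results/data/counts_rna.tsv",
                   "results/data/metadata_rna.tsv",
                   "results/data/gene_lengths.tsv")
write_count_matrix(sim$rpf, "results/data/counts_rpf.tsv",
                   "results/data/metadata_rpf.tsv")
write.table(sim$truth, "results/data/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sets <- generate_gene_sets(sim$truth, n_decoy_sets = 20, set_size = 50,
                           seed = seed + 1)
write_gmt(sets, "results/data/gene_sets.gmt")

cq <- generate_cq_table(n_genes = 4, te_ratio_truth = c(1, 2, 3, 6),
                        noise_sd = 0.3, seed = seed + 2)
write.table(cq$cq, "results/data/cq_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cq$truth, "results/data/cq_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d genes; class counts:\n", cfg$n_genes))
print(table(sim$truth$class))
cat(sprintf("library sizes %.2f-%.2fM (RNA), %.2f-%.2fM (RPF)\n",
            min(library_sizes(sim$rna)) / 1e6, max(library_sizes(sim$rna)) / 1e6,
            min(library_sizes(sim$rpf)) / 1e6, max(library_sizes(sim$rpf)) / 1e6))
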