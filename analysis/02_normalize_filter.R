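#!/usr/bin/env Rscript
# Stage 2: TMM normalization and expression filtering.
#
# Computes TMM factors per assay, applies the 1-CPM-in-all-replicates
# expression filter, and tabulates RPKM>1 presence per condition.

library(ribodecouple)

rna <- read_count_matrix("results/data/counts_rna.tsv",
                         "results/data/metadata_rna.tsv",
                         "results/data/gene_lengths.tsv")
rpf <- read_count_matrix("results/data/counts_rpf.tsv",
                         "results/data/metadata_rpf.tsv",
                         "results/data/gene_lengths.tsv")
dir.create("results", showWarnings = FALSE)

norm_rna <- tmm_normalize(rna)
norm_rpf <- tmm_normalize(rpf)
write_norm_factors(norm_rna, "results/tmm_rna.tsv")
write_norm_factors(norm_rpf, "results/tmm_rpf.tsv")
cat("TMM factor ranges: RNA", paste(round(range(norm_rna$factors), 4),
                                    collapse = "-"),
    "| RPF", paste(round(range(norm_rpf$factors), 4), collapse = "-"), "\n")

fl_rna <- filter_expressed(rna, 1, effective_sizes = norm_rna$effective_sizes)
fl_rpf <- filter_expressed(rpf, 1, effective_sizes = norm_rpf$effective_sizes)
expressed <- rownames(rna$counts)[fl_rna$keep & fl_rpf$keep]
writeLines(expressed, "results/expressed_genes.txt")
cat(sprintf("expressed (>=1 CPM in all replicates of some condition, both assays): %d / %d genes\n",
            length(expressed), nrow(rna$counts)))

pres <- presence_flags(rpkm(rna, norm_rna$effective_sizes),
                       rna$samples$condition)
pres_tab <- data.frame(gene_id = rownames(pres), pres, check.names = FALSE)
write.table(pres_tab, "results/presence_rpkm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("genes present (RPKM > 1 in all replicates) per condition:\n")
print(colSums(pres))
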