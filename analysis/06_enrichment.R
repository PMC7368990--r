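#!/usr/bin/env Rscript
# Stage 6: gene-set enrichment.
#
# Preranked GSEA on the per-gene delta-TE ranking against the simulated
# collection (one planted TE-up set among decoys), plus hypergeometric
# over-representation of each set in the TE_UP calls.

library(ribodecouple)

dte <- read.delim("results/differential_te.tsv")
calls <- read.delim("results/regulation_calls.tsv")
sets <- read_gmt("results/data/gene_sets.gmt")

ranking <- setNames(dte$delta_te, dte$gene_id)
gsea <- gsea_collection(ranking, sets, n_perm = 1000, seed = 106)
write.table(gsea, "results/gsea.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top GSEA results on the delta-TE ranking:\n")
print(head(gsea, 5), row.names = FALSE)

te_up_genes <- calls$gene_id[calls$class == "TE_UP"]
ora <- ora_hypergeometric(te_up_genes, calls$gene_id, sets)
write.table(ora, "results/ora.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nORA of %d TE_UP genes: %d set(s) at FDR < 0.01 (top: %s, p = %.3g)\n",
            length(te_up_genes), sum(ora$FDR < 0.01), ora$set[1], ora$pvalue[1]))
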