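#!/usr/bin/env Rscript
# Stage 5: transcription/translation decoupling.
#
# Classifies each tested gene as TRANSCRIPTIONAL (coupled significant
# change), TE_UP / TE_DOWN (RPF fold change departs from the mRNA fold
# change by more than 1 log2 unit) or UNCHANGED, reports the decoupled
# fraction, and checks the calls and mRNA fold changes against the planted
# ground truth.

library(ribodecouple)

rna <- read_count_matrix("results/data/counts_rna.tsv",
                         "results/data/metadata_rna.tsv",
                         "results/data/gene_lengths.tsv")
rpf <- read_count_matrix("results/data/counts_rpf.tsv",
                         "results/data/metadata_rpf.tsv",
                         "results/data/gene_lengths.tsv")
expressed <- readLines("results/expressed_genes.txt")
truth <- read.delim("results/data/ground_truth.tsv")

de_rna <- de_exact(rna, c("condB", "ctrl"), genes = expressed)
de_rpf <- de_exact(rpf, c("condB", "ctrl"), genes = expressed)
calls <- classify_regulation(de_rna, de_rpf, band = 1, mode = "guarded")
write.table(calls, "results/regulation_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("class counts:\n"); print(attr(calls, "class_counts"))
cat(sprintf("decoupled fraction of regulated genes: %.3f\n",
            decoupled_fraction(calls)))

tr <- truth[match(calls$gene_id, truth$gene_id), ]
tc <- c(null = "UNCHANGED", transcriptional = "TRANSCRIPTIONAL",
        te_up = "TE_UP", te_down = "TE_DOWN")[tr$class]
for (cl in c("TRANSCRIPTIONAL", "TE_UP", "TE_DOWN")) {
  cat(sprintf("  %s: sensitivity %.3f, precision %.3f\n", cl,
              sum(calls$class == cl & tc == cl) / sum(tc == cl),
              sum(calls$class == cl & tc == cl) / sum(calls$class == cl)))
}

conc <- compare_foldchanges(setNames(de_rna$logFC, de_rna$gene_id),
                            setNames(tr$lfc_rna, calls$gene_id))
cat(sprintf("estimated vs planted mRNA log2FC: r = %.3f (p = %.3g, n = %d)\n",
            conc$r, conc$pvalue, conc$n))

# high-transcription scatter groups on the ctrl condition
norm_rna <- tmm_normalize(rna); norm_rpf <- tmm_normalize(rpf)
gr <- scatter_expression_groups(
  rowMeans(rpkm(rna, norm_rna$effective_sizes)[expressed, , drop = FALSE]),
  rowMeans(rpkm(rpf, norm_rpf$effective_sizes)[expressed, , drop = FALSE]))
write.table(gr, "results/scatter_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("scatter groups of high-transcription genes:\n")
print(table(gr$group))
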