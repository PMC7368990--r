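#!/usr/bin/env Rscript
# Stage 3: exact-test differential expression, RNA and RPF independently.
#
# Contrast: condB vs ctrl. Significance: BH FDR < 0.01 and |log2FC| > 1
# (fold change beyond 2x).

library(ribodecouple)

rna <- read_count_matrix("results/data/counts_rna.tsv",
                         "results/data/metadata_rna.tsv")
rpf <- read_count_matrix("results/data/counts_rpf.tsv",
                         "results/data/metadata_rpf.tsv")
expressed <- readLines("results/expressed_genes.txt")

de_rna <- de_exact(rna, c("condB", "ctrl"), genes = expressed)
de_rpf <- de_exact(rpf, c("condB", "ctrl"), genes = expressed)
write.table(de_rna, "results/de_rna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(de_rpf, "results/de_rpf.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("common dispersion: RNA %.4f, RPF %.4f\n",
            attr(de_rna, "dispersion"), attr(de_rpf, "dispersion")))
cat(sprintf("differentially expressed (FDR<0.01, |log2FC|>1): %d RNA, %d RPF of %d tested\n",
            sum(de_rna$significant), sum(de_rpf$significant), nrow(de_rna)))
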