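#!/usr/bin/env Rscript
# Stage 4: translation efficiency.
#
# Global RPF-vs-RNA regression slope (with 95% CI) per condition on the
# replicate-averaged RPKM of genes detected in that condition, and the
# per-gene differential-TE Wald test on the condB vs ctrl contrast.

library(ribodecouple)

rna <- read_count_matrix("results/data/counts_rna.tsv",
                         "results/data/metadata_rna.tsv",
                         "results/data/gene_lengths.tsv")
rpf <- read_count_matrix("results/data/counts_rpf.tsv",
                         "results/data/metadata_rpf.tsv",
                         "results/data/gene_lengths.tsv")
expressed <- readLines("results/expressed_genes.txt")

norm_rna <- tmm_normalize(rna)
norm_rpf <- tmm_normalize(rpf)
rpkm_rna <- rpkm(rna, norm_rna$effective_sizes)
rpkm_rpf <- rpkm(rpf, norm_rpf$effective_sizes)
fl_rna <- filter_expressed(rna, 1, effective_sizes = norm_rna$effective_sizes)
fl_rpf <- filter_expressed(rpf, 1, effective_sizes = norm_rpf$effective_sizes)

conds <- unique(rna$samples$condition)
slopes <- lapply(setNames(conds, conds), function(cc) {
  keep <- fl_rna$detected[, cc] & fl_rpf$detected[, cc]
  global_te_slope(
    rowMeans(rpkm_rna[, rna$samples$condition == cc, drop = FALSE]),
    rowMeans(rpkm_rpf[, rpf$samples$condition == cc, drop = FALSE]),
    genes = keep)
})
slope_tab <- do.call(rbind, lapply(names(slopes), function(cc) {
  s <- slopes[[cc]]
  data.frame(condition = cc, slope = s$slope, ci_lower = s$ci[1],
             ci_upper = s$ci[2], r_squared = s$r_squared, n = s$n)
}))
write.table(slope_tab, "results/te_slopes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("global TE slopes (log2 RPF RPKM on log2 RNA RPKM):\n")
for (cc in names(slopes)) { cat(" ", cc, ": "); print(slopes[[cc]]) }

de_rna <- de_exact(rna, c("condB", "ctrl"), norm = norm_rna, genes = expressed)
de_rpf <- de_exact(rpf, c("condB", "ctrl"), norm = norm_rpf, genes = expressed)
dte <- differential_te(de_rna, de_rpf)
write.table(dte, "results/differential_te.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("differential TE: %d genes at FDR < 0.01\n", sum(dte$FDR < 0.01)))
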