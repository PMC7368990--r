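#' Classify genes into transcriptionally vs translationally regulated groups
#'
#' For one contrast measured in both assays, each gene receives exactly one
#' class based on its mRNA and RPF log2 fold changes and significance flags:
#'
#' * `TRANSCRIPTIONAL`: significant in both assays with RPF logFC within
#'   `band` of the mRNA logFC (coupled change);
#' * `TE_UP`: RPF logFC exceeds mRNA logFC by more than `band` (increased
#'   translation per mRNA);
#' * `TE_DOWN`: RPF logFC falls short of the mRNA logFC by more than `band`
#'   (decreased translation efficiency);
#' * `UNCHANGED`: everything else.
#'
#' In the default `"guarded"` mode decoupled calls additionally require
#' differential-expression significance (RPF for `TE_UP`, either assay for
#' `TE_DOWN`) so that pure noise in low-count genes does not create calls;
#' `"literal"` mode classifies by the fold-change band alone.
#'
#' @param de_rna,de_rpf `de_table` objects for the same genes and contrast.
#' @param band half-width of the coupling band in log2 units (default 1).
#' @param mode `"guarded"` (default) or `"literal"`.
#' @return data.frame of class `regulation_calls`: gene_id, class, lfc_rna,
#'   lfc_rpf, delta, sig_rna, sig_rpf; attribute `class_counts`.
#' @export
classify_regulation <- function(de_rna, de_rpf, band = 1.0,
                                mode = c("guarded", "literal")) {
  mode <- match.arg(mode)
  if (!identical(de_rna$gene_id, de_rpf$gene_id))
    stop("RNA and RPF tables must cover the same genes in the same order")
  lr <- de_rna$logFC; lp <- de_rpf$logFC
  sr <- de_rna$significant; sp <- de_rpf$significant
  d <- lp - lr
  cls <- rep("UNCHANGED", length(d))
  if (mode == "guarded") {
    cls[d > band & sp] <- "TE_UP"
    cls[d < -band & (sr | sp) & cls == "UNCHANGED"] <- "TE_DOWN"
    cls[sr & sp & abs(d) <= band & cls == "UNCHANGED"] <- "TRANSCRIPTIONAL"
    cls[!sr & !sp] <- "UNCHANGED"
  } else {
    cls[d > band] <- "TE_UP"
    cls[d < -band] <- "TE_DOWN"
    cls[abs(d) <= band & sr & sp] <- "TRANSCRIPTIONAL"
  }
  out <- data.frame(gene_id = de_rna$gene_id, class = cls,
                    lfc_rna = lr, lfc_rpf = lp, delta = d,
                    sig_rna = sr, sig_rpf = sp,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "class_counts") <- table(factor(cls, levels = c(
    "TRANSCRIPTIONAL", "TE_UP", "TE_DOWN", "UNCHANGED")))
  attr(out, "band") <- band
  attr(out, "mode") <- mode
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Fraction of classified genes with decoupled regulation
#'
#' `|TE_UP u TE_DOWN| / |TE_UP u TE_DOWN u TRANSCRIPTIONAL|` — the share of
#' regulated genes whose change is not explained by transcription alone.
#'
#' @param calls a `regulation_calls` data.frame.
#' @return fraction in [0, 1], or `NA` when no gene is classified as
#'   regulated.
#' @export
decoupled_fraction <- function(calls) {
  n_dec <- sum(calls$class %in% c("TE_UP", "TE_DOWN"))
  n_reg <- n_dec + sum(calls$class == "TRANSCRIPTIONAL")
  if (n_reg == 0) return(NA_real_)
  n_dec / n_reg
}

#' Scatter groups of high-transcription genes by regression residual
#'
#' On the log2 RPF-vs-RNA RPKM scatter, genes in the top `high_q` quantile of
#' RNA RPKM are split by their residual from the global regression line:
#' `RED` = residual below the `residual_q` quantile (high transcription, low
#' translation), `BLUE` = residual above the `1 - residual_q` quantile (very
#' high translation), `GREEN` = remaining high-transcription genes; all other
#' genes are `NONE`.
#'
#' @param rpkm_rna,rpkm_rpf replicate-averaged RPKM vectors (or matrices),
#'   matched by position.
#' @param high_q RNA-abundance quantile defining "high transcription".
#' @param residual_q tail quantile of regression residuals for RED/BLUE.
#' @param pseudocount added before log2 (default 0.01).
#' @return data.frame: gene index/id, group, rna, rpf, residual; attribute
#'   `slope_fit` holds the underlying [global_te_slope()] result.
#' @export
scatter_expression_groups <- function(rpkm_rna, rpkm_rpf, high_q = 0.90,
                                      residual_q = 0.05, pseudocount = 0.01) {
  if (high_q <= 0 || high_q >= 1 || residual_q <= 0 || residual_q >= 1)
    stop("quantiles must lie strictly inside (0, 1)")
  xr <- if (is.matrix(rpkm_rna)) rowMeans(rpkm_rna) else rpkm_rna
  yr <- if (is.matrix(rpkm_rpf)) rowMeans(rpkm_rpf) else rpkm_rpf
  fit <- global_te_slope(xr, yr, pseudocount = pseudocount)
  x <- log2(xr + pseudocount)
  y <- log2(yr + pseudocount)
  resid <- y - fit$intercept - fit$slope * x
  high <- x > stats::quantile(x, high_q)
  lo <- stats::quantile(resid, residual_q)
  hi <- stats::quantile(resid, 1 - residual_q)
  grp <- rep("NONE", length(x))
  grp[high] <- "GREEN"
  grp[high & resid < lo] <- "RED"
  grp[high & resid > hi] <- "BLUE"
  ids <- if (!is.null(names(xr))) names(xr) else as.character(seq_along(xr))
  out <- data.frame(gene_id = ids, group = grp, log2_rna = x, log2_rpf = y,
                    residual = resid, high_transcription = high,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "slope_fit") <- fit
  attr(out, "thresholds") <- c(high_q = high_q, residual_q = residual_q)
  out
}

#' Fold-change concordance between two platforms
#'
#' Pearson correlation (with two-sided t-based p-value) of per-gene log2 fold
#' changes measured on two platforms, on the genes shared by both vectors
#' (matched by name when named).
#'
#' @param lfc_a,lfc_b numeric log2 fold-change vectors, named by gene id or
#'   matched by position.
#' @return list: r, pvalue, n.
#' @export
compare_foldchanges <- function(lfc_a, lfc_b) {
  if (!is.null(names(lfc_a)) && !is.null(names(lfc_b))) {
    shared <- intersect(names(lfc_a), names(lfc_b))
    lfc_a <- lfc_a[shared]; lfc_b <- lfc_b[shared]
  }
  ok <- is.finite(lfc_a) & is.finite(lfc_b)
  lfc_a <- lfc_a[ok]; lfc_b <- lfc_b[ok]
  if (length(lfc_a) < 3) stop("need at least 3 shared genes")
  if (stats::sd(lfc_a) == 0 || stats::sd(lfc_b) == 0)
    stop("zero variance in fold changes")
  ct <- stats::cor.test(lfc_a, lfc_b, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(lfc_a))
}
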