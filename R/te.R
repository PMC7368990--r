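#' Global translation-efficiency slope
#'
#' Ordinary least squares of log2(RPF RPKM) on log2(RNA RPKM) over genes of
#' one condition (replicates averaged), with a 95% t confidence interval for
#' the slope. A slope above 1 means ribosome occupancy grows faster than mRNA
#' abundance, i.e. a globally higher translational efficiency of the
#' highly-expressed genes.
#'
#' @param rpkm_rna,rpkm_rpf numeric vectors (replicate-averaged RPKM per
#'   gene) or matrices (genes x replicates, averaged internally), matched by
#'   position.
#' @param genes optional logical/index subset of genes to use (e.g. the
#'   expressed set of the condition).
#' @param pseudocount added to RPKM before log2 (default 0.01).
#' @param conf_level confidence level for the slope interval.
#' @return object of class `slope_result`: slope, intercept, ci (length 2),
#'   r_squared, se, n.
#' @export
global_te_slope <- function(rpkm_rna, rpkm_rpf, genes = NULL,
                            pseudocount = 0.01, conf_level = 0.95) {
  xr <- if (is.matrix(rpkm_rna)) rowMeans(rpkm_rna) else rpkm_rna
  yr <- if (is.matrix(rpkm_rpf)) rowMeans(rpkm_rpf) else rpkm_rpf
  if (length(xr) != length(yr)) stop("matrices must cover the same genes")
  if (!is.null(genes)) { xr <- xr[genes]; yr <- yr[genes] }
  x <- log2(xr + pseudocount)
  y <- log2(yr + pseudocount)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("slope needs at least 3 genes")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero variance in RNA RPKM")
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = slope, intercept = intercept,
                 ci = c(lower = slope - tq * se, upper = slope + tq * se),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 se = se, n = n),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("TE slope %.4f (95%% CI [%.4f, %.4f]), R^2 %.3f, n = %d genes\n",
              x$slope, x$ci[1], x$ci[2], x$r_squared, x$n))
  invisible(x)
}

#' Per-gene log2 translation efficiency
#'
#' `log2((mean RPF CPM + c) / (mean RNA CPM + c))` per gene for one
#' condition.
#'
#' @param cpm_rna,cpm_rpf CPM vectors or genes x replicates matrices, matched
#'   by position.
#' @param pseudocount non-negative constant c (default 0.5).
#' @return numeric vector of log2 TE values.
#' @export
te_per_gene <- function(cpm_rna, cpm_rpf, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  mr <- if (is.matrix(cpm_rna)) rowMeans(cpm_rna) else cpm_rna
  mp <- if (is.matrix(cpm_rpf)) rowMeans(cpm_rpf) else cpm_rpf
  if (length(mr) != length(mp)) stop("matrices must cover the same genes")
  log2((mp + pseudocount) / (mr + pseudocount))
}

#' Differential translation efficiency (Wald test on delta TE)
#'
#' The per-gene change in translation efficiency for a contrast is
#' `delta_te = logFC(RPF) - logFC(RNA)`. The variance of each assay's log2
#' fold change is approximated by the delta method under the NB model,
#' `Var(logFC) = (1/ln(2)^2) * sum_groups (1/n_g) * (1/mu_g + phi)`, the two
#' assays are treated as independent, and a two-sided normal (Wald) p-value
#' with BH adjustment is reported.
#'
#' @param de_rna,de_rpf `de_table` objects from [de_exact()] for the same
#'   genes and contrast (their attributes supply group means, dispersions and
#'   replicate numbers unless overridden).
#' @param dispersion_rna,dispersion_rpf optional dispersion overrides.
#' @param mean_floor group means are floored at this value inside the
#'   variance formula so all-zero genes stay finite (default 0.5, the fold-
#'   change prior).
#' @return data.frame of class `dte_table`: gene_id, lfc_rna, lfc_rpf,
#'   delta_te, se, z, pvalue, FDR.
#' @export
differential_te <- function(de_rna, de_rpf,
                            dispersion_rna = attr(de_rna, "dispersion"),
                            dispersion_rpf = attr(de_rpf, "dispersion"),
                            mean_floor = 0.5) {
  if (!identical(de_rna$gene_id, de_rpf$gene_id))
    stop("RNA and RPF tables must cover the same genes in the same order")
  lfc_var <- function(tab, phi) {
    mu <- pmax(attr(tab, "group_means"), mean_floor)
    n <- attr(tab, "n_per_group")
    (1 / log(2)^2) * ((1 / n["A"]) * (1 / mu[, "A"] + phi) +
                      (1 / n["B"]) * (1 / mu[, "B"] + phi))
  }
  v_rna <- lfc_var(de_rna, dispersion_rna)
  v_rpf <- lfc_var(de_rpf, dispersion_rpf)
  delta <- de_rpf$logFC - de_rna$logFC
  se <- sqrt(v_rna + v_rpf)
  z <- delta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene_id = de_rna$gene_id,
                    lfc_rna = de_rna$logFC, lfc_rpf = de_rpf$logFC,
                    delta_te = delta, se = unname(se), z = unname(z),
                    pvalue = unname(p), FDR = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dte_table", "data.frame")
  out
}
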