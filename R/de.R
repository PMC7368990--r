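#' Scale counts to a common effective library size
#'
#' Each sample's counts are multiplied by (geometric-mean effective size /
#' its effective size) and rounded half-to-even back to integers, so that the
#' exact conditional test can treat replicates as identically distributed.
#'
#' @param x `count_matrix` or numeric matrix.
#' @param norm a `tmm_norm` from [tmm_normalize()]; when `NULL` the raw
#'   library sizes are equalized.
#' @return list with `counts` (adjusted integer matrix), `common_size` and
#'   `scale` (per-sample multipliers applied).
#' @export
equalize_libraries <- function(x, norm = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  eff <- if (is.null(norm)) colSums(m) else norm$effective_sizes
  if (any(eff <= 0)) stop("effective library sizes must be positive")
  common <- exp(mean(log(eff)))
  sc <- common / eff
  adj <- round(sweep(m, 2, sc, "*"))  # round() is IEC 60559 half-to-even
  list(counts = adj, common_size = common, scale = sc)
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Maximizes the sum over genes (and over conditions with at least two
#' replicates) of the NB log-likelihood conditional on each gene's
#' within-condition total, over dispersion phi in [1e-6, 10]. Counts must be
#' on equalized libraries.
#'
#' @param counts adjusted integer matrix (genes x samples).
#' @param conditions per-sample condition labels.
#' @return object of class `dispersion_estimate`: list(`phi`, `method`).
#' @export
estimate_common_dispersion <- function(counts, conditions) {
  counts <- as.matrix(counts)
  groups <- split(seq_along(conditions), conditions)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) stop("dispersion not estimable: no replicated condition")
  ll <- function(phi) {
    r <- 1 / phi
    s <- 0
    for (idx in groups) {
      y <- counts[, idx, drop = FALSE]
      n <- length(idx)
      z <- rowSums(y)
      s <- s + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
        sum(lgamma(n * r) - lgamma(z + n * r))
    }
    s
  }
  grid <- 10^seq(-6, 1, length.out = 25)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  if (i == 1 || i == length(grid)) {
    phi <- grid[i]
  } else {
    phi <- stats::optimize(ll, lower = grid[i - 1], upper = grid[i + 1],
                           maximum = TRUE, tol = 1e-8)$maximum
  }
  structure(list(phi = phi, method = "qCML-common"), class = "dispersion_estimate")
}

#' Exact conditional negative-binomial test for one gene
#'
#' Conditional on the total t of both groups, the probability of each split
#' (a, t - a) is computed from the NB-sum distributions of the two groups
#' (group of n replicates at mean mu and dispersion phi sums to
#' NB(n * mu, phi / n); phi = 0 is the Poisson limit). The two-sided p-value
#' is the sum of probabilities of all splits whose point probability does not
#' exceed that of the observed split.
#'
#' @param counts_a,counts_b integer replicate counts of the two groups, on
#'   equalized libraries.
#' @param phi common NB dispersion (>= 0).
#' @return two-sided p-value; t = 0 returns 1 by convention.
#' @export
exact_nb_test <- function(counts_a, counts_b, phi) {
  if (phi < 0) stop("phi must be >= 0")
  na <- length(counts_a); nb <- length(counts_b)
  sa <- sum(counts_a); sb <- sum(counts_b)
  t <- sa + sb
  if (t == 0) return(1)
  mu <- t / (na + nb)
  s <- 0:t
  if (phi == 0) {
    lp <- stats::dpois(s, na * mu, log = TRUE) +
          stats::dpois(t - s, nb * mu, log = TRUE)
  } else {
    lp <- stats::dnbinom(s, size = na / phi, mu = na * mu, log = TRUE) +
          stats::dnbinom(t - s, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pobs <- p[sa + 1]
  min(1, sum(p[p <= pobs * (1 + 1e-8)]))
}

#' Log2 fold change with a prior count
#'
#' `log2((mean(b) + prior) / (mean(a) + prior))` on equalized libraries; the
#' prior keeps zero-count genes finite and cancels when both groups are zero.
#'
#' @param counts_a,counts_b replicate counts (vectors) or matrices
#'   (genes x replicates) of groups A (baseline) and B.
#' @param prior_count non-negative prior added to both means (default 0.5).
#' @return log2 fold change (B vs A), scalar or per-gene vector.
#' @export
log2_fold_change <- function(counts_a, counts_b, prior_count = 0.5) {
  if (prior_count < 0) stop("prior_count must be >= 0")
  ma <- if (is.matrix(counts_a)) rowMeans(counts_a) else mean(counts_a)
  mb <- if (is.matrix(counts_b)) rowMeans(counts_b) else mean(counts_b)
  log2((mb + prior_count) / (ma + prior_count))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_(i) * n / i` with enforced monotonicity,
#' capped at 1.
#'
#' @param pvals p-values in [0, 1]; `NaN` is rejected.
#' @return adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals))) stop("NaN/NA p-values not allowed")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(pvals[o] * n / seq(n, 1)))
  adj[order(o)]
}

#' Significance call from FDR and fold-change cutoffs
#'
#' A gene is called significant when FDR < `fdr_cut` and |log2FC| >
#' `lfc_cut` (defaults 0.01 and 1, i.e. adjusted p < 0.01 and fold change
#' beyond 2x).
#'
#' @param table data.frame with columns `FDR` and `logFC` (a DE table from
#'   [de_exact()]).
#' @param fdr_cut FDR threshold (strict).
#' @param lfc_cut absolute log2 fold-change threshold (strict).
#' @return logical vector of significance flags.
#' @export
call_de <- function(table, fdr_cut = 0.01, lfc_cut = 1.0) {
  table$FDR < fdr_cut & abs(table$logFC) > lfc_cut
}

#' Exact-test differential expression for one contrast
#'
#' Runs TMM library equalization, common-dispersion estimation (unless
#' supplied), the per-gene exact conditional NB test, fold changes, BH
#' adjustment and significance calling for the contrast B vs A within one
#' assay's count matrix.
#'
#' @param x `count_matrix` for one assay.
#' @param contrast character vector `c(B, A)`: condition B is tested against
#'   baseline A.
#' @param norm optional `tmm_norm`; computed from `x` when `NULL`.
#' @param dispersion optional dispersion phi; estimated by
#'   [estimate_common_dispersion()] when `NULL`.
#' @param genes optional gene ids to test (e.g. the expressed set); defaults
#'   to all genes.
#' @param fdr_cut,lfc_cut significance cutoffs passed to [call_de()].
#' @param prior_count prior for [log2_fold_change()].
#' @return data.frame of class `de_table`: gene_id, logFC, meanCPM, pvalue,
#'   FDR, significant; attributes `contrast`, `dispersion`, `group_means`
#'   (genes x 2 matrix of equalized group means) and `n_per_group`.
#' @export
de_exact <- function(x, contrast, norm = NULL, dispersion = NULL, genes = NULL,
                     fdr_cut = 0.01, lfc_cut = 1.0, prior_count = 0.5) {
  stopifnot(length(contrast) == 2)
  if (is.null(norm)) norm <- tmm_normalize(x)
  eq <- equalize_libraries(x, norm)
  cond <- x$samples$condition
  if (!all(contrast %in% cond)) stop("contrast conditions not found in samples")
  cols_b <- which(cond == contrast[1])
  cols_a <- which(cond == contrast[2])
  counts <- eq$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      counts[, c(cols_a, cols_b), drop = FALSE],
      cond[c(cols_a, cols_b)])$phi
  }
  a <- counts[, cols_a, drop = FALSE]
  b <- counts[, cols_b, drop = FALSE]
  pv <- vapply(seq_len(nrow(counts)),
               function(i) exact_nb_test(a[i, ], b[i, ], dispersion),
               numeric(1))
  lfc <- log2_fold_change(a, b, prior_count)
  mean_cpm <- rowMeans(cpm(counts[, c(cols_a, cols_b), drop = FALSE]))
  fdr <- bh_adjust(pv)
  tab <- data.frame(gene_id = rownames(counts), logFC = lfc, meanCPM = mean_cpm,
                    pvalue = pv, FDR = fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab$significant <- call_de(tab, fdr_cut, lfc_cut)
  attr(tab, "contrast") <- contrast
  attr(tab, "dispersion") <- dispersion
  attr(tab, "group_means") <- cbind(A = rowMeans(a), B = rowMeans(b))
  attr(tab, "n_per_group") <- c(A = ncol(a), B = ncol(b))
  class(tab) <- c("de_table", "data.frame")
  tab
}
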