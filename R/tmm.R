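#' TMM between-sample normalization
#'
#' Trimmed mean of M-values: each sample is compared to a reference sample on
#' the M (log2 ratio of library-size-scaled counts) / A (average log2
#' abundance) scale. Genes with zero counts in either member of the pair are
#' excluded, the most extreme 30% of M values and 5% of A values are trimmed,
#' and the remaining M values are averaged with precision weights from the
#' delta-method (binomial) variance approximation. The scaling factor is
#' 2^(weighted trimmed mean); factors are rescaled so their geometric mean
#' is exactly 1.
#'
#' @param x `count_matrix` or numeric count matrix (genes x samples).
#' @param reference column index or sample name of the reference sample. By
#'   default the sample whose 75th-percentile count rate is closest to the
#'   mean 75th-percentile rate.
#' @param trim_M fraction of M values trimmed from each tail (default 0.30).
#' @param trim_A fraction of A values trimmed from each tail (default 0.05).
#' @return object of class `tmm_norm`: list with `factors` (named, geometric
#'   mean 1), `lib_sizes`, `effective_sizes` (= lib size x factor) and
#'   `reference`.
#' @export
tmm_normalize <- function(x, reference = NULL, trim_M = 0.30, trim_A = 0.05) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          colnames(m)[which(lib == 0)[1]])
  if (is.null(reference)) {
    f75 <- apply(m, 2, function(u) stats::quantile(u, probs = 0.75)) / lib
    reference <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(m))
    if (is.na(reference)) stop("reference sample not found")
  }
  fac <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, reference], lib[j], lib[reference],
                    trim_M = trim_M, trim_A = trim_A)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(m)
  structure(list(factors = fac, lib_sizes = lib,
                 effective_sizes = lib * fac,
                 reference = colnames(m)[reference]),
            class = "tmm_norm")
}

# Single-pair TMM factor (obs vs ref), unscaled.
tmm_pair_factor <- function(obs, ref, lib_obs = sum(obs), lib_ref = sum(ref),
                            trim_M = 0.30, trim_A = 0.05) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep] / lib_obs
  r <- ref[keep] / lib_ref
  M <- log2(o / r)
  A <- (log2(o) + log2(r)) / 2
  # delta-method variance of M on the count scale
  w <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
       (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)  # samples differ only by library size
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) return(1)
  f <- sum(M[sel] / w[sel]) / sum(1 / w[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference:", x$reference, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Write normalization factors to TSV
#' @param norm a `tmm_norm` object.
#' @param path output TSV path.
#' @return invisibly, `norm`.
#' @export
write_norm_factors <- function(norm, path) {
  out <- data.frame(sample = names(norm$factors), factor = norm$factors,
                    lib_size = norm$lib_sizes,
                    effective_size = norm$effective_sizes)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(norm)
}
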