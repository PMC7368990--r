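#' Spike-in correction of polysome-fraction qPCR Cq values
#'
#' Each gradient fraction receives an exogenous RNA spike-in before
#' extraction; technical per-fraction recovery differences show up as
#' fraction-to-fraction variation of the spike Cq. Corrected values subtract
#' the deviation of each fraction's spike Cq from the mean spike Cq of its
#' run: `Cq_corr = Cq - (spike_Cq - mean(spike_Cq within sample x replicate
#' x gene run))`. Adding any per-fraction constant to both the gene and the
#' spike Cq leaves the output unchanged.
#'
#' @param cq_table data.frame with columns `sample`, `gene`, `fraction`,
#'   `replicate`, `Cq`, `spike_Cq`.
#' @return the table with an added `Cq_corrected` column.
#' @export
spike_correct <- function(cq_table) {
  need <- c("sample", "gene", "fraction", "replicate", "Cq", "spike_Cq")
  if (!all(need %in% names(cq_table)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(cq_table$spike_Cq))) {
    bad <- cq_table[is.na(cq_table$spike_Cq), ][1, ]
    stop(sprintf("missing spike Cq for sample '%s' fraction %s",
                 bad$sample, bad$fraction))
  }
  run <- interaction(cq_table$sample, cq_table$gene, cq_table$replicate,
                     drop = TRUE)
  ref <- stats::ave(cq_table$spike_Cq, run)
  cq_table$Cq_corrected <- cq_table$Cq - (cq_table$spike_Cq - ref)
  cq_table
}

#' Relative quantity from Cq values
#'
#' `q = 2^(Cq_min - Cq)` across the fractions of one gene/sample run, so the
#' most abundant fraction has quantity exactly 1.
#'
#' @param cq numeric Cq vector (one gene/sample, one value per fraction).
#' @return numeric vector of relative quantities, max 1.
#' @export
relative_quantity <- function(cq) {
  if (all(is.na(cq))) stop("all Cq values missing")
  2^(min(cq, na.rm = TRUE) - cq)
}

#' Per-fraction abundance profiles from a corrected Cq table
#'
#' Converts spike-corrected Cq values to relative quantities per
#' (sample, gene, replicate) run and returns one row per run and fraction,
#' with the normalized profile `pi = q / sum(q)`.
#'
#' @param cq_table output of [spike_correct()] (column `Cq_corrected`), or a
#'   raw table with `use_corrected = FALSE`.
#' @param use_corrected use `Cq_corrected` (default) or raw `Cq`.
#' @return data.frame: sample, gene, replicate, fraction, q, pi.
#' @export
fraction_profile <- function(cq_table, use_corrected = TRUE) {
  col <- if (use_corrected) "Cq_corrected" else "Cq"
  if (!col %in% names(cq_table)) stop("column ", col, " missing; run spike_correct first")
  runs <- split(cq_table, interaction(cq_table$sample, cq_table$gene,
                                      cq_table$replicate, drop = TRUE))
  out <- lapply(runs, function(d) {
    d <- d[order(d$fraction), ]
    q <- relative_quantity(d[[col]])
    data.frame(sample = d$sample, gene = d$gene, replicate = d$replicate,
               fraction = d$fraction, q = q, pi = q / sum(q),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$gene, out$replicate, out$fraction), ]
}

#' Polysome / monosome translation-efficiency ratio
#'
#' `TE = sum(q over polysome fractions) / sum(q over monosome fractions)`
#' per replicate, aggregated as mean with SD across replicates. An mRNA whose
#' signal sits in the heavy fractions (many ribosomes per message) gets a
#' high ratio.
#'
#' @param profile output of [fraction_profile()].
#' @param monosome_fractions,polysome_fractions disjoint non-empty fraction
#'   index sets (defaults 7:8 and 9:14).
#' @return data.frame: sample, gene, te_ratio (mean across replicates),
#'   te_sd, n_replicates; per-replicate values in the `replicates` attribute.
#' @export
translation_efficiency_ratio <- function(profile,
                                         monosome_fractions = c(7, 8),
                                         polysome_fractions = 9:14) {
  if (length(monosome_fractions) == 0 || length(polysome_fractions) == 0)
    stop("fraction sets must be non-empty")
  if (length(intersect(monosome_fractions, polysome_fractions)))
    stop("monosome and polysome fraction sets must be disjoint")
  runs <- split(profile, interaction(profile$sample, profile$gene,
                                     profile$replicate, drop = TRUE))
  per_rep <- do.call(rbind, lapply(runs, function(d) {
    mono <- sum(d$q[d$fraction %in% monosome_fractions])
    poly <- sum(d$q[d$fraction %in% polysome_fractions])
    data.frame(sample = d$sample[1], gene = d$gene[1],
               replicate = d$replicate[1],
               te = if (mono > 0) poly / mono else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(per_rep, interaction(per_rep$sample,
                                                          per_rep$gene,
                                                          drop = TRUE)),
    function(d) data.frame(sample = d$sample[1], gene = d$gene[1],
                           te_ratio = mean(d$te), te_sd = stats::sd(d$te),
                           n_replicates = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  attr(agg, "replicates") <- per_rep
  attr(agg, "fractions") <- list(monosome = monosome_fractions,
                                 polysome = polysome_fractions)
  agg
}

# Weighted mean fraction index of one normalized profile.
profile_center <- function(q, fractions) {
  pi <- q / sum(q)
  sum(fractions * pi)
}

#' Shift between two polysome profiles
#'
#' The shift statistic is the difference (B minus A) in the
#' profile-weighted mean fraction index; a positive value means profile B
#' sits in heavier (more ribosome-loaded) fractions. Significance of a right
#' shift is assessed by bootstrap over replicates: replicates of each group
#' are resampled with replacement and the p-value is the (add-one smoothed)
#' fraction of bootstrap shifts <= 0.
#'
#' @param profile_a,profile_b replicate x fraction matrices of relative
#'   quantities, with fraction indices as column names (same grid for both).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list: shift, pvalue (NA when either group has a single
#'   replicate), n_boot, center_a, center_b.
#' @export
profile_shift <- function(profile_a, profile_b, n_boot = 1000, seed = 1) {
  profile_a <- rbind(profile_a); profile_b <- rbind(profile_b)
  fa <- as.numeric(colnames(profile_a)); fb <- as.numeric(colnames(profile_b))
  if (is.null(colnames(profile_a)) || is.null(colnames(profile_b)) ||
      !identical(fa, fb))
    stop("profiles must share the same fraction grid (column names)")
  center_group <- function(m) profile_center(colMeans(m), fa)
  ca <- center_group(profile_a); cb <- center_group(profile_b)
  shift <- cb - ca
  na <- nrow(profile_a); nb <- nrow(profile_b)
  pval <- NA_real_
  if (na >= 2 && nb >= 2) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(na, na, replace = TRUE)
      ib <- sample.int(nb, nb, replace = TRUE)
      center_group(profile_b[ib, , drop = FALSE]) -
        center_group(profile_a[ia, , drop = FALSE])
    }, numeric(1))
    pval <- (1 + sum(boots <= 0)) / (n_boot + 1)
  }
  list(shift = shift, pvalue = pval, n_boot = n_boot,
       center_a = ca, center_b = cb)
}
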