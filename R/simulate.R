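#' Configuration for the joint RNA/RPF count simulator
#'
#' The defaults emulate the study design the pipeline targets: three cell
#' lines with three independent biological replicates each, profiled by both
#' total RNA sequencing and ribosome profiling, with a minority of genes
#' carrying planted regulatory effects on the contrast of the second
#' condition versus the first.
#'
#' @param n_genes number of genes.
#' @param conditions condition labels; effects are planted on
#'   `conditions[2]` vs `conditions[1]`, any further conditions stay at
#'   baseline.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param class_proportions named fractions for `null`, `transcriptional`,
#'   `te_up`, `te_down`; must sum to 1.
#' @param lfc_transcriptional log2 effect applied to both assays of
#'   transcriptionally regulated genes (random sign per gene).
#' @param delta_te log2 TE effect: `te_up` genes gain it in RPF only,
#'   `te_down` genes lose it in RPF only.
#' @param dispersion NB dispersion phi >= 0 (`Var = mu + phi mu^2`); 0 gives
#'   Poisson counts.
#' @param baseline_log_mean,baseline_log_sd natural-log parameters of the
#'   log-normal baseline gene abundance.
#' @param te_log_sd SD (log2) of the per-gene baseline translation
#'   efficiency.
#' @param library_size_range min/max total counts per sample.
#' @param length_range min/max gene length (nt), drawn uniformly.
#' @param seed integer seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              conditions = c("ctrl", "condB", "condC"),
                              n_replicates = 3,
                              class_proportions = c(null = 0.6,
                                                    transcriptional = 0.2,
                                                    te_up = 0.1, te_down = 0.1),
                              lfc_transcriptional = 2,
                              delta_te = 2,
                              dispersion = 0.05,
                              baseline_log_mean = log(400),
                              baseline_log_sd = 0.5,
                              te_log_sd = 0.5,
                              library_size_range = c(2e6, 4e6),
                              length_range = c(300, 5000),
                              seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 2, length(conditions) >= 2)
  need <- c("null", "transcriptional", "te_up", "te_down")
  if (!all(need %in% names(class_proportions)))
    stop("class_proportions needs names: ", paste(need, collapse = ", "))
  class_proportions <- class_proportions[need]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (!is.finite(dispersion) || dispersion < 0) stop("dispersion must be >= 0")
  for (v in list(lfc_transcriptional, delta_te, baseline_log_mean,
                 baseline_log_sd, te_log_sd))
    if (!is.finite(v)) stop("non-finite simulation parameter")
  if (baseline_log_sd < 0 || te_log_sd < 0) stop("SD parameters must be >= 0")
  if (any(library_size_range <= 0) || diff(library_size_range) < 0)
    stop("invalid library_size_range")
  structure(list(n_genes = n_genes, conditions = conditions,
                 n_replicates = n_replicates,
                 class_proportions = class_proportions,
                 lfc_transcriptional = lfc_transcriptional,
                 delta_te = delta_te, dispersion = dispersion,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, te_log_sd = te_log_sd,
                 library_size_range = library_size_range,
                 length_range = length_range, seed = seed),
            class = "simulation_config")
}

# Integer class sizes matching the proportions within rounding.
class_sizes <- function(props, n) {
  raw <- props * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  sizes
}

#' Simulate paired RNA / RPF count matrices with planted regulatory classes
#'
#' Counts are drawn NB(mu, phi) where the expected value combines each gene's
#' log-normal baseline abundance, its baseline translation efficiency (RPF
#' only), the planted condition effect (applied symmetrically, -lfc/2 to the
#' reference and +lfc/2 to the second condition, so the contrast equals the
#' planted lfc exactly) and a per-sample library-size factor.
#'
#' @param config a [simulation_config()].
#' @return list with `rna` and `rpf` ([count_matrix()] objects sharing gene
#'   ids, lengths and condition labels) and `truth` (data.frame: gene_id,
#'   class, lfc_rna, lfc_rpf — true log2 fold changes of the
#'   `conditions[2]` vs `conditions[1]` contrast — baseline_te,
#'   baseline_mean).
#' @export
generate_joint_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  sizes <- class_sizes(config$class_proportions, n)
  cls <- rep(names(sizes), sizes)
  cls <- sample(cls)  # shuffle classes over gene ids

  lfc_rna <- numeric(n); lfc_rpf <- numeric(n)
  tr <- cls == "transcriptional"
  sgn <- sample(c(-1, 1), sum(tr), replace = TRUE)
  lfc_rna[tr] <- sgn * config$lfc_transcriptional
  lfc_rpf[tr] <- sgn * config$lfc_transcriptional
  lfc_rpf[cls == "te_up"] <- config$delta_te
  lfc_rpf[cls == "te_down"] <- -config$delta_te

  baseline <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  te0 <- stats::rnorm(n, 0, config$te_log_sd)
  lengths <- round(stats::runif(n, config$length_range[1], config$length_range[2]))
  names(lengths) <- gene_ids

  conds <- config$conditions
  # per-condition multiplier exponent: -lfc/2 for reference, +lfc/2 for the
  # contrasted condition, 0 elsewhere
  cond_coef <- stats::setNames(rep(0, length(conds)), conds)
  cond_coef[conds[1]] <- -0.5
  cond_coef[conds[2]] <- +0.5

  draw_assay <- function(assay) {
    lfc <- if (assay == "RNA") lfc_rna else lfc_rpf
    meta <- expand.grid(replicate = seq_len(config$n_replicates),
                        condition = conds, stringsAsFactors = FALSE)
    meta <- data.frame(sample = sprintf("%s_%s_r%d", assay, meta$condition,
                                        meta$replicate),
                       condition = meta$condition, replicate = meta$replicate,
                       assay = assay, stringsAsFactors = FALSE)
    lib <- stats::runif(nrow(meta), config$library_size_range[1],
                        config$library_size_range[2])
    # assay-specific baseline composition; condition effects sit on top of it
    # without renormalization, so planted fold changes stay exact in the
    # expected counts (library sizes then drift with the planted effects,
    # which the symmetric +/- lfc/2 application keeps small)
    base_conc <- if (assay == "RPF") baseline * 2^te0 else baseline
    base_conc <- base_conc / sum(base_conc)
    counts <- matrix(0, n, nrow(meta), dimnames = list(gene_ids, meta$sample))
    for (j in seq_len(nrow(meta))) {
      mu <- base_conc * 2^(cond_coef[meta$condition[j]] * lfc) * lib[j]
      counts[, j] <- if (config$dispersion == 0) stats::rpois(n, mu)
                     else stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
    }
    count_matrix(counts, meta, lengths)
  }
  rna <- draw_assay("RNA")
  rpf <- draw_assay("RPF")
  truth <- data.frame(gene_id = gene_ids, class = cls,
                      lfc_rna = lfc_rna, lfc_rpf = lfc_rpf,
                      baseline_te = te0, baseline_mean = baseline,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(rna = rna, rpf = rpf, truth = truth)
}

#' Simulate a polysome-fraction qPCR Cq table with known TE ratios
#'
#' Each gene's RNA mass is split between monosome and polysome fractions so
#' that the polysome/monosome ratio equals `te_ratio_truth` (mass uniform
#' within each group of fractions). Cq values follow
#' `Cq = Cq0 - log2(q_f) + offset_f + noise`, where `offset_f` is a
#' fraction-specific technical offset carried identically by the spike-in Cq,
#' so [spike_correct()] must remove it exactly.
#'
#' @param n_genes number of genes.
#' @param fractions gradient fraction indices (default 7:14; >= 2 required).
#' @param te_ratio_truth positive polysome/monosome ratio per gene (recycled).
#' @param noise_sd SD of Gaussian Cq noise (cycles, >= 0).
#' @param n_replicates replicate runs per gene.
#' @param monosome_fractions fractions carrying the monosome mass.
#' @param spike_offsets optional named per-fraction technical offsets
#'   (cycles); drawn N(0, 0.5) when `NULL`.
#' @param sample sample label.
#' @param seed integer seed.
#' @return list with `cq` (data.frame: sample, gene, fraction, replicate, Cq,
#'   spike_Cq) and `truth` (gene, te_ratio).
#' @export
generate_cq_table <- function(n_genes = 4, fractions = 7:14,
                              te_ratio_truth = 3, noise_sd = 0.3,
                              n_replicates = 3, monosome_fractions = c(7, 8),
                              spike_offsets = NULL, sample = "S1", seed = 1) {
  if (length(fractions) < 2) stop("need at least 2 fractions")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  te_ratio <- rep_len(te_ratio_truth, n_genes)
  if (any(te_ratio <= 0)) stop("te_ratio_truth must be positive")
  mono <- intersect(fractions, monosome_fractions)
  poly <- setdiff(fractions, mono)
  if (length(mono) == 0 || length(poly) == 0)
    stop("both monosome and polysome fractions must be present")
  set.seed(seed)
  if (is.null(spike_offsets)) {
    spike_offsets <- stats::setNames(stats::rnorm(length(fractions), 0, 0.5),
                                     fractions)
  } else {
    spike_offsets <- rep_len(spike_offsets, length(fractions))
    names(spike_offsets) <- fractions
  }
  genes <- sprintf("gene%02d", seq_len(n_genes))
  cq0 <- stats::runif(n_genes, 18, 24)
  rows <- list()
  for (g in seq_len(n_genes)) {
    r <- te_ratio[g]
    q <- stats::setNames(numeric(length(fractions)), fractions)
    q[as.character(mono)] <- (1 / (1 + r)) / length(mono)
    q[as.character(poly)] <- (r / (1 + r)) / length(poly)
    for (rep_i in seq_len(n_replicates)) {
      noise <- stats::rnorm(length(fractions), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample = sample, gene = genes[g], fraction = fractions,
        replicate = rep_i,
        Cq = cq0[g] - log2(q) + spike_offsets + noise,
        spike_Cq = 15 + spike_offsets,
        stringsAsFactors = FALSE)
    }
  }
  cq <- do.call(rbind, rows)
  rownames(cq) <- NULL
  list(cq = cq, truth = data.frame(gene = genes, te_ratio = te_ratio,
                                   stringsAsFactors = FALSE))
}

#' Simulate replicate polysome profiles with an optional right shift
#'
#' Profiles follow a Gaussian bump over the fraction grid; group B's bump
#' center is moved right by `shift` fractions. Replicates carry multiplica-
#' tive log-normal noise and are renormalized.
#'
#' @param n_replicates replicates per group.
#' @param fractions fraction grid.
#' @param center bump center of group A (fraction units).
#' @param width bump SD (fraction units).
#' @param shift right shift of group B's center.
#' @param noise_sd SD of the per-fraction log-normal replicate noise.
#' @param seed integer seed.
#' @return list with matrices `a` and `b` (replicates x fractions, fraction
#'   indices as column names) and `true_shift` (difference of the exact
#'   weighted-mean fraction indices of the two noise-free profiles).
#' @export
simulate_fraction_profiles <- function(n_replicates = 3, fractions = 7:14,
                                       center = 10, width = 1.5, shift = 0,
                                       noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  base <- function(ctr) {
    q <- stats::dnorm(fractions, ctr, width)
    q / sum(q)
  }
  qa <- base(center); qb <- base(center + shift)
  draw <- function(q) {
    m <- t(vapply(seq_len(n_replicates), function(i) {
      v <- q * exp(stats::rnorm(length(q), 0, noise_sd))
      v / sum(v)
    }, numeric(length(q))))
    colnames(m) <- fractions
    m
  }
  list(a = draw(qa), b = draw(qb),
       true_shift = sum(fractions * qb) - sum(fractions * qa))
}

#' Generate a gene-set collection with one planted TE-up set
#'
#' One set is drawn from the simulator's `te_up` genes (so a ranking by
#' delta TE should find it enriched); the remaining decoy sets are uniform
#' draws from all genes.
#'
#' @param truth ground-truth data.frame from [generate_joint_counts()].
#' @param n_decoy_sets number of decoy sets.
#' @param set_size members per set (>= 1, <= number of genes).
#' @param seed integer seed.
#' @return named list of gene-id vectors (GMT-compatible, see
#'   [write_gmt()]); the planted set is named `planted_te_up`.
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 20, set_size = 50,
                               seed = 1) {
  if (nrow(truth) == 0) stop("empty ground truth")
  if (set_size < 1) stop("set_size must be >= 1")
  if (set_size > nrow(truth)) stop("set_size exceeds number of genes")
  te_up <- truth$gene_id[truth$class == "te_up"]
  if (length(te_up) == 0) stop("no te_up genes to plant a set from")
  set.seed(seed)
  planted <- sample(te_up, min(set_size, length(te_up)))
  sets <- c(list(planted_te_up = planted),
            stats::setNames(
              lapply(seq_len(n_decoy_sets),
                     function(i) sample(truth$gene_id, set_size)),
              sprintf("decoy_%03d", seq_len(n_decoy_sets))))
  attr(sets, "descriptions") <- stats::setNames(
    c("planted translationally up-regulated genes",
      rep("random decoy set", n_decoy_sets)), names(sets))
  sets
}
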