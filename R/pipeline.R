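#' Pipeline configuration
#'
#' Collects every threshold the analysis uses (none are hard-coded downstream)
#' together with either a simulation block or paths to on-disk inputs.
#'
#' @param simulation a [simulation_config()], or `NULL` when counts are read
#'   from files.
#' @param counts_rna,metadata_rna,counts_rpf,metadata_rpf,lengths_path TSV
#'   paths used when `simulation` is `NULL`.
#' @param contrast conditions `c(B, A)` to test; defaults to
#'   `conditions[2]` vs `conditions[1]` of the data.
#' @param fdr_cut,lfc_cut differential-expression significance cutoffs
#'   (defaults: FDR < 0.01, |log2FC| > 1, i.e. fold change beyond 2x).
#' @param band log2 coupling band for [classify_regulation()] (default 1).
#' @param cpm_threshold expression filter cutoff (default 1 CPM).
#' @param rpkm_threshold presence cutoff (default 1 RPKM).
#' @param classification_mode `"guarded"` or `"literal"`.
#' @param gene_sets named list of gene sets or a GMT path; `NULL` simulates
#'   sets from the ground truth when simulating.
#' @param n_perm GSEA permutations.
#' @param cq_table data.frame or TSV path of polysome qPCR Cq values;
#'   optional.
#' @param monosome_fractions,polysome_fractions qPCR fraction split.
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            counts_rna = NULL, metadata_rna = NULL,
                            counts_rpf = NULL, metadata_rpf = NULL,
                            lengths_path = NULL,
                            contrast = NULL,
                            fdr_cut = 0.01, lfc_cut = 1.0, band = 1.0,
                            cpm_threshold = 1.0, rpkm_threshold = 1.0,
                            classification_mode = "guarded",
                            gene_sets = NULL, n_perm = 1000,
                            cq_table = NULL,
                            monosome_fractions = c(7, 8),
                            polysome_fractions = 9:14,
                            seed = 1) {
  if (is.null(simulation) && (is.null(counts_rna) || is.null(counts_rpf)))
    stop("config needs either a simulation block or count matrix paths")
  for (v in c(fdr_cut, lfc_cut, band, cpm_threshold, rpkm_threshold))
    if (v < 0) stop("thresholds must be >= 0")
  structure(list(simulation = simulation, counts_rna = counts_rna,
                 metadata_rna = metadata_rna, counts_rpf = counts_rpf,
                 metadata_rpf = metadata_rpf, lengths_path = lengths_path,
                 contrast = contrast, fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                 band = band, cpm_threshold = cpm_threshold,
                 rpkm_threshold = rpkm_threshold,
                 classification_mode = classification_mode,
                 gene_sets = gene_sets, n_perm = n_perm, cq_table = cq_table,
                 monosome_fractions = monosome_fractions,
                 polysome_fractions = polysome_fractions, seed = seed),
            class = "pipeline_config")
}

#' Run the full joint RNA/RPF analysis
#'
#' Executes simulate (or load) -> TMM normalize -> expression filter ->
#' exact-test DE per assay -> global TE slope per condition -> differential
#' TE -> decoupling classification -> GSEA on the delta-TE ranking + ORA of
#' the TE_UP calls -> (optionally) polysome qPCR quantification, writing
#' every stage table as TSV under `outdir` plus a JSON run manifest. The same
#' config always yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing); `NULL` skips writing.
#' @return invisibly, a named list with every stage result.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)

  # --- input stage -----------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- generate_joint_counts(config$simulation)
    res$rna <- sim$rna; res$rpf <- sim$rpf; res$truth <- sim$truth
  } else {
    res$rna <- read_count_matrix(config$counts_rna, config$metadata_rna,
                                 config$lengths_path)
    res$rpf <- read_count_matrix(config$counts_rpf, config$metadata_rpf,
                                 config$lengths_path)
    res$truth <- NULL
  }
  contrast <- config$contrast
  if (is.null(contrast)) {
    conds <- unique(res$rna$samples$condition)
    contrast <- c(conds[2], conds[1])
  }

  # --- normalization and filtering ------------------------------------
  res$norm_rna <- tmm_normalize(res$rna)
  res$norm_rpf <- tmm_normalize(res$rpf)
  res$filter_rna <- filter_expressed(res$rna, config$cpm_threshold,
                                     effective_sizes = res$norm_rna$effective_sizes)
  res$filter_rpf <- filter_expressed(res$rpf, config$cpm_threshold,
                                     effective_sizes = res$norm_rpf$effective_sizes)
  expressed <- rownames(res$rna$counts)[res$filter_rna$keep & res$filter_rpf$keep]

  # --- differential expression ----------------------------------------
  res$de_rna <- de_exact(res$rna, contrast, norm = res$norm_rna,
                         genes = expressed, fdr_cut = config$fdr_cut,
                         lfc_cut = config$lfc_cut)
  res$de_rpf <- de_exact(res$rpf, contrast, norm = res$norm_rpf,
                         genes = expressed, fdr_cut = config$fdr_cut,
                         lfc_cut = config$lfc_cut)

  # --- translation efficiency -----------------------------------------
  rpkm_rna <- rpkm(res$rna, res$norm_rna$effective_sizes)
  rpkm_rpf <- rpkm(res$rpf, res$norm_rpf$effective_sizes)
  conds <- unique(res$rna$samples$condition)
  res$te_slopes <- lapply(stats::setNames(conds, conds), function(cc) {
    keep <- res$filter_rna$detected[, cc] & res$filter_rpf$detected[, cc]
    global_te_slope(
      rowMeans(rpkm_rna[, res$rna$samples$condition == cc, drop = FALSE]),
      rowMeans(rpkm_rpf[, res$rpf$samples$condition == cc, drop = FALSE]),
      genes = keep)
  })
  res$dte <- differential_te(res$de_rna, res$de_rpf)

  # --- decoupling classification --------------------------------------
  res$calls <- classify_regulation(res$de_rna, res$de_rpf, band = config$band,
                                   mode = config$classification_mode)
  res$decoupled_fraction <- decoupled_fraction(res$calls)
  res$scatter_groups <- scatter_expression_groups(
    rowMeans(rpkm_rna[expressed, , drop = FALSE]),
    rowMeans(rpkm_rpf[expressed, , drop = FALSE]))

  # --- enrichment ------------------------------------------------------
  sets <- config$gene_sets
  if (is.null(sets) && !is.null(res$truth))
    sets <- generate_gene_sets(res$truth, seed = config$seed + 1)
  if (is.character(sets)) sets <- read_gmt(sets)
  if (!is.null(sets)) {
    ranking <- stats::setNames(res$dte$delta_te, res$dte$gene_id)
    res$gsea <- gsea_collection(ranking, sets, n_perm = config$n_perm,
                                seed = config$seed + 2)
    te_up_genes <- res$calls$gene_id[res$calls$class == "TE_UP"]
    if (length(te_up_genes) > 0) {
      res$ora <- ora_hypergeometric(te_up_genes, res$calls$gene_id, sets)
    }
  }

  # --- polysome qPCR ----------------------------------------------------
  cq <- config$cq_table
  if (is.character(cq)) cq <- utils::read.delim(cq, stringsAsFactors = FALSE)
  if (!is.null(cq)) {
    corrected <- spike_correct(cq)
    res$qpcr_profile <- fraction_profile(corrected)
    res$qpcr_te <- translation_efficiency_ratio(
      res$qpcr_profile, config$monosome_fractions, config$polysome_fractions)
  }

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir, contrast)
  invisible(res)
}

# Writes every stage table plus a manifest; deterministic byte-for-byte for
# a fixed config (no timestamps).
write_pipeline_outputs <- function(res, outdir, contrast) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  write_count_matrix(res$rna, p("counts_rna.tsv"), p("metadata_rna.tsv"),
                     p("gene_lengths.tsv"))
  write_count_matrix(res$rpf, p("counts_rpf.tsv"), p("metadata_rpf.tsv"))
  if (!is.null(res$truth)) wt(res$truth, "ground_truth.tsv")
  write_norm_factors(res$norm_rna, p("tmm_rna.tsv"))
  write_norm_factors(res$norm_rpf, p("tmm_rpf.tsv"))
  wt(res$de_rna, "de_rna.tsv")
  wt(res$de_rpf, "de_rpf.tsv")
  wt(res$dte, "differential_te.tsv")
  wt(res$calls, "regulation_calls.tsv")
  slope_tab <- do.call(rbind, lapply(names(res$te_slopes), function(cc) {
    s <- res$te_slopes[[cc]]
    data.frame(condition = cc, slope = s$slope, ci_lower = s$ci[1],
               ci_upper = s$ci[2], r_squared = s$r_squared, n = s$n)
  }))
  wt(slope_tab, "te_slopes.tsv")
  wt(res$scatter_groups, "scatter_groups.tsv")
  if (!is.null(res$gsea)) wt(res$gsea, "gsea.tsv")
  if (!is.null(res$ora)) wt(res$ora, "ora.tsv")
  if (!is.null(res$qpcr_te)) {
    wt(res$qpcr_profile, "qpcr_profile.tsv")
    wt(res$qpcr_te, "qpcr_te.tsv")
  }
  cfg <- res$config
  manifest <- list(
    package = "ribodecouple",
    version = as.character(utils::packageVersion("ribodecouple")),
    seed = cfg$seed, contrast = contrast,
    thresholds = list(fdr = cfg$fdr_cut, lfc = cfg$lfc_cut, band = cfg$band,
                      cpm = cfg$cpm_threshold, rpkm = cfg$rpkm_threshold),
    classification_mode = cfg$classification_mode,
    simulated = !is.null(cfg$simulation),
    decoupled_fraction = res$decoupled_fraction)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             p("manifest.json"))
  invisible(res)
}
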