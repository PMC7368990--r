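#' Gene-by-sample count matrix with assay metadata
#'
#' Container for integer read counts from one assay (total RNA or
#' ribosome-protected fragments, RPF) together with per-sample metadata
#' (condition, replicate, assay) and optional gene lengths in nucleotides.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Row names
#'   are gene ids (unique), column names are sample ids.
#' @param samples data.frame with one row per column of `counts` and columns
#'   `sample`, `condition`, `replicate`, `assay` (`assay` in `"RNA"`/`"RPF"`).
#' @param gene_lengths optional numeric vector of positive gene lengths (nt),
#'   one per gene, named or in row order.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as row names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (is.null(colnames(counts))) stop("counts must have sample ids as column names")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "double"  # keeps totals safe from integer overflow
  samples <- as.data.frame(samples)
  need <- c("sample", "condition", "replicate", "assay")
  if (!all(need %in% names(samples)))
    stop("samples metadata must have columns: ", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("metadata rows (", nrow(samples), ") != count columns (", ncol(counts), ")")
  if (!all(samples$sample == colnames(counts)))
    stop("metadata sample order must match count matrix columns")
  if (!all(samples$assay %in% c("RNA", "RPF")))
    stop("assay must be 'RNA' or 'RPF'")
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      if (!all(rownames(counts) %in% names(gene_lengths)))
        stop("gene_lengths missing for some genes")
      gene_lengths <- gene_lengths[rownames(counts)]
    }
    if (length(gene_lengths) != nrow(counts))
      stop("gene_lengths must have one value per gene")
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive and finite")
    gene_lengths <- stats::setNames(as.numeric(gene_lengths), rownames(counts))
  }
  structure(list(counts = counts, samples = samples, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = "/")))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Library sizes (column sums) of a count matrix
#' @param x a `count_matrix` or numeric matrix.
#' @return numeric vector of per-sample total counts.
#' @export
library_sizes <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  colSums(m)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The count file holds a `gene_id` column followed by one column per sample;
#' the metadata file holds `sample`, `condition`, `replicate`, `assay` and
#' optionally nothing else. Gene lengths, when present, are a `length` column
#' in a third file written by [write_count_matrix()].
#'
#' @param path TSV count file.
#' @param metadata_path TSV sample metadata file.
#' @param lengths_path optional TSV with columns `gene_id`, `length`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path, lengths_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("count file must start with a gene_id column")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id: ", tab$gene_id[duplicated(tab$gene_id)][1])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
    lengths <- stats::setNames(lt$length, lt$gene_id)
  }
  count_matrix(counts, meta, lengths)
}

#' Write a count matrix and its metadata to TSV files
#' @param x a `count_matrix`.
#' @param path output TSV count file.
#' @param metadata_path output TSV metadata file.
#' @param lengths_path optional output TSV for gene lengths.
#' @return invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, metadata_path, lengths_path = NULL) {
  out <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(x$gene_lengths)) {
    lt <- data.frame(gene_id = names(x$gene_lengths), length = x$gene_lengths)
    utils::write.table(lt, lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Counts per million
#'
#' `cpm_gs = count_gs / libsize_s * 1e6`. When `effective_sizes` (e.g. TMM
#' effective library sizes) are supplied they replace the raw column totals.
#'
#' @param x `count_matrix` or numeric matrix.
#' @param effective_sizes optional positive per-sample library sizes.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(x, effective_sizes = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  sizes <- if (is.null(effective_sizes)) colSums(m) else effective_sizes
  if (any(sizes <= 0)) stop("library sizes must be positive")
  sweep(m, 2, sizes, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' `rpkm_gs = count_gs / (libsize_s / 1e6) / (length_g / 1e3)`; requires gene
#' lengths on the matrix.
#'
#' @inheritParams cpm
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(x, effective_sizes = NULL) {
  if (!inherits(x, "count_matrix") || is.null(x$gene_lengths))
    stop("rpkm requires a count_matrix with gene_lengths")
  cpm(x, effective_sizes) / (x$gene_lengths / 1e3)
}

#' Expression filter: minimum CPM in all replicates of a condition
#'
#' Retains genes whose CPM reaches `threshold_cpm` in every replicate of at
#' least one condition (`scope = "any"`, the default) or of every condition
#' (`scope = "all"`).
#'
#' @param x a `count_matrix`.
#' @param threshold_cpm non-negative CPM cutoff (default 1).
#' @param scope `"any"` or `"all"` conditions.
#' @param effective_sizes optional effective library sizes for the CPM step.
#' @return list with `keep` (named logical per gene) and `detected`
#'   (gene x condition logical matrix).
#' @export
filter_expressed <- function(x, threshold_cpm = 1, scope = c("any", "all"),
                             effective_sizes = NULL) {
  scope <- match.arg(scope)
  if (threshold_cpm < 0) stop("threshold_cpm must be >= 0")
  cm <- cpm(x, effective_sizes)
  conds <- unique(x$samples$condition)
  detected <- sapply(conds, function(cc) {
    cols <- x$samples$condition == cc
    rowSums(cm[, cols, drop = FALSE] >= threshold_cpm) == sum(cols)
  })
  detected <- matrix(detected, nrow = nrow(cm),
                     dimnames = list(rownames(cm), conds))
  keep <- if (scope == "any") rowSums(detected) > 0 else rowSums(detected) == length(conds)
  list(keep = keep, detected = detected)
}

#' Presence flags from RPKM values
#'
#' A gene is present in a condition when its RPKM exceeds `threshold` in all
#' replicates of that condition simultaneously.
#'
#' @param rpkm_matrix numeric RPKM matrix, genes x samples.
#' @param conditions per-sample condition labels (length = ncol).
#' @param threshold RPKM cutoff, default 1 (strictly greater than).
#' @return logical gene x condition matrix.
#' @export
presence_flags <- function(rpkm_matrix, conditions, threshold = 1) {
  rpkm_matrix <- as.matrix(rpkm_matrix)
  if (length(conditions) != ncol(rpkm_matrix))
    stop("conditions must have one label per sample column")
  conds <- unique(conditions)
  out <- sapply(conds, function(cc) {
    cols <- conditions == cc
    rowSums(rpkm_matrix[, cols, drop = FALSE] > threshold) == sum(cols)
  })
  matrix(out, nrow = nrow(rpkm_matrix),
         dimnames = list(rownames(rpkm_matrix), conds))
}
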