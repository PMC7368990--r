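#' Read gene sets from a GMT file
#'
#' Tab-separated GMT dialect: set name, description, then one member per
#' field. Set names must be unique and every line needs at least one member.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate set name: ", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2), nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output path.
#' @return invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

# Signed maximum deviation of the GSEA running sum, given sorted member
# positions in the ranked list and the member weights (|metric|^p at those
# positions). The running sum only changes value at member positions, so the
# extrema are attained either right after a member increment or right before
# the next member; both candidate sets are scanned.
gsea_es_from_positions <- function(pos, w, n_total) {
  k <- length(pos)
  miss <- 1 / (n_total - k)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  wsum <- sum(w)
  if (wsum <= 0) {                 # all-zero metric inside the set
    w <- rep(1 / k, k)
  } else {
    w <- w / wsum
  }
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(k)) * miss          # just after each hit
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss  # just before each hit
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-like running-sum statistic over a ranked gene
#' list: walking down the ranking, the sum rises by `|metric|^p` (normalized
#' over the set) at set members and falls by `1/(N - k)` elsewhere. The
#' enrichment score ES is the signed maximum deviation. Significance comes
#' from gene-set permutation: `n_perm` random member sets of the same size,
#' `p = (1 + #{|ES_perm| >= |ES|}) / (n_perm + 1)`, and
#' `NES = ES / mean(|ES_perm|)` over the same-sign permutations.
#'
#' @param ranking named numeric vector of per-gene metric values (e.g. delta
#'   TE or a DE statistic); ranked internally in decreasing order.
#' @param set character vector of member gene ids; must overlap the ranking
#'   and must not cover it entirely.
#' @param n_perm number of gene-set permutations.
#' @param weight_p exponent on |metric| in the increments (default 1).
#' @param seed integer seed for the permutation null.
#' @return list of class `gsea_result`: es, nes, pvalue, direction
#'   ("left"/"right" position of the extremum relative to the middle of the
#'   ranking), overlap, n_perm.
#' @export
gsea_preranked <- function(ranking, set, n_perm = 1000, weight_p = 1, seed = 1) {
  if (is.null(names(ranking))) stop("ranking must be named by gene id")
  if (any(!is.finite(ranking))) stop("ranking metric must be finite")
  ord <- order(ranking, decreasing = TRUE)
  metric <- ranking[ord]
  genes <- names(metric)
  n <- length(genes)
  hit <- genes %in% set
  k <- sum(hit)
  if (k == 0) stop("set not represented in ranking")
  if (k == n) stop("set covers the whole ranking; ES undefined")
  absw <- abs(metric)^weight_p
  pos <- which(hit)
  es <- gsea_es_from_positions(pos, absw[pos], n)
  # rank position of the running-sum extremum, for the barcode-plot skew
  ext_pos <- {
    w <- absw[pos] / max(sum(absw[pos]), .Machine$double.eps)
    cw <- cumsum(w)
    miss <- 1 / (n - k)
    after <- cw - (pos - seq_len(k)) * miss
    before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss
    cand_pos <- c(pos, pmax(pos - 1, 1))
    cand_pos[which.max(abs(c(after, before)))]
  }
  dir <- if (ext_pos <= n / 2) "left" else "right"
  set.seed(seed)
  es_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, k)
    gsea_es_from_positions(idx, absw[idx], n)
  }, numeric(1))
  pval <- (1 + sum(abs(es_perm) >= abs(es))) / (n_perm + 1)
  same <- es_perm[sign(es_perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  structure(list(es = unname(es), nes = unname(nes), pvalue = pval,
                 direction = dir, overlap = k, n_perm = n_perm),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES %.3f (NES %.2f), p = %.4g, %d members, skew %s\n",
              x$es, x$nes, x$pvalue, x$overlap, x$direction))
  invisible(x)
}

#' Run preranked GSEA over a gene-set collection
#' @inheritParams gsea_preranked
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param min_overlap sets with fewer represented members are skipped.
#' @return data.frame: set, size, overlap, es, nes, pvalue, FDR, direction.
#' @export
gsea_collection <- function(ranking, collection, n_perm = 1000, weight_p = 1,
                            seed = 1, min_overlap = 1) {
  rows <- lapply(seq_along(collection), function(i) {
    st <- collection[[i]]
    k <- sum(names(ranking) %in% st)
    if (k < min_overlap || k == length(ranking)) return(NULL)
    r <- gsea_preranked(ranking, st, n_perm, weight_p, seed = seed + i)
    data.frame(set = names(collection)[i], size = length(st), overlap = r$overlap,
               es = r$es, nes = r$nes, pvalue = r$pvalue, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set overlaps the ranking")
  out$FDR <- bh_adjust(out$pvalue)
  out[order(out$pvalue), c("set", "size", "overlap", "es", "nes",
                           "pvalue", "FDR", "direction")]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set of a collection, within a stated gene universe, with BH
#' adjustment across sets.
#'
#' @param query character vector of genes of interest (must be contained in
#'   `universe`).
#' @param universe character vector of all eligible genes.
#' @param collection named list of gene sets.
#' @return data.frame: set, set_size (within universe), overlap,
#'   fold_enrichment, pvalue, FDR.
#' @export
ora_hypergeometric <- function(query, universe, collection) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be contained in the universe")
  n_u <- length(universe)
  k <- length(query)
  rows <- lapply(names(collection), function(nm) {
    m <- length(intersect(collection[[nm]], universe))
    ov <- length(intersect(collection[[nm]], query))
    p <- if (m == 0) 1 else stats::phyper(ov - 1, m, n_u - m, k, lower.tail = FALSE)
    fe <- if (m == 0 || k == 0) NA_real_ else (ov / k) / (m / n_u)
    data.frame(set = nm, set_size = m, overlap = ov, fold_enrichment = fe,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$pvalue)
  out[order(out$pvalue), ]
}
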