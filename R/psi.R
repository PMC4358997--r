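## Percent spliced in (PSI), the high-PSI gene screen, and heatmap
## matrices (z-scores, relative expression, clustering orders).

#' Percent spliced in
#'
#' PSI = c / (c + a), the fraction of junction-spanning reads supporting
#' the cryptic 3'SS relative to the cryptic plus canonical reads. Missing
#' (NA) when both counts are zero: no coverage is not the same as no
#' usage.
#'
#' @param c cryptic-junction read counts (non-negative integers).
#' @param a canonical-junction read counts.
#' @return numeric vector of PSI values in [0, 1] with NA where c + a = 0.
#' @export
compute_psi <- function(c, a) {
  if (any(c < 0) || any(a < 0)) stop("counts must be non-negative")
  ifelse(c + a == 0, NA_real_, c / (c + a))
}

#' Per-sample PSI table for cryptic-site records
#'
#' @param records cryptic-site records from [build_cryptic_records()].
#' @param fjcm filtered junction count matrix holding both the cryptic and
#'   canonical junction rows.
#' @return list with `psi` (records x samples matrix), `cryptic` and
#'   `canonical` count matrices, and `records`. Records whose canonical
#'   junction is absent from the matrix are dropped.
#' @export
psi_table <- function(records, fjcm) {
  jk <- junction_key(fjcm$junctions$chrom, fjcm$junctions$start,
                     fjcm$junctions$end, fjcm$junctions$strand)
  ck <- junction_key(records$chrom, records$novel_start, records$novel_end,
                     records$strand)
  kk <- junction_key(records$chrom, records$canonical_start,
                     records$canonical_end, records$strand)
  mi <- match(ck, jk); mj <- match(kk, jk)
  keep <- !is.na(mi) & !is.na(mj)
  records <- records[keep, , drop = FALSE]
  cr <- fjcm$counts[mi[keep], , drop = FALSE]
  ca <- fjcm$counts[mj[keep], , drop = FALSE]
  psi <- matrix(compute_psi(as.vector(cr), as.vector(ca)), nrow(cr),
                dimnames = list(ck[keep], colnames(fjcm$counts)))
  list(psi = psi, cryptic = cr, canonical = ca, records = records)
}

#' Screen for cryptic 3'SSs with high PSI in mutants
#'
#' Keeps records whose median mutant PSI exceeds `mut_min`, whose median
#' wild-type PSI is below `wt_max` (medians over defined PSI values only),
#' whose mean mutant coverage (c + a) is at least `min_mut_cov`
#' junction-spanning reads, and (optionally) that are out-of-frame.
#'
#' @param pt output of [psi_table()].
#' @param conditions per-sample condition labels (`mut`/`wt`).
#' @param mut_min,wt_max PSI thresholds (default 0.5 and 0.2, strict
#'   inequalities).
#' @param min_mut_cov minimum mean mutant coverage (default 30).
#' @param require_out_of_frame restrict to out-of-frame records (default
#'   TRUE).
#' @return the retained records with screen statistics appended.
#' @export
high_psi_screen <- function(pt, conditions, mut_min = 0.5, wt_max = 0.2,
                            min_mut_cov = 30, require_out_of_frame = TRUE) {
  mut <- conditions == "mut"
  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  med_mut <- apply(pt$psi[, mut, drop = FALSE], 1, med)
  med_wt <- apply(pt$psi[, !mut, drop = FALSE], 1, med)
  cov_mut <- rowMeans(pt$cryptic[, mut, drop = FALSE] +
                        pt$canonical[, mut, drop = FALSE])
  keep <- !is.na(med_mut) & !is.na(med_wt) &
    med_mut > mut_min & med_wt < wt_max & cov_mut >= min_mut_cov
  if (require_out_of_frame) keep <- keep & pt$records$frame == "out_of_frame"
  out <- pt$records[keep, , drop = FALSE]
  out$median_psi_mut <- med_mut[keep]
  out$median_psi_wt <- med_wt[keep]
  out$mean_mut_cov <- cov_mut[keep]
  rownames(out) <- NULL
  out
}

#' Junction-by-sample z-score matrix of log2 library-normalized counts
#'
#' Counts are converted to counts per million of the sample's library
#' size, log2(x + 1)-transformed, and z-scored within each junction across
#' samples. Zero-variance rows become zero rows and are flagged.
#'
#' @param counts junction x sample count matrix.
#' @param lib_sizes per-sample library sizes (> 0).
#' @return list with `z` (matrix) and `flat` (logical vector of
#'   zero-variance rows).
#' @export
zscore_matrix <- function(counts, lib_sizes) {
  stopifnot(all(lib_sizes > 0), ncol(counts) == length(lib_sizes))
  l <- log2(sweep(counts, 2, lib_sizes / 1e6, "/") + 1)
  mu <- rowMeans(l)
  sdv <- apply(l, 1, sd)
  flat <- sdv == 0 | !is.finite(sdv)
  z <- (l - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  list(z = z, flat = flat)
}

#' Gene-by-cancer relative mean expression
#'
#' Mean expression per cancer type for each gene, divided by the gene's
#' largest mean so that each gene's maximum is exactly 1. Genes with
#' all-zero expression become zero rows and are flagged.
#'
#' @param expr gene x sample non-negative expression matrix.
#' @param cancer_labels per-sample cancer-type labels.
#' @return list with `rel` (gene x cancer matrix) and `zero` (flag).
#' @export
relative_expression_matrix <- function(expr, cancer_labels) {
  stopifnot(all(expr >= 0), ncol(expr) == length(cancer_labels))
  labs <- unique(cancer_labels)
  m <- vapply(labs, function(l)
    rowMeans(expr[, cancer_labels == l, drop = FALSE]), numeric(nrow(expr)))
  m <- matrix(m, nrow = nrow(expr), dimnames = list(rownames(expr), labs))
  mx <- apply(m, 1, max)
  zero <- mx == 0
  rel <- m / ifelse(zero, 1, mx)
  rel[zero, ] <- 0
  list(rel = rel, zero = zero)
}

#' Hierarchical clustering leaf orders for heatmap rows and columns
#'
#' Agglomerative clustering on Euclidean distance with complete or single
#' linkage. Missing values are imputed as zero (with a message).
#'
#' @param mat numeric matrix.
#' @param linkage `"complete"` or `"single"`.
#' @return list with row_order, col_order and the two hclust objects
#'   (NULL for single-row or single-column matrices, where the order is
#'   the identity).
#' @export
cluster_order <- function(mat, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  if (anyNA(mat)) {
    message("missing values imputed as 0 for clustering")
    mat[is.na(mat)] <- 0
  }
  rh <- if (nrow(mat) > 1) hclust(dist(mat), method = linkage) else NULL
  ch <- if (ncol(mat) > 1) hclust(dist(t(mat)), method = linkage) else NULL
  list(row_order = if (is.null(rh)) seq_len(nrow(mat)) else rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(mat)) else ch$order,
       row_hclust = rh, col_hclust = ch)
}
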