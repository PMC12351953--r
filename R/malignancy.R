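# Malignant-cell classification from copy-number state matrices and a
# bulk-similarity score.

#' Normalize a copy-number state matrix
#'
#' Inferred per-gene CNA states 1..6 (1 = complete allele loss, 3 = neutral,
#' 6 = gain of more than two alleles) are first capped at 5, mapped to
#' \[-1, 1\] via `(state - 3) / 2`, and squared so gains and losses carry
#' equal weight.
#'
#' @param states integer matrix (genes x cells) with entries in 1..6.
#' @return numeric matrix of the same shape with entries in `{0, 0.0625,
#'   0.25, 1}` (0.0625 never occurs for integer states; image is
#'   `{0, 0.25, 1}`).
#' @export
normalize_cna_matrix <- function(states) {
  m <- as.matrix(states)
  if (any(!is.finite(m)) || any(m < 1 | m > 6) || any(m != round(m)))
    stop("CNA states must be integers in 1..6")
  ((pmin(m, 5) - 3) / 2)^2
}

#' Per-cell CNA burden and the tumor CNA profile
#'
#' Burden is each cell's mean normalized CNA value over all genes.  The tumor
#' profile is the per-gene mean over the CD45-negative cells with the top
#' `top_frac` (default 10%) burden; `ceiling(top_frac * n)` cells are taken,
#' ties broken by cell order.
#'
#' @param norm normalized CNA matrix from [normalize_cna_matrix()].
#' @param cd45neg logical vector: per-cell CD45-negative flag.
#' @param top_frac fraction of CD45-negative cells defining the profile.
#' @return list with `burden` (per cell), `profile` (per gene), and
#'   `profile_cells` (ids used).
#' @export
tumor_cna_profile <- function(norm, cd45neg, top_frac = 0.10) {
  stopifnot(length(cd45neg) == ncol(norm))
  if (!any(cd45neg)) stop("no CD45-negative cells; cannot build tumor CNA profile")
  burden <- colMeans(norm)
  neg_idx <- which(cd45neg)
  k <- max(1L, ceiling(top_frac * length(neg_idx)))
  ord <- neg_idx[order(-burden[neg_idx], neg_idx)]
  sel <- ord[seq_len(k)]
  list(burden = burden,
       profile = rowMeans(norm[, sel, drop = FALSE]),
       profile_cells = colnames(norm)[sel])
}

#' Flag cells with detected copy-number alterations
#'
#' Each cell's per-gene normalized CNA vector is Spearman-correlated with the
#' tumor profile; cells strictly above the sample's `pct` percentile
#' (type-7) of these correlations are flagged.  Cells with a constant CNA
#' vector have undefined correlation and are not flagged.
#'
#' @param norm normalized CNA matrix (genes x cells).
#' @param profile per-gene tumor CNA profile.
#' @param pct percentile in \[0, 1\], default 0.25.
#' @return list with `rho` (per-cell Spearman) and `detected` (logical).
#' @export
call_cna_detected <- function(norm, profile, pct = 0.25) {
  stopifnot(nrow(norm) == length(profile))
  rho <- suppressWarnings(
    apply(norm, 2L, function(v) stats::cor(v, profile, method = "spearman")))
  if (anyNA(rho))
    warning(sum(is.na(rho)), " cells with undefined CNA correlation (constant vector); not flagged")
  cutoff <- scanact_quantile(rho, pct)
  detected <- !is.na(rho) & rho > cutoff
  list(rho = rho, detected = detected, cutoff = cutoff)
}

#' Bulk-similarity score per cell
#'
#' Spearman correlation of each cell's expression with the mean bulk tumor
#' profile, minus Spearman correlation with the mean normal-cell profile,
#' computed on the genes the three matrices share.  A score above 0 marks the
#' cell as potentially malignant.
#'
#' @param cells a [cell_table()] (raw counts are used).
#' @param bulk_reference [expression_panel()] of bulk tumor samples.
#' @param normal_reference [expression_panel()] of normal reference cells.
#' @param min_common_genes minimum size of the shared gene set (default 50).
#' @return named numeric vector of per-cell similarity scores.
#' @export
similarity_score <- function(cells, bulk_reference, normal_reference,
                             min_common_genes = 50) {
  common <- Reduce(intersect, list(rownames(cells$counts),
                                   rownames(bulk_reference$values),
                                   rownames(normal_reference$values)))
  if (length(common) < min_common_genes)
    stop("only ", length(common), " genes shared across cell/bulk/normal matrices (need >= ",
         min_common_genes, ")")
  expr <- as.matrix(cells$counts[common, , drop = FALSE])
  tumor_mean <- rowMeans(bulk_reference$values[common, , drop = FALSE])
  normal_mean <- rowMeans(normal_reference$values[common, , drop = FALSE])
  rho_t <- suppressWarnings(as.numeric(stats::cor(expr, tumor_mean, method = "spearman")))
  rho_n <- suppressWarnings(as.numeric(stats::cor(expr, normal_mean, method = "spearman")))
  stats::setNames(rho_t - rho_n, colnames(expr))
}

#' Combine CD45, CNA and similarity evidence into malignancy calls
#'
#' A cell is malignant iff it is CD45-negative (PTPRC count 0) and has either
#' detected CNA or a similarity score strictly above 0.
#'
#' @param cd45neg logical per-cell flag.
#' @param cna_detected logical per-cell flag.
#' @param similarity numeric per-cell score.
#' @param cell_ids optional cell identifiers.
#' @return data.frame with columns `cell`, `cd45_negative`, `cna_detected`,
#'   `similarity_score`, `malignant`.
#' @export
classify_malignant <- function(cd45neg, cna_detected, similarity, cell_ids = NULL) {
  n <- length(cd45neg)
  stopifnot(length(cna_detected) == n, length(similarity) == n)
  if (is.null(cell_ids)) cell_ids <- names(cd45neg) %||% paste0("cell", seq_len(n))
  data.frame(cell = cell_ids,
             cd45_negative = cd45neg,
             cna_detected = cna_detected,
             similarity_score = similarity,
             malignant = cd45neg & (cna_detected | similarity > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full malignancy-calling stage
#'
#' Runs [normalize_cna_matrix()], [tumor_cna_profile()],
#' [call_cna_detected()], [similarity_score()] and [classify_malignant()] on
#' one sample.
#'
#' @param cells a [cell_table()].
#' @param states CNA state matrix (genes x cells, states 1..6) aligned to the
#'   same cells.
#' @param bulk_reference,normal_reference panels for [similarity_score()].
#' @param config a [scanact_config()].
#' @return the [classify_malignant()] data.frame plus `cna_burden` column.
#' @export
call_malignancy <- function(cells, states, bulk_reference, normal_reference,
                            config = scanact_config()) {
  stopifnot(identical(colnames(states), cells$cell_ids))
  norm <- normalize_cna_matrix(states)
  cd45 <- cd45_negative(cells)
  prof <- tumor_cna_profile(norm, cd45, top_frac = config$cna_top_frac)
  det <- call_cna_detected(norm, prof$profile, pct = config$cna_detect_percentile)
  sim <- similarity_score(cells, bulk_reference, normal_reference,
                          min_common_genes = config$min_common_genes)
  out <- classify_malignant(cd45, det$detected, sim[cells$cell_ids],
                            cell_ids = cells$cell_ids)
  out$cna_burden <- prof$burden[cells$cell_ids]
  out
}
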