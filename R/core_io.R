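#' @importFrom stats cor cor.test median p.adjust quantile sd setNames
#' @importFrom utils read.delim write.table head
#' @keywords internal
"_PACKAGE"

# Closed vocabularies used across modules ------------------------------------

.CELL_LABELS <- c("tumor", "endothelial", "myeloid", "lymphoid", "CAF", "unknown")
.IHC_LEVELS  <- c("Not Detected", "Low", "Medium", "High")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Quantile convention used throughout the package
#'
#' All named percentiles (25th, 50th, 75th, 90th, 99th) use linear
#' interpolation (Hyndman-Fan type 7), the R default.
#'
#' @param x numeric vector.
#' @param p probability in \[0, 1\].
#' @return the type-7 quantile of `x` at `p`.
#' @export
scanact_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, na.rm = TRUE, names = FALSE))
}

# ExpressionPanel -------------------------------------------------------------

.PANEL_UNITS <- c("raw-count", "CPM", "TPM", "nTPM", "log2p1", "zscore",
                  "categorical-ordinal", "categorical")

#' Construct an expression panel
#'
#' An `ExpressionPanel` is a genes-by-columns numeric (or, after
#' categorization, character) matrix carrying a declared unit and an optional
#' column-to-tissue-group mapping.  It is the common currency of every
#' normal-tissue and tumor expression dataset in the framework.
#'
#' @param values matrix with gene symbols as rownames and column labels
#'   (tissues, samples, or cell types) as colnames.
#' @param unit one of `r paste(.PANEL_UNITS, collapse = ", ")`.
#' @param grouping optional named character vector mapping column label to
#'   tissue-group label.
#' @param zero_sd character vector of gene symbols flagged as zero-variance
#'   (set after z-scoring).
#' @return an object of class `ExpressionPanel`.
#' @export
expression_panel <- function(values, unit, grouping = NULL, zero_sd = character()) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression panel requires gene rownames and column labels")
  unit <- match.arg(unit, .PANEL_UNITS)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in panel; resolve or suffix before construction")
  if (!is.null(grouping)) {
    missing_cols <- setdiff(colnames(values), names(grouping))
    if (length(missing_cols))
      stop("grouping does not cover columns: ", paste(missing_cols, collapse = ", "))
    grouping <- grouping[colnames(values)]
  }
  structure(list(values = values, unit = unit, grouping = grouping,
                 zero_sd = zero_sd),
            class = "ExpressionPanel")
}

#' @exportS3Method base::print
print.ExpressionPanel <- function(x, ...) {
  cat(sprintf("ExpressionPanel: %d genes x %d columns [unit: %s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (length(x$zero_sd)) sprintf(" (%d zero-SD genes)", length(x$zero_sd)) else ""))
  invisible(x)
}

#' @export
dim.ExpressionPanel <- function(x) dim(x$values)

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
}

#' Read an expression panel from TSV/CSV
#'
#' The first column holds gene symbols; remaining columns are numeric.
#' Tab-separated by default, comma autodetected.  Duplicate gene symbols
#' (alternative transcripts) are kept distinct by suffixing `.2`, `.3`, ...
#' with a warning.
#'
#' @param path file path.
#' @param unit declared unit of the stored values.
#' @param grouping optional named character vector (column -> tissue group).
#' @return an [expression_panel()].
#' @export
read_expression_panel <- function(path, unit, grouping = NULL) {
  sep <- .detect_sep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression panel file needs a gene column plus >= 1 value column: ", path)
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      stop(sprintf("non-numeric value in column '%s', row %s of %s",
                   names(vals)[j], if (length(bad)) bad[1L] else "?", path))
    }
  }
  m <- as.matrix(vals)
  if (nrow(m) == 0L) stop("empty expression matrix: ", path)
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols suffixed in ", basename(path))
    genes <- make.unique(genes, sep = ".")
  }
  rownames(m) <- genes
  expression_panel(m, unit = unit, grouping = grouping)
}

#' Write an expression panel to TSV
#'
#' @param panel an [expression_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_panel <- function(panel, path) {
  df <- data.frame(gene = rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse cell-by-gene count matrix (MTX triplet)
#'
#' Matrix-Market triplet plus sidecar feature and barcode files, the layout
#' written by common single-cell quantifiers.  Rows are genes, columns cells.
#'
#' @param mtx path to the `.mtx` file.
#' @param features path to one-gene-per-line feature file (defaults to
#'   `features.tsv` next to `mtx`).
#' @param barcodes path to one-cell-per-line barcode file (defaults to
#'   `barcodes.tsv` next to `mtx`).
#' @return a `dgCMatrix` with gene rownames and cell colnames.
#' @export
read_cell_counts_mtx <- function(mtx,
                                 features = file.path(dirname(mtx), "features.tsv"),
                                 barcodes = file.path(dirname(mtx), "barcodes.tsv")) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(features)
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1L), 1L)
  cells <- readLines(barcodes)
  if (length(genes) != nrow(m) || length(cells) != ncol(m))
    stop("feature/barcode sidecars do not match matrix dimensions")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a sparse count matrix as MTX triplet with sidecars
#'
#' @param counts a sparse (or dense) genes-by-cells matrix with dimnames.
#' @param dir output directory; `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   are written inside.
#' @return `dir`, invisibly.
#' @export
write_cell_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# CellTable -------------------------------------------------------------------

#' Construct a per-cell table for one tumor sample
#'
#' Bundles the sparse count matrix with per-cell annotation labels and the
#' PTPRC (CD45) count used to call CD45-negative cells.
#'
#' @param counts genes-by-cells matrix (sparse or dense) with dimnames.
#' @param sample_id scalar sample identifier.
#' @param labels character vector of per-cell labels from the closed
#'   vocabulary `tumor, endothelial, myeloid, lymphoid, CAF, unknown`.
#' @param ptprc_gene gene symbol used for the CD45 transcript (default
#'   `"PTPRC"`).
#' @return an object of class `CellTable`.
#' @export
cell_table <- function(counts, sample_id, labels, ptprc_gene = "PTPRC") {
  stopifnot(length(labels) == ncol(counts))
  bad <- setdiff(unique(labels), .CELL_LABELS)
  if (length(bad)) stop("unknown cell labels: ", paste(bad, collapse = ", "))
  ptprc <- if (ptprc_gene %in% rownames(counts)) {
    as.numeric(counts[ptprc_gene, ])
  } else {
    warning("PTPRC gene '", ptprc_gene, "' absent from counts; all cells treated as CD45-")
    rep(0, ncol(counts))
  }
  structure(list(counts = counts, sample_id = sample_id,
                 cell_ids = colnames(counts), labels = labels,
                 ptprc = stats::setNames(ptprc, colnames(counts))),
            class = "CellTable")
}

#' CD45-negative flag per cell
#'
#' A cell is CD45-negative when its PTPRC RNA count equals zero.
#'
#' @param cells a [cell_table()].
#' @return named logical vector over cells.
#' @export
cd45_negative <- function(cells) cells$ptprc == 0

#' Counts-per-million transform
#'
#' @param counts genes-by-cells count matrix.
#' @param log2p1 if TRUE return `log2(CPM + 1)`.
#' @return matrix of the same shape.
#' @export
cpm <- function(counts, log2p1 = FALSE) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  out <- sweep(as.matrix(counts), 2L, totals, "/") * 1e6
  if (log2p1) log2(out + 1) else out
}

# Normalization primitives ----------------------------------------------------

#' Median-center columns, then z-score genes
#'
#' Each column is shifted by its median (centering across tissues or samples),
#' then each gene row is standardized to mean 0 and sample SD 1 (n - 1
#' denominator).  Rows with zero SD are set to all-zero and flagged in
#' `$zero_sd`; downstream correlation-based scores treat them as score 0
#' rather than NaN.
#'
#' @param panel an [expression_panel()] on a log or ordinal-numeric scale.
#' @return a z-scored [expression_panel()].
#' @export
median_center_zscore <- function(panel) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  m <- panel$values
  if (ncol(m) < 2L) stop("z-scoring undefined for a single-column panel")
  m <- sweep(m, 2L, apply(m, 2L, stats::median, na.rm = TRUE), "-")
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, stats::sd, na.rm = TRUE)
  flat <- !is.finite(s) | s == 0
  z <- (m - mu) / ifelse(flat, 1, s)
  z[flat, ] <- 0
  expression_panel(z, unit = "zscore", grouping = panel$grouping,
                   zero_sd = rownames(m)[flat])
}

#' Average panel columns within tissue groups
#'
#' @param panel an [expression_panel()] with a `grouping`.
#' @return an [expression_panel()] with one column per tissue group (same
#'   unit).
#' @export
average_by_group <- function(panel) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  if (is.null(panel$grouping)) stop("panel has no tissue-group mapping")
  groups <- unique(unname(panel$grouping))
  out <- vapply(groups, function(g) {
    rowMeans(panel$values[, panel$grouping == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(panel$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(rownames(panel$values), groups))
  colnames(out) <- groups
  expression_panel(out, unit = panel$unit)
}

#' Categorize bulk expression into Medium-High vs Not Detected-Low
#'
#' Tissue-group mean `log2(TPM + 1)` at or above the threshold (default 4) is
#' labelled `M-H`, anything below `ND-L`.  Columns are first averaged within
#' tissue groups.
#'
#' @param panel an [expression_panel()] with unit `log2p1` and a `grouping`.
#' @param threshold inclusive `log2(TPM + 1)` cutoff, default 4.
#' @return an [expression_panel()] of categories (one column per tissue
#'   group, unit `categorical`).
#' @export
categorize_bulk_expression <- function(panel, threshold = 4) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  if (panel$unit != "log2p1") stop("categorization expects a log2p1 panel")
  grouped <- average_by_group(panel)
  cat_m <- ifelse(grouped$values >= threshold, "M-H", "ND-L")
  expression_panel(cat_m, unit = "categorical")
}

#' Aggregate per-cell IHC categories to a tissue, then a tissue-group label
#'
#' Tissue rules over the cell-level categories `Not Detected, Low, Medium,
#' High`: `ND-L` when every cell is Not Detected or Low; `Medium` when every
#' cell is Medium; `M-H` when every cell is Medium or High (with at least one
#' High); `Variable` otherwise.  The tissue-group label is the hierarchy
#' maximum `M-H > Variable > Medium > ND-L` across tissues in the group.
#'
#' @param cell_categories list: one character vector of cell-level categories
#'   per tissue, named by tissue.
#' @param tissue_groups optional named character vector (tissue -> group); if
#'   supplied the result is per group, otherwise per tissue.
#' @return named character vector of labels.
#' @export
aggregate_ihc_tissue_group <- function(cell_categories, tissue_groups = NULL) {
  tissue_label <- function(cats) {
    bad <- setdiff(cats, .IHC_LEVELS)
    if (length(bad)) stop("unknown IHC category: ", paste(bad, collapse = ", "))
    if (all(cats %in% c("Not Detected", "Low"))) return("ND-L")
    if (all(cats == "Medium")) return("Medium")
    if (all(cats %in% c("Medium", "High"))) return("M-H")
    "Variable"
  }
  per_tissue <- vapply(cell_categories, tissue_label, character(1L))
  if (is.null(tissue_groups)) return(per_tissue)
  hierarchy <- c("ND-L" = 1, "Medium" = 2, "Variable" = 3, "M-H" = 4)
  groups <- unique(unname(tissue_groups[names(per_tissue)]))
  vapply(stats::setNames(groups, groups), function(g) {
    labs <- per_tissue[names(per_tissue)[tissue_groups[names(per_tissue)] == g]]
    names(hierarchy)[hierarchy == max(hierarchy[labs])][1L]
  }, character(1L))
}

#' Numeric recoding of IHC categories
#'
#' `Not Detected = 1, Low = 2, Medium = 3, High = 4`; used to build the
#' numeric IHC panel that is tissue-group averaged, median-centered and
#' z-scored like every other quantitative panel.
#'
#' @param categories character vector (or matrix) of IHC levels.
#' @return numeric object of the same shape.
#' @export
ihc_numeric <- function(categories) {
  codes <- c("Not Detected" = 1, "Low" = 2, "Medium" = 3, "High" = 4)
  bad <- setdiff(unique(as.vector(categories)), names(codes))
  if (length(bad)) stop("unknown IHC category: ", paste(bad, collapse = ", "))
  out <- codes[as.vector(categories)]
  if (is.matrix(categories))
    out <- matrix(out, nrow = nrow(categories), dimnames = dimnames(categories))
  out
}

#' Resolve gene-symbol aliases through a lookup table
#'
#' Standardizes symbols via a user-supplied two-column table (`alias`,
#' `symbol`).  Unresolved symbols pass through unchanged with a warning; no
#' network service is queried.
#'
#' @param symbols character vector.
#' @param alias_table data.frame with columns `alias` and `symbol`, or NULL.
#' @return character vector of the same length.
#' @export
resolve_gene_aliases <- function(symbols, alias_table = NULL) {
  if (is.null(alias_table)) return(symbols)
  stopifnot(all(c("alias", "symbol") %in% names(alias_table)))
  idx <- match(symbols, alias_table$alias)
  hit <- !is.na(idx)
  if (any(!hit) && any(hit))
    warning(sum(!hit), " gene symbols not in alias table; passed through unchanged")
  symbols[hit] <- alias_table$symbol[idx[hit]]
  symbols
}

#' Framework configuration with the published default thresholds
#'
#' Every numeric constant of the scoring framework, overridable by name.
#'
#' @param ... named overrides.
#' @return a named list of class `scanact_config`.
#' @export
scanact_config <- function(...) {
  cfg <- list(
    mh_log2tpm1_threshold = 4,        # Medium-High call on log2(TPM+1)
    fdr_cutoff = 0.25,                # DE significance
    log2fc_pseudocount = 0.01,
    cna_top_frac = 0.10,              # top CNA-burden CD45- cells for tumor profile
    cna_detect_percentile = 0.25,     # rho above this percentile -> CNA detected
    min_common_genes = 50,            # similarity-score gene intersection floor
    high_expr_percentile = 0.50,      # monospecific high-expression filter
    tcr_high_expr_percentile = 0.25,  # TCR/PC high-expression filter
    permissive_ref_percentile = 0.90, # cutoff on reference M-H tissue-group counts
    stringent_sc_ref_percentile = 0.75,
    zscore_high = 1,                  # "high" expression call on z-scores
    ts_car_cutoff_percentile = 0.25,  # reference percentile behind TS_CAR >= 5
    coexpr_alpha = 0.05,              # BH-adjusted significance for co-expression
    gtex_prot_max_missing = 0.25,
    ts_and_cutoff = 1,
    ts_andnot_percentile = 0.99,
    n_score_cutoff = 3.5,
    ts_tcr_percentile = 0.99,
    hlathena_min = 0.85,
    top_k_peptides = 5,
    presentation_min = 0.5,           # MHCflurry presentation floor (predicted-only)
    affinity_percentile_max = 2.0,
    s_sim_threshold = 1.15,           # cross-reactive flag
    s_cr_observed_bonus = 1.25,
    s_cr_diff_alpha = 2,
    excluded_celltypes = c("T-cells", "NK-cells", "B-cells", "plasma cells",
                           "fibroblasts", "adipocytes", "endometrial stromal cells",
                           "ovarian stromal cells", "granulosa cells", "oocytes",
                           "peritubular cells", "cytotrophoblasts",
                           "extravillous trophoblasts", "Hofbauer cells",
                           "syncytiotrophoblasts", "Leydig cells", "spermatocytes",
                           "late spermatids", "spermatogonia", "early spermatids",
                           "Sertoli cells"),
    excluded_tissues = c("fetal tissue", "testis", "ovary", "placenta",
                         "CD4 T-cells", "CD8 T-cells", "NK-cells", "B-cells",
                         "spleen", "immune cells", "immune tissue"),
    hla_excluded_genes = c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G",
                           "HLA-DRA", "HLA-DRB1", "HLA-DQA1", "HLA-DQB1",
                           "HLA-DPA1", "HLA-DPB1", "HLA-DMA", "HLA-DMB",
                           "HLA-DOA", "HLA-DOB"),
    seed = 1L)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "scanact_config")
}

# shared min-max helpers ------------------------------------------------------

#' Min-max normalization to \[0, 1\] over a pool
#'
#' Degenerate pools (single value, or max equal to min) normalize to 0 with a
#' warning so downstream sums stay defined.
#'
#' @param x numeric vector.
#' @return numeric vector in \[0, 1\].
#' @export
minmax01 <- function(x) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo) {
    warning("degenerate pool for min-max normalization; returning 0")
    return(rep(0, length(x)))
  }
  (x - lo) / (hi - lo)
}

.minmax_pm1 <- function(x, flip = FALSE) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (hi == lo) {
    warning("degenerate pool for min-max scaling; returning 0")
    return(rep(0, length(x)))
  }
  out <- ((x - lo) / (hi - lo)) * 2 - 1
  if (flip) -out else out
}
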