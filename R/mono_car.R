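# Monospecific CAR-T target nomination: high-expression filter, permissive
# and stringent on-target off-tumor toxicity filters, and the TS_CAR score.
#
# Dataset tags and their TS_CAR weights:
#   bulk RNA categorical panels (hpa_rna, gtex_rna)          +-1
#   protein panels (hpa_ihc, gtex_prot, hpm, hpa_ihc_num)    +-2
#   single-cell RNA panel (hpa_sc)                           +-1.5
.TSCAR_WEIGHTS <- c(hpa_rna = 1, gtex_rna = 1,
                    hpa_ihc = 2, gtex_prot = 2, hpm = 2, hpa_ihc_num = 2,
                    hpa_sc = 1.5)

#' High-tumor-expression filter for CAR candidates
#'
#' Keeps genes with expression at or above the pool percentile (default the
#' median) in both the single-cell data and the bulk tumor cohort, or in both
#' the single-cell data and the tumor cell lines.  Genes missing from both
#' external datasets are retained on single-cell expression alone.
#'
#' @param genes candidate gene symbols.
#' @param sc_expr named per-gene mean `log2(CPM + 1)` over tumor cells.
#' @param bulk_expr named per-gene mean `log2(TPM + 1)` over bulk tumor
#'   samples (NA/absent allowed).
#' @param line_expr named per-gene `log2(nTPM + 1)` in tumor cell lines
#'   (NA/absent allowed).
#' @param pct pool percentile in \[0, 1\], default 0.5.
#' @return character vector of retained genes.
#' @export
high_expression_filter <- function(genes, sc_expr, bulk_expr, line_expr, pct = 0.5) {
  if (!length(genes)) stop("empty candidate pool")
  sc <- sc_expr[genes]; bulk <- bulk_expr[genes]; line <- line_expr[genes]
  if (all(is.na(sc))) stop("no single-cell expression for the candidate pool")
  q_sc <- scanact_quantile(sc, pct)
  q_bulk <- if (all(is.na(bulk))) NA_real_ else scanact_quantile(bulk, pct)
  q_line <- if (all(is.na(line))) NA_real_ else scanact_quantile(line, pct)
  sc_hi <- !is.na(sc) & sc >= q_sc
  bulk_hi <- !is.na(bulk) & !is.na(q_bulk) & bulk >= q_bulk
  line_hi <- !is.na(line) & !is.na(q_line) & line >= q_line
  both_missing <- is.na(bulk) & is.na(line)
  genes[sc_hi & (bulk_hi | line_hi | both_missing)]
}

.count_mh <- function(cat_panel, gene) {
  if (!(gene %in% rownames(cat_panel$values))) return(NA_integer_)
  sum(cat_panel$values[gene, ] == "M-H")
}

#' Permissive on-target off-tumor toxicity filter
#'
#' For each categorized panel (tissue-group M-H / ND-L labels) the cutoff is
#' the 90th percentile of the number of M-H tissue groups among the tested
#' reference targets; a candidate passes when its own M-H count is strictly
#' below that cutoff.  Genes absent from a panel get verdict `absent`.
#'
#' @param genes candidate gene symbols.
#' @param panels named list of categorical [expression_panel()]s (tags among
#'   `hpa_rna`, `gtex_rna`, `hpa_ihc`).
#' @param references character vector of tested CAR-T reference targets.
#' @param ref_percentile default 0.90.
#' @return character matrix genes x panels with entries
#'   `pass`/`fail`/`absent`; cutoffs attached as attribute `cutoffs`.
#' @export
permissive_filter <- function(genes, panels, references, ref_percentile = 0.90) {
  stopifnot(length(names(panels)) == length(panels))
  verdicts <- matrix("absent", nrow = length(genes), ncol = length(panels),
                     dimnames = list(genes, names(panels)))
  cutoffs <- numeric(length(panels)); names(cutoffs) <- names(panels)
  for (tag in names(panels)) {
    panel <- panels[[tag]]
    ref_counts <- vapply(references, .count_mh, integer(1L), cat_panel = panel)
    ref_counts <- ref_counts[!is.na(ref_counts)]
    if (!length(ref_counts)) stop("no reference targets present in panel '", tag, "'")
    cutoffs[tag] <- scanact_quantile(as.numeric(ref_counts), ref_percentile)
    for (g in genes) {
      cnt <- .count_mh(panel, g)
      if (is.na(cnt)) next
      verdicts[g, tag] <- if (cnt < cutoffs[tag]) "pass" else "fail"
    }
  }
  attr(verdicts, "cutoffs") <- cutoffs
  verdicts
}

#' Stringent single-cell RNA toxicity filter
#'
#' Two conditions on the z-scored cell-type panel, after dropping the
#' excluded cell types (lymphoid, tumor-like stromal, gonadal/placental):
#' the candidate's number of cell types with z-score above 1 must not exceed
#' the 75th percentile of that count among the reference targets, and its
#' expression must be strictly below the per-cell-type reference maximum in
#' every retained cell type.
#'
#' @param genes candidate gene symbols.
#' @param sc_zpanel z-scored [expression_panel()] of cell-type means.
#' @param references tested CAR-T reference targets.
#' @param excluded_celltypes column labels to drop.
#' @param ref_percentile default 0.75.
#' @param z_high "high"-expression z threshold, default 1.
#' @return named character vector of verdicts `pass`/`fail`/`absent`.
#' @export
stringent_sc_filter <- function(genes, sc_zpanel, references,
                                excluded_celltypes = character(),
                                ref_percentile = 0.75, z_high = 1) {
  keep_cols <- setdiff(colnames(sc_zpanel$values), excluded_celltypes)
  z <- sc_zpanel$values[, keep_cols, drop = FALSE]
  refs <- intersect(references, rownames(z))
  if (!length(refs)) stop("no reference targets present in the single-cell panel")
  ref_counts <- rowSums(z[refs, , drop = FALSE] > z_high)
  count_cutoff <- scanact_quantile(as.numeric(ref_counts), ref_percentile)
  ref_max <- apply(z[refs, , drop = FALSE], 2L, max)
  vapply(stats::setNames(genes, genes), function(g) {
    if (!(g %in% rownames(z))) return("absent")
    v <- z[g, ]
    ok_count <- sum(v > z_high) <= count_cutoff
    ok_max <- all(v < ref_max)
    if (ok_count && ok_max) "pass" else "fail"
  }, character(1L))
}

#' Stringent protein-level toxicity filters
#'
#' For each z-scored protein panel the per-tissue (or tissue-group) maxima of
#' the reference targets are the thresholds; a candidate passes when it is
#' strictly below the threshold in every retained tissue.  NA tissues for a
#' gene are ignored; genes absent from a panel get `absent`.
#'
#' @param genes candidate gene symbols.
#' @param protein_zpanels named list of z-scored [expression_panel()]s (tags
#'   among `gtex_prot`, `hpm`, `hpa_ihc_num`).
#' @param references tested CAR-T reference targets.
#' @param excluded_tissues column labels to drop in every panel.
#' @return character matrix genes x panels of verdicts.
#' @export
stringent_protein_filter <- function(genes, protein_zpanels, references,
                                     excluded_tissues = character()) {
  verdicts <- matrix("absent", nrow = length(genes), ncol = length(protein_zpanels),
                     dimnames = list(genes, names(protein_zpanels)))
  for (tag in names(protein_zpanels)) {
    z <- protein_zpanels[[tag]]$values
    z <- z[, setdiff(colnames(z), excluded_tissues), drop = FALSE]
    refs <- intersect(references, rownames(z))
    if (!length(refs)) stop("no reference targets present in panel '", tag, "'")
    ref_max <- apply(z[refs, , drop = FALSE], 2L, max, na.rm = TRUE)
    for (g in genes) {
      if (!(g %in% rownames(z))) next
      v <- z[g, ]
      ok <- all(v < ref_max, na.rm = TRUE)
      verdicts[g, tag] <- if (ok) "pass" else "fail"
    }
  }
  verdicts
}

#' Monospecific CAR targetability score
#'
#' Weighted sum over the seven dataset verdicts: the two bulk RNA panels
#' weigh +-1, the four protein panels +-2, the single-cell RNA panel +-1.5;
#' a gene absent from a dataset contributes 0.  Range \[-11.5, 11.5\].
#'
#' @param verdicts named character vector (or one-row slice) of
#'   `pass`/`fail`/`absent` with names among
#'   `r paste(names(.TSCAR_WEIGHTS), collapse = ", ")`.
#' @return numeric score.
#' @export
ts_car <- function(verdicts) {
  tags <- names(verdicts)
  bad <- setdiff(tags, names(.TSCAR_WEIGHTS))
  if (length(bad)) stop("unknown dataset tag: ", paste(bad, collapse = ", "))
  w <- .TSCAR_WEIGHTS[tags]
  signs <- c(pass = 1, fail = -1, absent = 0)[as.character(verdicts)]
  if (anyNA(signs)) stop("verdicts must be pass/fail/absent")
  sum(w * signs)
}

#' Score a verdict table and select monospecific targets
#'
#' The selection cutoff is the 25th percentile of the reference targets'
#' TS_CAR scores (computed with the same panels); selection is inclusive
#' (score >= cutoff).  With fewer than 4 reference scores an explicit
#' numeric cutoff is required.
#'
#' @param verdict_matrix character matrix genes x datasets of verdicts
#'   (candidates and references together or candidates only).
#' @param reference_scores numeric TS_CAR values for the reference targets.
#' @param cutoff optional explicit numeric cutoff overriding the percentile.
#' @param ref_percentile default 0.25.
#' @return data.frame `gene`, `ts_car`, `selected`.
#' @export
select_mono_targets <- function(verdict_matrix, reference_scores = NULL,
                                cutoff = NULL, ref_percentile = 0.25) {
  scores <- apply(verdict_matrix, 1L, ts_car)
  if (is.null(cutoff)) {
    if (is.null(reference_scores) || length(reference_scores) < 4L)
      stop("need >= 4 reference TS_CAR scores or an explicit numeric cutoff")
    cutoff <- scanact_quantile(reference_scores, ref_percentile)
  }
  data.frame(gene = rownames(verdict_matrix), ts_car = unname(scores),
             selected = unname(scores >= cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the whole monospecific nomination stage
#'
#' Surfaceome restriction and HLA removal, normal-bias filter,
#' high-expression filter, both toxicity filters, TS_CAR scoring and target
#' selection.
#'
#' @param up_genes upregulated genes for one histotype.
#' @param comparisons full DE comparison table (for the normal-bias filter).
#' @param surfaceome character vector of surfaceome gene symbols.
#' @param sc_expr,bulk_expr,line_expr per-gene tumor expression vectors, as
#'   in [high_expression_filter()].
#' @param categorical_panels named list for [permissive_filter()].
#' @param sc_zpanel z-scored cell-type panel for [stringent_sc_filter()].
#' @param protein_zpanels named list for [stringent_protein_filter()].
#' @param references tested CAR-T reference targets.
#' @param config a [scanact_config()].
#' @return data.frame with per-dataset verdicts, `ts_car` and `selected`.
#' @export
nominate_mono_targets <- function(up_genes, comparisons, surfaceome,
                                  sc_expr, bulk_expr, line_expr,
                                  categorical_panels, sc_zpanel, protein_zpanels,
                                  references, config = scanact_config()) {
  pool <- setdiff(intersect(up_genes, surfaceome), config$hla_excluded_genes)
  pool <- pool[normal_bias_filter(pool, comparisons, fdr = config$fdr_cutoff)]
  pool <- high_expression_filter(pool, sc_expr, bulk_expr, line_expr,
                                 pct = config$high_expr_percentile)
  if (!length(pool)) return(data.frame(gene = character(), ts_car = numeric(),
                                       selected = logical()))
  score_rows <- function(genes) {
    perm <- permissive_filter(genes, categorical_panels, references,
                              ref_percentile = config$permissive_ref_percentile)
    sc_v <- stringent_sc_filter(genes, sc_zpanel, references,
                                excluded_celltypes = config$excluded_celltypes,
                                ref_percentile = config$stringent_sc_ref_percentile,
                                z_high = config$zscore_high)
    prot <- stringent_protein_filter(genes, protein_zpanels, references,
                                     excluded_tissues = config$excluded_tissues)
    cbind(perm, prot, hpa_sc = sc_v)
  }
  cand_verdicts <- score_rows(pool)
  ref_verdicts <- score_rows(references)
  ref_scores <- apply(ref_verdicts, 1L, ts_car)
  out <- select_mono_targets(cand_verdicts, reference_scores = ref_scores,
                             ref_percentile = config$ts_car_cutoff_percentile)
  cbind(out, as.data.frame(cand_verdicts, stringsAsFactors = FALSE),
        row.names = NULL)
}
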