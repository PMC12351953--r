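# Target Priority Indices: expression homogeneity (H_RNA), multi-evidence
# validation scores (V_CAR, V_TCR/PC) and the normalized TPI sums.

.ESSENTIALITY_CLASSES <- c("histotype", "any", "none")
.EVENT_CLASSES <- c("histotype", "any", "none")       # fusions, SNV/indel
.CNA_CLASSES <- c("histotype-rna-corr", "histotype", "none")
.DEV_CLASSES <- c("clinical", "preclinical", "none")  # antibody / CAR development

#' Expression-homogeneity score
#'
#' Product of the mean tumor-cell `log2(CPM + 1)` and the percentage of
#' tumor cells expressing the gene (`log2(CPM + 1) > 0`).
#'
#' @param cell_expr per-tumor-cell `log2(CPM + 1)` for one gene.
#' @return scalar `H_RNA`.
#' @export
h_rna <- function(cell_expr) {
  if (!length(cell_expr)) stop("H_RNA needs at least one tumor cell")
  mean(cell_expr) * (100 * mean(cell_expr > 0))
}

.class_score <- function(value, classes, points) {
  if (is.na(value) || !nzchar(value)) return(0)
  if (!(value %in% classes)) stop("unknown evidence class: ", value)
  points[[match(value, classes)]]
}

#' Validation score for (monospecific or gated) CAR targets
#'
#' Sum of eight evidence items, each scored against closed vocabularies:
#' expression homogeneity and clinical-proteomics prevalence each score 2
#' when at or above the reference antigen's value; clinical development of
#' antibodies and of CAR-T cells score 1 (clinical), 0.5 (preclinical) or 0;
#' cell-line essentiality, gene fusions, SNV/indels and copy-number events
#' score 1 (in the histotype; for copy number, with positive copy-number to
#' expression correlation), 0.5 (in any histotype / without the
#' correlation) or 0.  Range \[0, 10\].  Missing fields score 0 with a
#' warning.
#'
#' @param evidence one-row data.frame (or named list) with fields `h_rna`,
#'   `proteomics_mh_pct`, `antibody_class`, `car_class`, `essentiality`,
#'   `fusion`, `snv_indel`, `cna`.
#' @param references list with `h_rna_ref` and `proteomics_mh_pct_ref`
#'   (reference-antigen values; must be supplied, no silent defaults).
#' @return scalar `V_CAR`.
#' @export
v_car <- function(evidence, references) {
  if (is.null(references$h_rna_ref) || is.null(references$proteomics_mh_pct_ref))
    stop("reference constants (h_rna_ref, proteomics_mh_pct_ref) must be supplied")
  get <- function(f) {
    if (is.null(evidence[[f]]) || (length(evidence[[f]]) == 1L && is.na(evidence[[f]]))) {
      warning("evidence field '", f, "' missing; scored as 0")
      return(NA)
    }
    evidence[[f]]
  }
  num <- function(f) { v <- get(f); if (length(v) == 1L && is.na(v)) -Inf else v }
  chr <- function(f) { v <- get(f); if (length(v) == 1L && is.na(v)) "none" else v }
  sum(if (num("h_rna") >= references$h_rna_ref) 2 else 0,
      if (num("proteomics_mh_pct") >= references$proteomics_mh_pct_ref) 2 else 0,
      .class_score(chr("antibody_class"), .DEV_CLASSES, c(1, 0.5, 0)),
      .class_score(chr("car_class"), .DEV_CLASSES, c(1, 0.5, 0)),
      .class_score(chr("essentiality"), .ESSENTIALITY_CLASSES, c(1, 0.5, 0)),
      .class_score(chr("fusion"), .EVENT_CLASSES, c(1, 0.5, 0)),
      .class_score(chr("snv_indel"), .EVENT_CLASSES, c(1, 0.5, 0)),
      .class_score(chr("cna"), .CNA_CLASSES, c(1, 0.5, 0)))
}

#' Validation score for TCR-T / PC-CAR targets
#'
#' Six items: expression homogeneity versus the reference antigen (2),
#' protein support in at least two tumor cell lines (1), then essentiality,
#' fusions, SNV/indels and copy-number events as in [v_car()].  Range
#' \[0, 7\].
#'
#' @param evidence one-row data.frame/list with fields `h_rna`,
#'   `cellline_protein` (logical), `essentiality`, `fusion`, `snv_indel`,
#'   `cna`.
#' @param references list with `h_rna_ref`.
#' @return scalar `V_TCR/PC`.
#' @export
v_tcr_pc <- function(evidence, references) {
  if (is.null(references$h_rna_ref))
    stop("reference constant h_rna_ref must be supplied")
  hr <- evidence$h_rna %||% NA
  clp <- evidence$cellline_protein %||% NA
  sum(if (!is.na(hr) && hr >= references$h_rna_ref) 2 else 0,
      if (!is.na(clp) && isTRUE(clp)) 1 else 0,
      .class_score(evidence$essentiality %||% "none", .ESSENTIALITY_CLASSES, c(1, 0.5, 0)),
      .class_score(evidence$fusion %||% "none", .EVENT_CLASSES, c(1, 0.5, 0)),
      .class_score(evidence$snv_indel %||% "none", .EVENT_CLASSES, c(1, 0.5, 0)),
      .class_score(evidence$cna %||% "none", .CNA_CLASSES, c(1, 0.5, 0)))
}

#' Target priority index for monospecific CAR targets
#'
#' Min-max normalizes the targetability scores and the validation scores
#' over the selected-target pool and sums them; `TPI` lies in \[0, 2\].
#'
#' @param ts_car_values named per-gene TS_CAR scores.
#' @param v_values named per-gene V_CAR scores (same genes).
#' @return data.frame `gene`, `ts_norm`, `v_norm`, `tpi`, ordered by
#'   decreasing `tpi` (stable in gene order on ties).
#' @export
tpi_car <- function(ts_car_values, v_values) {
  genes <- names(ts_car_values)
  stopifnot(!is.null(genes), identical(sort(genes), sort(names(v_values))))
  v_values <- v_values[genes]
  if (length(genes) < 2L) warning("fewer than 2 targets; normalized components are 0")
  ts_n <- suppressWarnings(minmax01(ts_car_values))
  v_n <- suppressWarnings(minmax01(v_values))
  if (length(genes) < 2L) { ts_n[] <- 0; v_n[] <- 0 }
  out <- data.frame(gene = genes, ts_norm = unname(ts_n), v_norm = unname(v_n),
                    tpi = unname(ts_n + v_n), stringsAsFactors = FALSE)
  out[order(-out$tpi, seq_len(nrow(out))), , drop = FALSE]
}

#' Target priority index for logic-gated CAR genes
#'
#' For each "AND" target gene (or "AND-NOT" activator) the mean pair score
#' over all selected pairs containing it is normalized and summed with the
#' normalized validation score, exactly as [tpi_car()].
#'
#' @param pair_scores data.frame of selected pairs with score column `ts`
#'   and gene columns named by `gene_cols`.
#' @param v_values named per-gene V_CAR scores.
#' @param gene_cols columns of `pair_scores` whose genes enter the ranking
#'   (both for "AND", the activator only for "AND-NOT").
#' @param score_col name of the pair score column.
#' @return data.frame as in [tpi_car()], plus `mean_ts`.
#' @export
tpi_gate <- function(pair_scores, v_values, gene_cols, score_col) {
  long <- do.call(rbind, lapply(gene_cols, function(cl) {
    data.frame(gene = pair_scores[[cl]], ts = pair_scores[[score_col]],
               stringsAsFactors = FALSE)
  }))
  mean_ts <- tapply(long$ts, long$gene, mean)
  genes <- names(mean_ts)
  v <- v_values[genes]
  if (anyNA(v)) stop("missing validation scores for: ",
                     paste(genes[is.na(v)], collapse = ", "))
  out <- tpi_car(stats::setNames(as.numeric(mean_ts), genes), v)
  out$mean_ts <- as.numeric(mean_ts[out$gene])
  out
}

#' Target priority index for TCR-T / PC-CAR antigens
#'
#' Five normalized components per antigen: the normal-expression score
#' `N(g)`, the validation score, the summed per-locus mean HLA allele
#' frequency of its candidate pMHCs (`HLA_TOT`), and the length-normalized
#' counts of candidate pMHCs (`pMHC_TOT`) and of pMHCs with acceptable
#' cross-reactivity (`pMHC_SCR`, those with `S_CR Diff <= 0`).  `TPI` lies
#' in \[0, 5\].
#'
#' @param antigens character vector of antigen symbols.
#' @param n_scores named `N(g)` values.
#' @param v_scores named `V_TCR/PC` values.
#' @param pmhcs data.frame of candidate pMHCs with columns `antigen`,
#'   `allele`, `f_allele`, and logical `scr_acceptable` (`S_CR Diff <= 0`).
#' @param protein_lengths named amino-acid lengths per antigen.
#' @return data.frame with raw and normalized components and `tpi`, ordered
#'   by decreasing `tpi`.
#' @export
tpi_tcr_pc <- function(antigens, n_scores, v_scores, pmhcs, protein_lengths) {
  stopifnot(all(antigens %in% names(n_scores)),
            all(antigens %in% names(v_scores)),
            all(antigens %in% names(protein_lengths)))
  locus <- function(allele) sub("\\*.*$", "", .normalize_allele(allele))
  hla_tot <- pmhc_tot <- pmhc_scr <- stats::setNames(numeric(length(antigens)), antigens)
  for (ag in antigens) {
    sub <- pmhcs[pmhcs$antigen == ag, , drop = FALSE]
    L <- protein_lengths[[ag]]
    if (L <= 0) stop("protein length must be positive for ", ag)
    if (nrow(sub)) {
      by_locus <- tapply(sub$f_allele, locus(sub$allele), mean)
      hla_tot[ag] <- sum(by_locus[c("A", "B", "C")], na.rm = TRUE)
      pmhc_tot[ag] <- nrow(sub) / L
      pmhc_scr[ag] <- sum(sub$scr_acceptable, na.rm = TRUE) / L
    }
  }
  norm <- function(x) {
    if (length(x) < 2L || max(x) == min(x)) {
      warning("degenerate antigen pool; normalized component set to 0")
      return(stats::setNames(rep(0, length(x)), names(x)))
    }
    minmax01(x)
  }
  n_n <- norm(n_scores[antigens]); v_n <- norm(v_scores[antigens])
  h_n <- norm(hla_tot); pt_n <- norm(pmhc_tot); ps_n <- norm(pmhc_scr)
  out <- data.frame(antigen = antigens,
                    n_score = unname(n_scores[antigens]), n_norm = unname(n_n),
                    v_score = unname(v_scores[antigens]), v_norm = unname(v_n),
                    hla_tot = unname(hla_tot), hla_norm = unname(h_n),
                    pmhc_tot = unname(pmhc_tot), pmhc_tot_norm = unname(pt_n),
                    pmhc_scr = unname(pmhc_scr), pmhc_scr_norm = unname(ps_n),
                    stringsAsFactors = FALSE)
  out$tpi <- out$n_norm + out$v_norm + out$hla_norm + out$pmhc_tot_norm + out$pmhc_scr_norm
  out[order(-out$tpi, seq_len(nrow(out))), , drop = FALSE]
}
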