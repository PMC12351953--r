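# Logic-gated ("AND", "AND-NOT") gene-pair scoring.
#
# Dataset tags and weights shared by the raw N and raw TS_'AND-NOT' sums:
#   bulk RNA z-panels (hpa_rna, gtex_rna), Pearson          +-1
#   odds-ratio panels (hpa_ihc_num, hpm)                    +-2
#   single-cell RNA z-panel (hpa_sc), Pearson               +-1.5
#   tissue proteomics z-panel (gtex_prot), Pearson          +-2
.GATE_WEIGHTS <- c(hpa_rna = 1, gtex_rna = 1, hpa_ihc_num = 2, hpm = 2,
                   hpa_sc = 1.5, gtex_prot = 2)
.GATE_CORR_TAGS <- c("hpa_rna", "gtex_rna", "hpa_sc", "gtex_prot")
.GATE_OR_TAGS <- c("hpa_ihc_num", "hpm")

#' All unordered pairs of a gene pool
#'
#' @param genes character vector.
#' @return data.frame `gene_i`, `gene_j` (i < j in pool order).
#' @export
gene_pairs <- function(genes) {
  idx <- utils::combn(length(genes), 2L)
  data.frame(gene_i = genes[idx[1L, ]], gene_j = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Default single-cell co-expression estimator
#'
#' Spearman correlation on `log2(CPM + 1)` across tumor cells with the
#' t-approximation p-value, the standard stand-in when a dedicated
#' sparse-count co-expression estimator's output is not supplied as a table.
#'
#' @param expr genes x cells `log2(CPM + 1)` matrix.
#' @param pairs data.frame `gene_i`, `gene_j`.
#' @return data.frame `gene_i`, `gene_j`, `rho`, `p`.
#' @export
spearman_coexpression <- function(expr, pairs) {
  ranks <- t(apply(expr, 1L, rank))
  res <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- ranks[pairs$gene_i[k], ]; y <- ranks[pairs$gene_j[k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(0, 1))
    rho <- stats::cor(x, y)
    n <- length(x)
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    c(rho, 2 * stats::pt(-abs(tt), df = n - 2))
  }, numeric(2L))
  cbind(pairs, data.frame(rho = res[1L, ], p = res[2L, ]))
}

#' Tumor-cell co-expression with multiple-testing control
#'
#' Runs the estimator over all pairs, BH-corrects the p-values across the
#' tested pairs, and zeroes every correlation whose adjusted p-value is at
#' or above `alpha` (0.05).
#'
#' @param counts genes x cells raw counts over tumor cells.
#' @param genes gene pool (all unordered pairs are scored).
#' @param estimator function `(expr, pairs) -> data.frame(rho, p)`; defaults
#'   to [spearman_coexpression()].  Externally computed tables (e.g. from a
#'   sparse-count co-expression model) can be injected via a closure.
#' @param alpha adjusted-p significance threshold, default 0.05.
#' @return data.frame `gene_i`, `gene_j`, `rho`, `p`, `padj`, `rho_tumor`
#'   (zeroed where non-significant).
#' @export
tumor_coexpression <- function(counts, genes, estimator = spearman_coexpression,
                               alpha = 0.05) {
  if (ncol(counts) < 20L) stop("need >= 20 tumor cells for co-expression estimation")
  missing <- setdiff(genes, rownames(counts))
  if (length(missing)) stop("genes absent from counts: ", paste(missing, collapse = ", "))
  # library sizes from the full matrix, then subset: normalizing within the
  # pair pool alone would induce compositional anti-correlation
  expr <- cpm(counts, log2p1 = TRUE)[genes, , drop = FALSE]
  res <- estimator(expr, gene_pairs(genes))
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res$rho_tumor <- ifelse(res$padj < alpha, res$rho, 0)
  res
}

#' Modified odds ratio for "AND" pairs
#'
#' Over the panel columns, with `d` the number where both genes have z-score
#' above `zcut`, `b` where only the first does and `c` where only the
#' second does: `OR = d / (b * c)`; 0 when both `d` and `b * c` are 0, and
#' `Inf` when `b * c = 0` with `d > 0` (treated as co-expression, i.e. a
#' failing pair).
#'
#' @param zpanel z-scored [expression_panel()] (or plain matrix).
#' @param gene_i,gene_j gene symbols.
#' @param zcut z threshold, default 1.
#' @return scalar odds ratio (possibly `Inf`).
#' @export
or_mod_and <- function(zpanel, gene_i, gene_j, zcut = 1) {
  z <- if (inherits(zpanel, "ExpressionPanel")) zpanel$values else zpanel
  hi <- z[c(gene_i, gene_j), , drop = FALSE] > zcut
  keep <- !is.na(hi[1L, ]) & !is.na(hi[2L, ])
  hi <- hi[, keep, drop = FALSE]
  d <- sum(hi[1L, ] & hi[2L, ])
  b <- sum(hi[1L, ] & !hi[2L, ])
  cc <- sum(!hi[1L, ] & hi[2L, ])
  if (d == 0 && b * cc == 0) return(0)
  d / (b * cc)
}

#' Modified odds ratio for "AND-NOT" pairs
#'
#' `d` counts columns where activator and inhibitor both exceed the z
#' threshold, `b` columns where only the activator does; `OR = d / b`, with
#' `Inf` whenever `b = 0` (including `d = b = 0`).  `Inf` marks a suitable
#' pair: wherever the activator is high the inhibitor is high too.
#'
#' @param zpanel z-scored panel (or matrix).
#' @param activator,inhibitor gene symbols.
#' @param zcut z threshold, default 1.
#' @return scalar odds ratio (possibly `Inf`).
#' @export
or_mod_andnot <- function(zpanel, activator, inhibitor, zcut = 1) {
  z <- if (inherits(zpanel, "ExpressionPanel")) zpanel$values else zpanel
  hi <- z[c(activator, inhibitor), , drop = FALSE] > zcut
  keep <- !is.na(hi[1L, ]) & !is.na(hi[2L, ])
  hi <- hi[, keep, drop = FALSE]
  d <- sum(hi[1L, ] & hi[2L, ])
  b <- sum(hi[1L, ] & !hi[2L, ])
  if (b == 0) return(Inf)
  d / b
}

# Pairwise Pearson with BH across pairs within one dataset.  Returns a score
# vector following a piecewise rule; genes absent, zero-SD, or non-significant
# score 0.
.corr_dataset_scores <- function(zpanel, pairs, weight, alpha, reward_sign) {
  z <- if (inherits(zpanel, "ExpressionPanel")) zpanel$values else zpanel
  zero_sd <- if (inherits(zpanel, "ExpressionPanel")) zpanel$zero_sd else character()
  n <- nrow(pairs)
  rho <- rep(NA_real_, n); p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    gi <- pairs[[1L]][k]; gj <- pairs[[2L]][k]
    if (!(gi %in% rownames(z)) || !(gj %in% rownames(z))) next
    if (gi %in% zero_sd || gj %in% zero_sd) { rho[k] <- 0; p[k] <- 1; next }
    x <- z[gi, ]; y <- z[gj, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rho[k] <- 0; p[k] <- 1; next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "pearson"))
    rho[k] <- unname(ct$estimate); p[k] <- ct$p.value
  }
  padj <- rep(NA_real_, n)
  tested <- !is.na(p)
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  score <- numeric(n)
  sig <- tested & padj < alpha & rho != 0
  # reward_sign = -1: mutual exclusivity (rho < 0) rewarded ("AND")
  # reward_sign = +1: normal co-expression (rho > 0) rewarded ("AND-NOT")
  score[sig & sign(rho) == reward_sign] <- weight
  score[sig & sign(rho) == -reward_sign] <- -weight
  list(score = score, rho = rho, padj = padj)
}

# Drop genes with more than `max_missing` fraction of NA columns (tissue
# proteomics rule).
.filter_missing_genes <- function(zpanel, max_missing = 0.25) {
  z <- zpanel$values
  frac_na <- rowMeans(is.na(z))
  keep <- frac_na <= max_missing
  expression_panel(z[keep, , drop = FALSE], unit = zpanel$unit,
                   grouping = zpanel$grouping,
                   zero_sd = intersect(zpanel$zero_sd, rownames(z)[keep]))
}

#' Normal-tissue co-expression score N for "AND" pairs
#'
#' Sums per-dataset evidence of mutual exclusivity across normal tissues and
#' cells: Pearson datasets reward significantly negative correlation
#' (mutually exclusive expression) with `+weight` and penalize significantly
#' positive correlation with `-weight` (bulk +-1, single-cell +-1.5, tissue
#' proteomics +-2 after removing genes with > 25% missing values);
#' odds-ratio datasets score `+2` when `OR = 0` (mutual exclusion) and `-2`
#' otherwise; absent genes contribute 0.  `N_norm` rescales N over the pair
#' pool to \[-1, 1\] with a sign flip so that positive values mean higher
#' normal co-expression risk.
#'
#' @param pairs data.frame `gene_i`, `gene_j`.
#' @param datasets named list of z-scored panels with tags among
#'   `hpa_rna, gtex_rna, hpa_sc, gtex_prot, hpa_ihc_num, hpm`.
#' @param alpha BH-adjusted significance threshold, default 0.05.
#' @param zcut z threshold for the odds-ratio datasets, default 1.
#' @param max_missing missing-value fraction tolerated in `gtex_prot`.
#' @return data.frame `gene_i`, `gene_j`, `n_raw`, `n_norm` plus per-dataset
#'   score columns.
#' @export
normal_coexpression_N <- function(pairs, datasets, alpha = 0.05, zcut = 1,
                                  max_missing = 0.25) {
  bad <- setdiff(names(datasets), names(.GATE_WEIGHTS))
  if (length(bad)) stop("unknown dataset tag: ", paste(bad, collapse = ", "))
  total <- numeric(nrow(pairs))
  per_ds <- list()
  for (tag in names(datasets)) {
    panel <- datasets[[tag]]
    if (tag == "gtex_prot") panel <- .filter_missing_genes(panel, max_missing)
    w <- .GATE_WEIGHTS[[tag]]
    if (tag %in% .GATE_CORR_TAGS) {
      sc <- .corr_dataset_scores(panel, pairs, w, alpha, reward_sign = -1)$score
    } else {
      z <- panel$values
      sc <- vapply(seq_len(nrow(pairs)), function(k) {
        gi <- pairs$gene_i[k]; gj <- pairs$gene_j[k]
        if (!(gi %in% rownames(z)) || !(gj %in% rownames(z))) return(0)
        orv <- or_mod_and(z, gi, gj, zcut = zcut)
        if (orv == 0) w else -w
      }, numeric(1L))
    }
    total <- total + sc
    per_ds[[paste0("score_", tag)]] <- sc
  }
  out <- cbind(pairs, data.frame(n_raw = total, stringsAsFactors = FALSE),
               as.data.frame(per_ds))
  out$n_norm <- .minmax_pm1(out$n_raw, flip = TRUE)
  out
}

#' "AND" targetability score
#'
#' `TS = rho_tumor - N_norm`; pairs with `TS >= cutoff` (default 1) are
#' selected: co-expressed in tumor, mutually exclusive in normal tissue.
#'
#' @param rho_tumor significance-gated tumor co-expression in \[-1, 1\].
#' @param n_norm normalized normal co-expression in \[-1, 1\].
#' @param cutoff selection cutoff, default 1.
#' @return data.frame `ts_and`, `selected`.
#' @export
ts_and <- function(rho_tumor, n_norm, cutoff = 1) {
  ts <- rho_tumor - n_norm
  data.frame(ts_and = ts, selected = ts >= cutoff)
}

#' Inhibitor candidate pool for "AND-NOT" designs
#'
#' Surfaceome genes among the downregulated set with tumor single-cell
#' expression strictly below the pool's 50th percentile.
#'
#' @param down_genes downregulated genes for the histotype.
#' @param surfaceome surfaceome gene symbols.
#' @param sc_expr named per-gene mean `log2(CPM + 1)` over tumor cells.
#' @param pct percentile, default 0.5.
#' @return character vector of inhibitor candidates.
#' @export
inhibitor_pool <- function(down_genes, surfaceome, sc_expr, pct = 0.5) {
  pool <- intersect(down_genes, surfaceome)
  if (!length(pool)) stop("no downregulated surfaceome genes to draw inhibitors from")
  e <- sc_expr[pool]
  q <- scanact_quantile(e, pct)
  pool[!is.na(e) & e < q]
}

# Proportions I (inhibitor z >= activator z) and A (activator z > inhibitor z)
# over the dataset's retained columns.
.ia_proportions <- function(z, activator, inhibitor) {
  x <- z[activator, ]; y <- z[inhibitor, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(c(I = 0, A = 0))
  c(I = mean(y[ok] >= x[ok]), A = mean(x[ok] > y[ok]))
}

#' Raw and normalized "AND-NOT" targetability scores
#'
#' Per dataset, pairs where the inhibitor shadows the activator across
#' normal tissue are rewarded: Pearson datasets reward significantly
#' positive correlation (protective normal co-expression) with
#' `+weight * (1 + I)` and penalize significantly negative correlation with
#' `-weight * (1 + A)`; odds-ratio datasets reward `OR = Inf` with
#' `+2 * (1 + I)` and penalize otherwise with `-2 * (1 + A)`.  `I` is the
#' proportion of dataset columns where the inhibitor's z-score is at or
#' above the activator's; `A` the proportion where the activator's exceeds
#' the inhibitor's.  Raw scores are min-max scaled to \[-1, 1\] over the
#' pool (no sign flip); pairs strictly above the pool's 99th percentile of
#' the normalized score are selected.
#'
#' @param pairs data.frame `activator`, `inhibitor`.
#' @param datasets named list of z-scored panels (tags as in
#'   [normal_coexpression_N()]).
#' @param alpha BH threshold, default 0.05.
#' @param zcut z threshold for odds-ratio datasets, default 1.
#' @param selection_percentile default 0.99.
#' @param max_missing missing-value tolerance for `gtex_prot`.
#' @return data.frame `activator`, `inhibitor`, `ts_raw`, `ts_norm`,
#'   `selected` plus per-dataset scores.
#' @export
ts_and_not <- function(pairs, datasets, alpha = 0.05, zcut = 1,
                       selection_percentile = 0.99, max_missing = 0.25) {
  bad <- setdiff(names(datasets), names(.GATE_WEIGHTS))
  if (length(bad)) stop("unknown dataset tag: ", paste(bad, collapse = ", "))
  total <- numeric(nrow(pairs))
  per_ds <- list()
  for (tag in names(datasets)) {
    panel <- datasets[[tag]]
    if (tag == "gtex_prot") panel <- .filter_missing_genes(panel, max_missing)
    z <- panel$values
    w <- .GATE_WEIGHTS[[tag]]
    if (tag %in% .GATE_CORR_TAGS) {
      base <- .corr_dataset_scores(panel, pairs, 1, alpha, reward_sign = +1)$score
      sc <- vapply(seq_len(nrow(pairs)), function(k) {
        if (base[k] == 0) return(0)
        ia <- .ia_proportions(z, pairs$activator[k], pairs$inhibitor[k])
        if (base[k] > 0) w * (1 + ia[["I"]]) else -w * (1 + ia[["A"]])
      }, numeric(1L))
    } else {
      sc <- vapply(seq_len(nrow(pairs)), function(k) {
        ga <- pairs$activator[k]; gi <- pairs$inhibitor[k]
        if (!(ga %in% rownames(z)) || !(gi %in% rownames(z))) return(0)
        ia <- .ia_proportions(z, ga, gi)
        orv <- or_mod_andnot(z, ga, gi, zcut = zcut)
        if (is.infinite(orv)) w * (1 + ia[["I"]]) else -w * (1 + ia[["A"]])
      }, numeric(1L))
    }
    total <- total + sc
    per_ds[[paste0("score_", tag)]] <- sc
  }
  ts_norm <- .minmax_pm1(total, flip = FALSE)
  cutoff <- scanact_quantile(ts_norm, selection_percentile)
  cbind(pairs,
        data.frame(ts_raw = total, ts_norm = ts_norm,
                   selected = ts_norm > cutoff, stringsAsFactors = FALSE),
        as.data.frame(per_ds))
}

#' Serialize a pair table (infinite odds ratios as the token "Inf")
#'
#' @param pairs data.frame of pair scores.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  df <- pairs
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- ifelse(is.infinite(df[[j]]), "Inf", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
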