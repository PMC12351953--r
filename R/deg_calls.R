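# Aggregation of per-comparison differential-expression tables into
# per-histotype up/down gene calls.  The DE engines themselves (pseudobulk
# linear models, distribution tests) are upstream; their result tables are
# the input contract here.

#' Pseudocount log2 fold change on CPM means
#'
#' `log2((tumor + 0.01) / (normal + 0.01))` with the 0.01 pseudocount keeping
#' all-zero genes defined.
#'
#' @param mean_tumor_cpm,mean_normal_cpm non-negative CPM means.
#' @param pseudocount default 0.01.
#' @return log2 fold change (vectorized).
#' @export
log2fc_cpm <- function(mean_tumor_cpm, mean_normal_cpm, pseudocount = 0.01) {
  if (any(mean_tumor_cpm < 0) || any(mean_normal_cpm < 0))
    stop("CPM means must be non-negative")
  log2((mean_tumor_cpm + pseudocount) / (mean_normal_cpm + pseudocount))
}

.check_deg_table <- function(comparisons) {
  need <- c("gene", "log2fc", "padj", "comparison", "ref_class")
  missing <- setdiff(need, names(comparisons))
  if (length(missing))
    stop("comparison table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(comparisons) == 0L) stop("empty comparison table")
  if (any(comparisons$padj < 0 | comparisons$padj > 1, na.rm = TRUE))
    stop("adjusted p-values outside [0, 1]")
  invisible(comparisons)
}

#' Aggregate differential-expression calls into up/down gene sets
#'
#' A gene is upregulated if it is significantly up (`log2fc > 0`,
#' `padj < fdr`) in at least one comparison.  A gene is downregulated if it
#' is significantly down in at least one comparison and never significantly
#' up, evaluated separately within each reference class (tumor-microenvironment
#' vs normal-tissue panels) and then unioned; `strict_joint = TRUE` instead
#' requires "never up" across both classes jointly.
#'
#' @param comparisons data.frame with columns `gene`, `log2fc`, `padj`,
#'   `comparison`, `ref_class`.
#' @param fdr significance cutoff on the adjusted p-value, default 0.25.
#' @param strict_joint apply the never-upregulated rule across classes.
#' @return list of class `DEGCallSet`: `up`, `down` (character vectors) and
#'   `support` (per-gene supporting comparison ids).
#' @export
aggregate_deg_calls <- function(comparisons, fdr = 0.25, strict_joint = FALSE) {
  .check_deg_table(comparisons)
  sig <- !is.na(comparisons$padj) & comparisons$padj < fdr & comparisons$log2fc != 0
  up_rows <- sig & comparisons$log2fc > 0
  dn_rows <- sig & comparisons$log2fc < 0
  up <- sort(unique(comparisons$gene[up_rows]))
  down <- character()
  for (cls in unique(comparisons$ref_class)) {
    in_cls <- comparisons$ref_class == cls
    up_cls <- unique(comparisons$gene[up_rows & in_cls])
    dn_cls <- unique(comparisons$gene[dn_rows & in_cls])
    down <- union(down, setdiff(dn_cls, up_cls))
  }
  if (strict_joint) down <- setdiff(down, up)
  support <- function(rows) {
    split(comparisons$comparison[rows], comparisons$gene[rows])
  }
  structure(list(up = up, down = sort(down),
                 support = list(up = support(up_rows), down = support(dn_rows))),
            class = "DEGCallSet")
}

#' @exportS3Method base::print
print.DEGCallSet <- function(x, ...) {
  cat(sprintf("DEGCallSet: %d up, %d down genes\n", length(x$up), length(x$down)))
  invisible(x)
}

#' Normal-bias filter on upregulated genes
#'
#' Drops a gene when, over all comparisons in which it appears, the number of
#' significant comparisons favoring normal cells (`log2fc < 0`) strictly
#' exceeds those favoring tumor cells (`log2fc > 0`).
#'
#' @param genes candidate genes (typically the up set).
#' @param comparisons the full comparison table.
#' @param fdr significance cutoff, default 0.25.
#' @return logical keep-flag vector named by gene.
#' @export
normal_bias_filter <- function(genes, comparisons, fdr = 0.25) {
  .check_deg_table(comparisons)
  sig <- !is.na(comparisons$padj) & comparisons$padj < fdr & comparisons$log2fc != 0
  vapply(stats::setNames(genes, genes), function(g) {
    rows <- sig & comparisons$gene == g
    tumor <- sum(comparisons$log2fc[rows] > 0)
    normal <- sum(comparisons$log2fc[rows] < 0)
    normal <= tumor
  }, logical(1L))
}

#' Read a differential-expression comparison table
#'
#' @param path TSV with header `gene log2fc padj comparison ref_class`.
#' @return validated data.frame.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE)
  .check_deg_table(df)
}

#' Write a DEG call set as TSV
#'
#' @param calls a `DEGCallSet`.
#' @param path output TSV (one row per gene: `gene direction`).
#' @return `path`, invisibly.
#' @export
write_deg_calls <- function(calls, path) {
  df <- rbind(
    data.frame(gene = calls$up, direction = "up", stringsAsFactors = FALSE),
    data.frame(gene = calls$down, direction = "down", stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
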