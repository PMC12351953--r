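# TCR-T / peptide-centric CAR target antigen nomination and candidate
# peptide-MHC selection.  Presentation (HLAthena-style) and immunogenicity
# (DeepImmuno-style) predictors are consumed as score tables keyed by
# (peptide, allele); the models are never invoked here.

# N(g) weights: bulk RNA +1, protein +2, single-cell RNA +1.5 (pass/0, no
# penalties: candidates are compared to cancer-germline-antigen references).
.NSCORE_WEIGHTS <- c(hpa_rna = 1, gtex_rna = 1,
                     hpa_ihc_num = 2, gtex_prot = 2, hpm = 2,
                     hpa_sc = 1.5)

#' Normal-expression score N(g) against cancer-germline-antigen references
#'
#' For each z-scored panel the candidate scores the dataset's weight when
#' its expression is below the reference maximum in every tissue group (or
#' cell type), and 0 otherwise or when absent: two bulk RNA panels (+1),
#' three protein panels (+2), one single-cell panel (+1.5).  Maximum 9.5.
#'
#' @param genes candidate gene symbols.
#' @param datasets named list of z-scored [expression_panel()]s with tags
#'   among `hpa_rna, gtex_rna, hpa_ihc_num, gtex_prot, hpm, hpa_sc`.
#' @param cga_references reference target symbols (cancer germline
#'   antigens in clinical TCR-T development).
#' @return data.frame `gene`, per-dataset `t_` columns, `n_score`.
#' @export
n_score <- function(genes, datasets, cga_references) {
  bad <- setdiff(names(datasets), names(.NSCORE_WEIGHTS))
  if (length(bad)) stop("unknown dataset tag: ", paste(bad, collapse = ", "))
  scores <- matrix(0, nrow = length(genes), ncol = length(datasets),
                   dimnames = list(genes, names(datasets)))
  for (tag in names(datasets)) {
    z <- datasets[[tag]]$values
    refs <- intersect(cga_references, rownames(z))
    if (!length(refs)) {
      warning("no reference targets in dataset '", tag, "'; it scores 0")
      next
    }
    ref_max <- apply(z[refs, , drop = FALSE], 2L, max, na.rm = TRUE)
    w <- .NSCORE_WEIGHTS[[tag]]
    for (g in genes) {
      if (!(g %in% rownames(z))) next
      if (all(z[g, ] < ref_max, na.rm = TRUE)) scores[g, tag] <- w
    }
  }
  out <- data.frame(gene = genes, scores, n_score = rowSums(scores),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1L + seq_along(datasets)] <- paste0("t_", names(datasets))
  out
}

#' High-tumor-expression filter for TCR/PC candidates
#'
#' Primary rule: expression at or above the pool's 25th percentile in both
#' the single-cell data and the bulk cohort, or in both the single-cell data
#' and the cell lines (genes missing from both externals pass on single-cell
#' alone).  Relaxed rule: `N(g) >= 3.5` and single-cell expression at or
#' above the 25th percentile regardless of the external datasets.
#'
#' @param genes candidate genes.
#' @param sc_expr,bulk_expr,line_expr named per-gene expression vectors.
#' @param n_scores named `N(g)` values for the relaxed rule.
#' @param pct pool percentile, default 0.25.
#' @param n_cutoff relaxed-rule `N(g)` cutoff, default 3.5.
#' @return data.frame `gene`, `primary`, `relaxed`, `high_expression`.
#' @export
tcr_high_expression_filter <- function(genes, sc_expr, bulk_expr, line_expr,
                                       n_scores, pct = 0.25, n_cutoff = 3.5) {
  sc <- sc_expr[genes]; bulk <- bulk_expr[genes]; line <- line_expr[genes]
  q_sc <- scanact_quantile(sc, pct)
  q_bulk <- if (all(is.na(bulk))) NA_real_ else scanact_quantile(bulk, pct)
  q_line <- if (all(is.na(line))) NA_real_ else scanact_quantile(line, pct)
  sc_hi <- !is.na(sc) & sc >= q_sc
  bulk_hi <- !is.na(bulk) & !is.na(q_bulk) & bulk >= q_bulk
  line_hi <- !is.na(line) & !is.na(q_line) & line >= q_line
  primary <- sc_hi & (bulk_hi | line_hi | (is.na(bulk) & is.na(line)))
  relaxed <- sc_hi & !is.na(n_scores[genes]) & n_scores[genes] >= n_cutoff
  data.frame(gene = genes, primary = unname(primary), relaxed = unname(relaxed),
             high_expression = unname(primary | relaxed),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate candidate peptides from protein sequences
#'
#' All distinct 9-mer and 10-mer windows (stride 1) of each protein;
#' windows containing a non-standard residue are skipped with a warning,
#' and sequences shorter than the window yield none.
#'
#' @param fasta path to a protein FASTA file, or a named character vector of
#'   sequences, or a `Biostrings::AAStringSet`.
#' @param lengths peptide lengths, default `c(9, 10)`.
#' @return data.frame `antigen`, `peptide`, `length`, `positions`
#'   (comma-separated 1-based start positions of the window).
#' @export
enumerate_peptides <- function(fasta, lengths = c(9L, 10L)) {
  seqs <- if (inherits(fasta, "AAStringSet")) {
    stats::setNames(as.character(fasta), names(fasta))
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else {
    fasta
  }
  out <- list()
  skipped <- 0L
  for (ag in names(seqs)) {
    s <- toupper(seqs[[ag]])
    chars <- strsplit(s, "")[[1L]]
    for (L in lengths) {
      n <- nchar(s)
      if (n < L) { warning("sequence '", ag, "' shorter than ", L, "; no ", L, "-mers"); next }
      starts <- seq_len(n - L + 1L)
      peps <- substring(s, starts, starts + L - 1L)
      ok <- vapply(starts, function(i) all(chars[i:(i + L - 1L)] %in% .AA20), logical(1L))
      skipped <- skipped + sum(!ok)
      if (!any(ok)) next
      df <- data.frame(antigen = ag, peptide = peps[ok], length = L,
                       position = starts[ok], stringsAsFactors = FALSE)
      agg <- stats::aggregate(position ~ antigen + peptide + length, df,
                              function(p) paste(p, collapse = ","))
      names(agg)[names(agg) == "position"] <- "positions"
      out[[length(out) + 1L]] <- agg
    }
  }
  if (skipped) warning(skipped, " windows with non-standard residues skipped")
  if (!length(out))
    return(data.frame(antigen = character(), peptide = character(),
                      length = integer(), positions = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-size-weighted world HLA allele frequency
#'
#' Frequencies are averaged (unweighted) across population studies within a
#' country, then averaged across countries weighted by country population
#' size.  Countries with missing population size are dropped with a warning.
#'
#' @param table data.frame with columns `allele`, `population`, `frequency`,
#'   `country`, `population_size`.
#' @return named numeric vector: allele -> world frequency.
#' @export
world_allele_frequency <- function(table) {
  need <- c("allele", "population", "frequency", "country", "population_size")
  missing <- setdiff(need, names(table))
  if (length(missing)) stop("allele frequency table lacks: ", paste(missing, collapse = ", "))
  if (any(table$frequency < 0 | table$frequency > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  drop <- is.na(table$population_size) | table$population_size <= 0
  if (any(drop)) {
    warning("dropping ", length(unique(table$country[drop])),
            " countries with missing population size")
    table <- table[!drop, , drop = FALSE]
  }
  out <- c()
  for (a in unique(table$allele)) {
    ta <- table[table$allele == a, , drop = FALSE]
    by_country <- vapply(split(ta, ta$country), function(tc) {
      c(f = mean(tc$frequency), w = tc$population_size[1L])
    }, numeric(2L))
    out[a] <- sum(by_country["f", ] * by_country["w", ]) / sum(by_country["w", ])
  }
  out
}

#' Peptide-MHC targetability score
#'
#' `TS = (S_presentation + S_immunogenicity) * (1 + F_allele)` for each
#' peptide-HLA pair.
#'
#' @param s_hlathena presentation score in \[0, 1\].
#' @param s_deepimmuno immunogenicity score in \[0, 1\].
#' @param f_allele world allele frequency in \[0, 1\].
#' @return numeric score (vectorized).
#' @export
ts_tcr_pc <- function(s_hlathena, s_deepimmuno, f_allele) {
  (s_hlathena + s_deepimmuno) * (1 + f_allele)
}

#' Assemble scored pMHC records for a set of antigens
#'
#' Joins enumerated peptides with predictor score tables and allele
#' frequencies; records missing either predictor score are excluded with a
#' warning.
#'
#' @param peptides data.frame from [enumerate_peptides()].
#' @param hlathena data.frame `peptide`, `allele`, `score`.
#' @param deepimmuno data.frame `peptide`, `allele`, `score`.
#' @param allele_freq named allele -> frequency vector
#'   (from [world_allele_frequency()]).
#' @return data.frame `antigen`, `peptide`, `length`, `allele`,
#'   `s_hlathena`, `s_deepimmuno`, `f_allele`, `ts`.
#' @export
score_pmhc_records <- function(peptides, hlathena, deepimmuno, allele_freq) {
  key <- function(df) paste(df$peptide, df$allele, sep = "|")
  alleles <- names(allele_freq)
  grid <- merge(peptides, data.frame(allele = alleles, stringsAsFactors = FALSE))
  h_idx <- match(key(grid), key(hlathena))
  d_idx <- match(key(grid), key(deepimmuno))
  keep <- !is.na(h_idx) & !is.na(d_idx)
  if (any(!keep))
    warning(sum(!keep), " pMHC records lack a predictor score; excluded")
  grid <- grid[keep, , drop = FALSE]
  grid$s_hlathena <- hlathena$score[h_idx[keep]]
  grid$s_deepimmuno <- deepimmuno$score[d_idx[keep]]
  grid$f_allele <- unname(allele_freq[grid$allele])
  grid$ts <- ts_tcr_pc(grid$s_hlathena, grid$s_deepimmuno, grid$f_allele)
  rownames(grid) <- NULL
  grid
}

#' Select candidate pMHCs for cross-reactivity assessment
#'
#' Per antigen: rank peptides by cumulative HLA allele frequency (the sum of
#' `f_allele` over the pMHCs each peptide forms) and keep pMHCs from the top
#' `k_peptides` peptides (ties at the boundary kept), with targetability at
#' or above the `ts_pct` percentile (per antigen by default, or over the
#' whole pool) and presentation score at or above `hlathena_min`.
#'
#' @param records data.frame from [score_pmhc_records()].
#' @param k_peptides default 5.
#' @param ts_pct percentile in \[0, 1\], default 0.99.
#' @param hlathena_min default 0.85.
#' @param ts_scope `"antigen"` (default) or `"global"` percentile pool.
#' @return `records` plus `cumfreq`, `cumfreq_rank`, `selected`.
#' @export
select_candidate_pmhcs <- function(records, k_peptides = 5, ts_pct = 0.99,
                                   hlathena_min = 0.85,
                                   ts_scope = c("antigen", "global")) {
  ts_scope <- match.arg(ts_scope)
  records$cumfreq <- NA_real_
  records$cumfreq_rank <- NA_integer_
  records$selected <- FALSE
  if (ts_scope == "global") global_cut <- scanact_quantile(records$ts, ts_pct)
  for (ag in unique(records$antigen)) {
    rows <- which(records$antigen == ag)
    sub <- records[rows, , drop = FALSE]
    cf <- tapply(sub$f_allele, sub$peptide, sum)
    records$cumfreq[rows] <- cf[sub$peptide]
    rnk <- rank(-cf, ties.method = "min")
    records$cumfreq_rank[rows] <- rnk[sub$peptide]
    ts_cut <- if (ts_scope == "antigen") scanact_quantile(sub$ts, ts_pct) else global_cut
    records$selected[rows] <- records$cumfreq_rank[rows] <= k_peptides &
      sub$ts >= ts_cut & sub$s_hlathena >= hlathena_min
  }
  records
}
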