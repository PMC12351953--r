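# PS-TRACT: peptide similarity and TCR reactivity analysis for cellular
# therapies.  Ligandome indexing, entropy-weighted peptide similarity
# (S_sim), tissue-specific cross-reactivity scoring (S_CR) and benchmarking
# against a reference pMHC (S_CR Diff).

.normalize_allele <- function(allele) sub("^HLA-", "", allele)
.is_four_digit <- function(allele) grepl("^[A-Z]+[0-9]*\\*[0-9]{2,3}:[0-9]{2,3}$", allele)

#' Load a residue substitution model
#'
#' Reads a 20x20 residue similarity matrix (PMBEC-style: higher values mean
#' substitutions better tolerated by peptide-HLA binding) and a 20x9 residue
#' embedding (AAindex-style principal components of physicochemical
#' properties), and derives the two distances used by [s_sim_pool()]:
#' `dist_sub = max(sim) - sim` and the Euclidean embedding distance.  The
#' package ships deterministic synthetic stand-ins for both tables
#' (`pmbec_synthetic.tsv`, `aaindex_pc9_synthetic.tsv`); supply the published
#' matrices through the same arguments to reproduce literature values.
#'
#' @param pmbec path to a TSV holding the 20x20 similarity matrix (residue
#'   rownames/colnames).
#' @param aaindex path to a TSV holding the 20x9 residue embedding.
#' @return list of class `ResidueSubstitutionModel` with `sim`, `dist_sub`,
#'   `embedding`, `dist_embed`.
#' @export
load_substitution_model <- function(
    pmbec = system.file("extdata", "pmbec_synthetic.tsv", package = "scanact"),
    aaindex = system.file("extdata", "aaindex_pc9_synthetic.tsv", package = "scanact")) {
  sim <- as.matrix(utils::read.delim(pmbec, row.names = 1L, check.names = FALSE))
  emb <- as.matrix(utils::read.delim(aaindex, row.names = 1L, check.names = FALSE))
  if (!identical(sort(rownames(sim)), sort(colnames(sim))))
    stop("substitution matrix must be square with matching residue labels")
  if (max(abs(sim - t(sim[colnames(sim), rownames(sim)]))) > 1e-8)
    stop("substitution matrix must be symmetric")
  dist_embed <- as.matrix(stats::dist(emb))
  structure(list(sim = sim, dist_sub = max(sim) - sim,
                 embedding = emb, dist_embed = dist_embed),
            class = "ResidueSubstitutionModel")
}

#' Positional residue entropy of a peptide set
#'
#' Shannon entropy of the residue distribution at each position, normalized
#' by `log(20)` so 0 means no variability and 1 maximal variability over the
#' 20 standard residues.  Fewer than two peptides give an all-zero vector
#' with a warning.
#'
#' @param peptides character vector of equal-length peptides.
#' @return numeric vector of per-position entropies in \[0, 1\].
#' @export
residue_entropy <- function(peptides) {
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must share one length")
  if (length(peptides) < 2L) {
    warning("fewer than 2 peptides; entropy set to 0 at every position")
    return(rep(0, L))
  }
  m <- do.call(rbind, strsplit(peptides, ""))
  vapply(seq_len(L), function(i) {
    p <- table(m[, i]) / nrow(m)
    -sum(p * log(p)) / log(20)
  }, numeric(1L))
}

#' Build the unified normal ligandome index
#'
#' Filters and merges observed (mass-spectrometry) and predicted peptide-MHC
#' tables into one deduplicated index and computes per-(allele, length)
#' positional entropy vectors.  Rules: only 9/10-mers; only four-digit HLA
#' allele names (others dropped with a warning); predicted records require
#' affinity percentile below `affinity_max`; records with presentation score
#' at or below `presentation_min` are removed unless observed.
#'
#' @param observed data.frame `peptide allele parent presentation_score
#'   affinity_percentile` (scores may be NA for observed records).
#' @param predicted data.frame with the same columns.
#' @param presentation_min default 0.5.
#' @param affinity_max default 2.0.
#' @return list of class `LigandomeIndex`: `records` (with `observed` flag
#'   and `length`) and `entropy` (named list keyed `"allele|length"`).
#' @export
build_ligandome_index <- function(observed, predicted,
                                  presentation_min = 0.5, affinity_max = 2.0) {
  prep <- function(df, obs) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(peptide = character(), allele = character(),
                        parent = character(), presentation_score = numeric(),
                        observed = logical(), stringsAsFactors = FALSE))
    df$allele <- .normalize_allele(df$allele)
    ok_allele <- .is_four_digit(df$allele)
    if (any(!ok_allele))
      warning(sum(!ok_allele), " records with non-four-digit allele names dropped")
    df <- df[ok_allele & nchar(df$peptide) %in% c(9L, 10L), , drop = FALSE]
    if (!obs) df <- df[!is.na(df$affinity_percentile) &
                         df$affinity_percentile < affinity_max, , drop = FALSE]
    data.frame(peptide = df$peptide, allele = df$allele, parent = df$parent,
               presentation_score = df$presentation_score,
               observed = obs, stringsAsFactors = FALSE)
  }
  all_rec <- rbind(prep(observed, TRUE), prep(predicted, FALSE))
  if (nrow(all_rec) == 0L) stop("no ligandome records after filtering")
  key <- paste(all_rec$peptide, all_rec$allele, all_rec$parent, sep = "|")
  obs_by_key <- tapply(all_rec$observed, key, any)
  pres_by_key <- tapply(all_rec$presentation_score, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) max(x) else NA_real_
  })
  first <- !duplicated(key)
  rec <- all_rec[first, , drop = FALSE]
  rec$observed <- unname(obs_by_key[key[first]])
  rec$presentation_score <- unname(pres_by_key[key[first]])
  keep <- rec$observed | (!is.na(rec$presentation_score) &
                            rec$presentation_score > presentation_min)
  rec <- rec[keep, , drop = FALSE]
  rec$length <- nchar(rec$peptide)
  rownames(rec) <- NULL
  entropy <- list()
  for (al in unique(rec$allele)) for (L in unique(rec$length[rec$allele == al])) {
    peps <- unique(rec$peptide[rec$allele == al & rec$length == L])
    entropy[[paste(al, L, sep = "|")]] <-
      if (length(peps) >= 2L) residue_entropy(peps) else rep(0, L)
  }
  structure(list(records = rec, entropy = entropy), class = "LigandomeIndex")
}

#' @exportS3Method base::print
print.LigandomeIndex <- function(x, ...) {
  cat(sprintf("LigandomeIndex: %d pMHC records (%d observed), %d (allele, length) strata\n",
              nrow(x$records), sum(x$records$observed), length(x$entropy)))
  invisible(x)
}

# One similarity component: mean over positions of
#   1/(1 + dist(p_t[i], p_n[i])) * (1 + H[i])
.sim_component <- function(pt, pn, dist_m, H) {
  a <- strsplit(pt, "")[[1L]]; b <- strsplit(pn, "")[[1L]]
  mean(1 / (1 + dist_m[cbind(a, b)]) * (1 + H))
}

#' Entropy-weighted peptide similarity against a comparison pool
#'
#' For a tumoral peptide and every normal peptide in the pool (same allele
#' and length), computes a binding-energy-covariance component and a
#' physicochemical-embedding component, each the positional mean of
#' `1/(1 + dist) * (1 + H_i)` with `H_i` the allele's positional entropy.
#' Each component is min-max scaled within the pool and the two are summed,
#' giving `S_sim` in \[0, 2\].  Values above 1.15 flag likely TCR
#' cross-reactivity.
#'
#' @param tumoral tumoral peptide.
#' @param pool character vector of normal peptides (the comparison pool that
#'   defines the min-max scaling).
#' @param model a [load_substitution_model()].
#' @param entropy positional entropy vector for the (allele, length)
#'   stratum.
#' @return named numeric vector of `S_sim` over the pool.
#' @export
s_sim_pool <- function(tumoral, pool, model, entropy) {
  if (!length(pool)) stop("empty comparison pool for S_sim")
  L <- nchar(tumoral)
  pool <- pool[nchar(pool) == L]
  if (!length(pool)) stop("no pool peptides of the tumoral peptide's length")
  stopifnot(length(entropy) == L)
  sp <- vapply(pool, .sim_component, numeric(1L), pt = tumoral,
               dist_m = model$dist_sub, H = entropy)
  sa <- vapply(pool, .sim_component, numeric(1L), pt = tumoral,
               dist_m = model$dist_embed, H = entropy)
  scale01 <- function(x) {
    if (max(x) == min(x)) return(rep(0, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  stats::setNames(scale01(sp) + scale01(sa), pool)
}

#' Tissue-specific cross-reactivity score of one normal pMHC
#'
#' `S_CR = (P + 0.5) * E * 1.25^observed` per tissue, where `P` is the
#' presentation score of the normal pMHC and `E` the median-centered,
#' z-scored consensus expression of its parent antigen in that tissue.
#' Below-median tissues give negative values, read as low risk.
#'
#' @param presentation_score presentation score of the normal pMHC.
#' @param parent_expression named numeric vector: z-scored expression of the
#'   parent antigen per tissue.
#' @param observed logical: was the pMHC observed by mass spectrometry.
#' @param observed_bonus multiplier for observed records, default 1.25.
#' @return named numeric vector of per-tissue scores.
#' @export
s_cr <- function(presentation_score, parent_expression, observed,
                 observed_bonus = 1.25) {
  p <- if (is.na(presentation_score)) 0 else presentation_score
  (p + 0.5) * parent_expression * if (observed) observed_bonus else 1
}

#' Cross-reactivity profile of a tumoral pMHC
#'
#' Finds the normal pMHCs of the same allele and length, keeps those with
#' `S_sim` above the threshold, scores each with [s_cr()] using the parent
#' antigen's consensus expression, and takes the per-tissue maximum.
#' Tissues with no cross-reactive pMHC (or a fully empty set) get the floor
#' value (default 0) with `no_crossreactive` flagged.
#'
#' @param tumoral_peptide peptide sequence.
#' @param allele HLA allele (four-digit).
#' @param index a [build_ligandome_index()].
#' @param panel z-scored consensus [expression_panel()] (genes x tissues).
#' @param model a [load_substitution_model()].
#' @param s_sim_threshold default 1.15.
#' @param floor per-tissue value when no cross-reactive pMHC exists.
#' @return list of class `CrossReactivityProfile`: `profile` (named tissue
#'   vector), `no_crossreactive` flag, `crossreactive` (data.frame of the
#'   contributing normal pMHCs with their `s_sim`).
#' @export
cr_profile <- function(tumoral_peptide, allele, index, panel, model,
                       s_sim_threshold = 1.15, floor = 0) {
  allele <- .normalize_allele(allele)
  L <- nchar(tumoral_peptide)
  tissues <- colnames(panel$values)
  rec <- index$records[index$records$allele == allele &
                         index$records$length == L, , drop = FALSE]
  empty <- function() {
    structure(list(profile = stats::setNames(rep(floor, length(tissues)), tissues),
                   no_crossreactive = TRUE,
                   crossreactive = rec[0, , drop = FALSE]),
              class = "CrossReactivityProfile")
  }
  if (nrow(rec) == 0L) return(empty())
  H <- index$entropy[[paste(allele, L, sep = "|")]]
  sims_by_pep <- s_sim_pool(tumoral_peptide, unique(rec$peptide), model, H)
  rec$s_sim <- unname(sims_by_pep[rec$peptide])
  rec <- rec[rec$s_sim > s_sim_threshold, , drop = FALSE]
  if (nrow(rec) == 0L) return(empty())
  scores <- matrix(NA_real_, nrow = nrow(rec), ncol = length(tissues),
                   dimnames = list(NULL, tissues))
  keep <- logical(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    parent <- rec$parent[k]
    if (!(parent %in% rownames(panel$values))) {
      warning("parent antigen '", parent, "' absent from consensus panel; record skipped")
      next
    }
    keep[k] <- TRUE
    scores[k, ] <- s_cr(rec$presentation_score[k], panel$values[parent, ],
                        rec$observed[k])
  }
  if (!any(keep)) return(empty())
  profile <- apply(scores[keep, , drop = FALSE], 2L, max)
  structure(list(profile = profile, no_crossreactive = FALSE,
                 crossreactive = rec[keep, , drop = FALSE]),
            class = "CrossReactivityProfile")
}

#' Penalized profile difference against the reference pMHC
#'
#' Mean over tissues of the reference-standardized difference
#' `(S_CR_i - S_CR_ref) / sigma_j`, multiplied by `alpha` (default 2) where
#' the candidate exceeds the reference; `sigma_j` is the per-tissue SD of
#' the scores over all profiles considered (candidates plus reference).
#' Zero-SD tissues are excluded from the mean with a warning.  A value at
#' or below 0 marks acceptable cross-reactivity risk.
#'
#' @param profile named tissue vector for the candidate pMHC.
#' @param reference_profile named tissue vector for the reference pMHC.
#' @param all_profiles matrix (profiles x tissues) used for `sigma_j`;
#'   should include candidates and the reference.
#' @param alpha penalty on excursions above the reference, default 2.
#' @return list `s_cr_diff` (scalar), `acceptable` (logical),
#'   `n_tissues_used`.
#' @export
s_cr_diff <- function(profile, reference_profile, all_profiles, alpha = 2) {
  tissues <- names(profile)
  if (!all(tissues %in% names(reference_profile)))
    stop("reference profile is missing tissues present in the candidate profile")
  reference_profile <- reference_profile[tissues]
  sigma <- apply(all_profiles[, tissues, drop = FALSE], 2L, stats::sd)
  use <- is.finite(sigma) & sigma > 0
  if (any(!use)) warning(sum(!use), " zero-variance tissues excluded from S_CR Diff")
  if (!any(use)) stop("no tissues with positive score variance")
  delta <- (profile - reference_profile)[use] / sigma[use]
  val <- mean(ifelse(delta > 0, delta * alpha, delta))
  list(s_cr_diff = val, acceptable = val <= 0, n_tissues_used = sum(use))
}
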