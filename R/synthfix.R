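# Synthetic-fixture generation.  Produces cohorts, normal-tissue panels,
# differential-expression tables, ligandomes and evidence tables with the
# statistical structure the scoring stages assume, so the full pipeline runs
# end to end with no downloads.  All randomness flows from the single SimSpec
# seed; repeated calls with the same SimSpec are bit-identical.

#' Simulation specification
#'
#' Defaults define the study conditions the generators emulate: a tumor
#' sample dominated by malignant cells (as in sarcoma biopsies), a planted
#' transcriptional tumor signature, planted copy-number blocks, gene pairs
#' engineered to be tumor-co-expressed and normal-mutually-exclusive ("AND"
#' plants) or normal-shadowed ("AND-NOT" plants), and a peptide ligandome
#' with anchor-constrained positions.
#'
#' @param seed mandatory integer seed; every generator derives its RNG
#'   stream from it.
#' @param n_filler number of background genes.
#' @param n_signature tumor-signature genes; `signature_log2fc` their
#'   planted effect (log2 scale).
#' @param n_cells named vector of cells per class.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param n_and_pairs planted "AND" pairs (pool has `2 * n_and_pairs`
#'   genes).
#' @param coexpr_strength latent-factor scale for tumor co-expression.
#' @param n_activators,n_inhibitors "AND-NOT" pool sizes;
#'   `n_andnot_planted` planted pairs.
#' @param cna_frac fraction of tumor cells carrying each planted CNA block;
#'   `cna_block_size` genes per block; `state_noise` per-entry probability
#'   of a spurious one-step state in any cell.
#' @param n_tissues_hpa,n_groups_hpa,... normal-panel dimensions.
#' @param n_ligandome peptides per (allele, 9-mer) stratum.
#' @return list of class `SimSpec`.
#' @export
sim_spec <- function(seed,
                     n_filler = 120L, n_signature = 30L, signature_log2fc = 2,
                     n_cells = c(tumor = 400L, endothelial = 25L, myeloid = 40L,
                                 lymphoid = 30L, CAF = 25L),
                     nb_size = 2,
                     n_and_pairs = 10L, coexpr_strength = 0.8,
                     n_activators = 10L, n_inhibitors = 20L, n_andnot_planted = 2L,
                     n_down_extra = 5L,
                     cna_frac = 0.95, cna_block_size = 40L, state_noise = 0.02,
                     n_references = 8L, n_cga = 4L,
                     n_tissues_hpa = 24L, n_groups_hpa = 12L,
                     n_samples_gtex = 30L, n_groups_gtex = 10L,
                     n_celltypes_sc = 30L, n_tissues_prot = 24L,
                     n_tissues_hpm = 16L, n_groups_ihc = 12L,
                     n_ligandome = 60L, n_consensus_tissues = 20L) {
  if (missing(seed)) stop("seed is mandatory")
  spec <- as.list(environment())
  stopifnot(all(unlist(spec[vapply(spec, is.numeric, logical(1L))]) >= 0))
  structure(spec, class = "SimSpec")
}

# Central gene naming shared by cohort and panel generators.
.sim_genes <- function(spec) {
  list(
    filler = sprintf("F%03d", seq_len(spec$n_filler)),
    signature = sprintf("S%02d", seq_len(spec$n_signature)),
    and_pool = sprintf("P%02d", seq_len(2L * spec$n_and_pairs)),
    activators = sprintf("A%02d", seq_len(spec$n_activators)),
    inhibitors = sprintf("I%02d", seq_len(spec$n_inhibitors)),
    down_extra = sprintf("D%02d", seq_len(spec$n_down_extra)),
    references = sprintf("REF%02d", seq_len(spec$n_references)),
    cga = sprintf("CGA%02d", seq_len(spec$n_cga)))
}

#' Planted "AND" pairs of a spec
#'
#' @param spec a [sim_spec()].
#' @return data.frame `gene_i`, `gene_j` of the planted pairs.
#' @export
planted_and_pairs <- function(spec) {
  g <- .sim_genes(spec)$and_pool
  data.frame(gene_i = g[seq(1L, length(g), 2L)],
             gene_j = g[seq(2L, length(g), 2L)], stringsAsFactors = FALSE)
}

#' Planted "AND-NOT" pairs of a spec
#'
#' @param spec a [sim_spec()].
#' @return data.frame `activator`, `inhibitor`.
#' @export
planted_andnot_pairs <- function(spec) {
  g <- .sim_genes(spec)
  k <- spec$n_andnot_planted
  data.frame(activator = g$activators[seq_len(k)],
             inhibitor = g$inhibitors[seq_len(k)], stringsAsFactors = FALSE)
}

#' Generate a tumor-sample cohort
#'
#' Negative-binomial counts for one sample with truth labels: the tumor
#' signature and "AND"-pool genes are upregulated in tumor cells (the pool
#' genes pairwise co-expressed through per-pair latent factors), activator
#' genes are tumor-high, inhibitor and extra down genes tumor-low, and
#' PTPRC is expressed only in immune classes.  The CNA state matrix is
#' neutral everywhere except planted gain/loss blocks in tumor cells and
#' sparse one-step noise.  Bulk tumor and normal-cell reference panels for
#' the similarity score are derived from the same generative means.
#'
#' @param spec a [sim_spec()].
#' @return list with `cells` ([cell_table()]), `states` (genes x cells),
#'   `truth` (per-cell class), `bulk_reference`, `normal_reference`
#'   ([expression_panel()]s).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  g <- .sim_genes(spec)
  genes <- c(g$filler, g$signature, g$and_pool, g$activators, g$inhibitors,
             g$down_extra, "PTPRC")
  classes <- rep(names(spec$n_cells), spec$n_cells)
  n_cells <- length(classes)
  cell_ids <- sprintf("C%04d", seq_len(n_cells))

  base_mu <- stats::setNames(stats::rlnorm(length(genes), log(5), 1), genes)
  base_mu[g$and_pool] <- 20
  base_mu[g$activators] <- 25
  base_mu[c(g$inhibitors, g$down_extra)] <- 20
  base_mu["PTPRC"] <- 30

  mu <- matrix(base_mu, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cell_ids))
  is_tumor <- classes == "tumor"
  # planted tumor signature and tumor-restricted pools
  mu[g$signature, is_tumor] <- mu[g$signature, is_tumor] * 2^spec$signature_log2fc
  mu[g$signature, !is_tumor] <- base_mu[g$signature]
  mu[g$and_pool, !is_tumor] <- 2
  mu[g$activators, !is_tumor] <- 2
  # inhibitors/extra down genes: expressed in normal classes, silenced in tumor
  mu[c(g$inhibitors, g$down_extra), is_tumor] <- 0.5
  # PTPRC only in immune classes
  mu["PTPRC", !(classes %in% c("myeloid", "lymphoid"))] <- 0
  # per-pair latent factors drive tumor co-expression of the AND pool
  pairs <- planted_and_pairs(spec)
  for (k in seq_len(nrow(pairs))) {
    u <- stats::rnorm(sum(is_tumor))
    fac <- exp(spec$coexpr_strength * u - spec$coexpr_strength^2 / 2)
    for (gn in c(pairs$gene_i[k], pairs$gene_j[k]))
      mu[gn, is_tumor] <- mu[gn, is_tumor] * fac
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = spec$nb_size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  counts["PTPRC", mu["PTPRC", ] == 0] <- 0L

  # CNA states: neutral + sparse noise + planted tumor blocks
  states <- matrix(3L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, cell_ids))
  noise_idx <- which(stats::runif(length(states)) < spec$state_noise)
  states[noise_idx] <- sample(c(2L, 4L), length(noise_idx), replace = TRUE)
  bs <- spec$cna_block_size
  block_gain <- g$filler[seq_len(bs)]
  block_loss <- g$filler[bs + seq_len(bs)]
  tumor_idx <- which(is_tumor)
  carriers <- tumor_idx[stats::runif(length(tumor_idx)) < spec$cna_frac]
  states[block_gain, carriers] <- 5L
  states[block_loss, carriers] <- 1L

  cells <- cell_table(counts, sample_id = sprintf("SIM%04d", spec$seed),
                      labels = classes)

  # similarity-score references from the generative means
  tumor_mean <- rowMeans(mu[, is_tumor, drop = FALSE])
  normal_mean <- rowMeans(mu[, !is_tumor, drop = FALSE])
  mk_panel <- function(center, prefix) {
    m <- vapply(seq_len(5L), function(i) center * stats::rlnorm(length(center), 0, 0.3),
                numeric(length(center)))
    dimnames(m) <- list(genes, paste0(prefix, seq_len(5L)))
    expression_panel(m, unit = "TPM")
  }
  list(cells = cells, states = states,
       truth = stats::setNames(classes, cell_ids),
       bulk_reference = mk_panel(tumor_mean, "BULK"),
       normal_reference = mk_panel(normal_mean, "NORM"))
}

# Raw log2p1-scale tissue profile builders -----------------------------------

# planted two-level profile: `hi` on the index set, `lo` elsewhere, plus noise
.profile2 <- function(n, hi_idx, hi = 6, lo = 0.5, noise = 0.05) {
  v <- rep(lo, n); v[hi_idx] <- hi
  v + stats::rnorm(n, 0, noise)
}

#' Generate the normal-tissue and normal-cell panels
#'
#' Builds the six quantitative panels (two bulk RNA, one single-cell RNA,
#' three protein) and the three categorical panels the toxicity filters
#' consume.  Planted structure: "AND"-pool gene pairs get mutually
#' exclusive profiles (disjoint tissue supports, pair-specific random
#' splits) in every panel; planted "AND-NOT" activator/inhibitor pairs get
#' nested supports (inhibitor high wherever the activator is high, and
#' beyond); reference targets get controlled expression envelopes covering
#' every tissue so filter cutoffs are defined; candidate genes are
#' near-silent in normal tissue; inhibitors and extra down genes are
#' broadly expressed.
#'
#' @param spec a [sim_spec()].
#' @return list with `zpanels` (tags `hpa_rna, gtex_rna, hpa_sc, gtex_prot,
#'   hpm, hpa_ihc_num`), `cat_panels` (tags `hpa_rna, gtex_rna, hpa_ihc`),
#'   `raw` (log2p1 panels), `surfaceome`, `references`, `cga_references`,
#'   `genes` (the naming list).
#' @export
gen_normal_panels <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed + 1000L)
  g <- .sim_genes(spec)
  genes <- c(g$filler, g$signature, g$and_pool, g$activators, g$inhibitors,
             g$down_extra, g$references, g$cga, "PTPRC")
  and_pairs <- planted_and_pairs(spec)
  an_pairs <- planted_andnot_pairs(spec)

  build_raw <- function(n_col, col_prefix, or_style) {
    m <- matrix(NA_real_, nrow = length(genes), ncol = n_col,
                dimnames = list(genes, sprintf("%s%02d", col_prefix, seq_len(n_col))))
    # background: moderate variable expression
    m[g$filler, ] <- matrix(pmax(stats::rnorm(length(g$filler) * n_col, 3, 1), 0),
                            nrow = length(g$filler))
    # candidates near-silent in normal tissue
    quiet <- c(g$signature, g$activators)
    m[quiet, ] <- matrix(0.5 + stats::rnorm(length(quiet) * n_col, 0, 0.15),
                         nrow = length(quiet))
    # broadly expressed genes (inhibitor pool source, down genes, PTPRC)
    broad <- c(g$inhibitors, g$down_extra, "PTPRC")
    m[broad, ] <- matrix(5 + stats::rnorm(length(broad) * n_col, 0, 0.5),
                         nrow = length(broad))
    # AND plants: disjoint supports, pair-specific splits.  Correlation
    # panels use complementary halves (Pearson ~ -1); odds-ratio panels use
    # two disjoint 30% subsets (z > 1 only inside the support).
    for (k in seq_len(nrow(and_pairs))) {
      if (or_style) {
        q <- max(1L, round(0.3 * n_col))
        idx <- sample(n_col, 2L * q)
        hi_i <- idx[seq_len(q)]; hi_j <- idx[q + seq_len(q)]
      } else {
        half <- sample(n_col, floor(n_col / 2))
        hi_i <- half; hi_j <- setdiff(seq_len(n_col), half)
      }
      m[and_pairs$gene_i[k], ] <- .profile2(n_col, hi_i)
      m[and_pairs$gene_j[k], ] <- .profile2(n_col, hi_j)
    }
    # AND-NOT plants: shared 30% support, inhibitor at a higher level, so
    # the pair is strongly co-expressed across normal tissue and the
    # inhibitor is high (z > 1) wherever the activator is
    for (k in seq_len(nrow(an_pairs))) {
      s_act <- sample(n_col, max(1L, round(0.3 * n_col)))
      m[an_pairs$activator[k], ] <- .profile2(n_col, s_act, hi = 4)
      m[an_pairs$inhibitor[k], ] <- .profile2(n_col, s_act, hi = 6)
    }
    # reference envelopes: each reference is high on a block of tissues;
    # blocks tile all columns so each tissue has a high reference, and two
    # broad references add a heavy ceiling everywhere.
    for (r in seq_along(g$references)) {
      width <- max(2L, round(0.3 * n_col))
      start <- ((r - 1L) * width) %% n_col
      idx <- ((start + seq_len(width) - 1L) %% n_col) + 1L
      m[g$references[r], ] <- .profile2(n_col, idx, hi = 6, lo = 1, noise = 0.2)
    }
    m[g$references[1L], ] <- 5 + stats::rnorm(n_col, 0, 1.5)
    m[g$references[2L], ] <- 4 + stats::rnorm(n_col, 0, 2)
    # CGA references: confined to a couple of "immune-privileged" columns
    for (r in seq_along(g$cga))
      m[g$cga[r], ] <- .profile2(n_col, sample(n_col, 2L), hi = 5, lo = 0.2)
    pmax(m, 0)
  }

  grouping <- function(cols, n_groups, prefix) {
    stats::setNames(sprintf("%s%02d", prefix, ((seq_along(cols) - 1L) %% n_groups) + 1L),
                    cols)
  }

  hpa_raw <- build_raw(spec$n_tissues_hpa, "HT", or_style = FALSE)
  hpa_grp <- grouping(colnames(hpa_raw), spec$n_groups_hpa, "HG")
  gtex_raw <- build_raw(spec$n_samples_gtex, "GS", or_style = FALSE)
  gtex_grp <- grouping(colnames(gtex_raw), spec$n_groups_gtex, "GG")
  sc_names <- c("T-cells", "NK-cells", "fibroblasts",
                sprintf("celltype%02d", seq_len(spec$n_celltypes_sc - 3L)))
  sc_raw <- build_raw(spec$n_celltypes_sc, "CT", or_style = FALSE)
  colnames(sc_raw) <- sc_names
  prot_raw <- build_raw(spec$n_tissues_prot, "PT", or_style = FALSE)
  # tissue-proteomics missingness (a few genes beyond the 25% tolerance)
  na_genes <- sample(g$filler, 6L)
  for (gn in na_genes[1:3]) prot_raw[gn, sample(ncol(prot_raw), ceiling(0.4 * ncol(prot_raw)))] <- NA
  for (gn in na_genes[4:6]) prot_raw[gn, sample(ncol(prot_raw), 2L)] <- NA
  hpm_raw <- build_raw(spec$n_tissues_hpm, "MT", or_style = TRUE)
  ihc_raw <- build_raw(spec$n_groups_ihc, "IG", or_style = TRUE)

  pan <- function(m, unit = "log2p1", grouping = NULL) expression_panel(m, unit, grouping)
  zpanels <- list(
    hpa_rna = median_center_zscore(pan(hpa_raw, grouping = hpa_grp)),
    gtex_rna = median_center_zscore(pan(gtex_raw, grouping = gtex_grp)),
    hpa_sc = median_center_zscore(pan(sc_raw)),
    gtex_prot = median_center_zscore(pan(prot_raw)),
    hpm = median_center_zscore(pan(hpm_raw)),
    hpa_ihc_num = median_center_zscore(pan(ihc_raw)))
  cat_panels <- list(
    hpa_rna = categorize_bulk_expression(pan(hpa_raw, grouping = hpa_grp)),
    gtex_rna = categorize_bulk_expression(pan(gtex_raw, grouping = gtex_grp)),
    hpa_ihc = expression_panel(
      ifelse(ihc_raw >= 4, "M-H", "ND-L"), unit = "categorical"))

  surfaceome <- c(g$signature, g$and_pool, g$activators, g$inhibitors,
                  g$references, utils::head(g$filler, 40L))
  list(zpanels = zpanels, cat_panels = cat_panels,
       raw = list(hpa_rna = pan(hpa_raw, grouping = hpa_grp),
                  gtex_rna = pan(gtex_raw, grouping = gtex_grp),
                  hpa_sc = pan(sc_raw)),
       surfaceome = surfaceome, references = g$references,
       cga_references = g$cga, genes = g)
}

#' Generate differential-expression comparison tables
#'
#' Emulates the output of the upstream DE engines on the cohort truth: each
#' comparison (tumor vs each microenvironment class, and tumor vs two
#' normal-panel pools) reports the pseudocount log2 fold change of the
#' generative CPM means plus noise, with adjusted p-values small for genes
#' whose means truly differ and uniform otherwise.
#'
#' @param spec a [sim_spec()].
#' @param cohort output of [gen_cohort()].
#' @return data.frame with the standard comparison-table columns.
#' @export
gen_deg_tables <- function(spec, cohort) {
  set.seed(spec$seed + 2000L)
  counts <- as.matrix(cohort$cells$counts)
  lab <- cohort$truth
  cpm_m <- cpm(counts)
  tumor_mean <- rowMeans(cpm_m[, lab == "tumor", drop = FALSE])
  out <- list()
  add_cmp <- function(ref_mean, cmp_id, ref_class) {
    lfc <- log2fc_cpm(tumor_mean, ref_mean)
    changed <- abs(lfc) > 1
    padj <- ifelse(changed, stats::runif(length(lfc), 0, 0.2),
                   stats::runif(length(lfc), 0.25, 1))
    out[[length(out) + 1L]] <<- data.frame(
      gene = names(tumor_mean), log2fc = unname(lfc), padj = unname(padj),
      comparison = cmp_id, ref_class = ref_class, stringsAsFactors = FALSE)
  }
  for (cl in setdiff(unique(lab), "tumor"))
    add_cmp(rowMeans(cpm_m[, lab == cl, drop = FALSE]), paste0("TME_", cl), "TME")
  shuffle <- function(x) x * stats::rlnorm(length(x), 0, 0.1)
  normal_pool <- rowMeans(cpm_m[, lab != "tumor", drop = FALSE])
  add_cmp(shuffle(normal_pool), "PANEL_1", "normal-panel")
  add_cmp(shuffle(normal_pool), "PANEL_2", "normal-panel")
  do.call(rbind, out)
}

# Ligandome -------------------------------------------------------------------

.LIG_ALLELES <- c("A*01:01", "A*02:01", "B*07:02", "C*07:01")
# per-allele anchor residues (position 2 and the C-terminus)
.LIG_ANCHORS <- list("A*01:01" = c("T", "Y"), "A*02:01" = c("L", "V"),
                     "B*07:02" = c("P", "L"), "C*07:01" = c("Y", "L"))

.gen_peptide <- function(allele, L) {
  anchors <- .LIG_ANCHORS[[allele]]
  res <- sample(.AA20[1:15], L, replace = TRUE)
  res[2L] <- sample(c(anchors[1L], .AA20[16]), 1L, prob = c(0.9, 0.1))
  res[L] <- sample(c(anchors[2L], .AA20[17]), 1L, prob = c(0.9, 0.1))
  paste(res, collapse = "")
}

#' Generate a synthetic ligandome, predictor tables and consensus panel
#'
#' Normal peptides are drawn per allele from position-specific residue
#' distributions (anchor positions 2 and C-terminal nearly constant, others
#' broad), split into observed and predicted tables with presentation and
#' affinity scores, and assigned parent proteins whose consensus-tissue
#' expression panel is generated alongside.  For each tumoral antigen one
#' peptide receives a planted single-substitution neighbor in the normal
#' ligandome (at a high-entropy position, using the most conservative
#' substitution under the synthetic model), and the reference pMHC gets a
#' planted neighbor whose parent is highly expressed so candidate profiles
#' compare favorably.
#'
#' @param spec a [sim_spec()].
#' @return list with `observed`, `predicted` (ligandome tables),
#'   `consensus_panel` (z-scored), `proteins` (tumoral antigen sequences),
#'   `tumoral` (data.frame `antigen, peptide, allele` of planted tumoral
#'   pMHCs), `reference` (list `peptide, allele`), `hlathena`, `deepimmuno`
#'   (predictor tables), `allele_freq` (population table), `model`.
#' @export
gen_ligandome <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed + 3000L)
  model <- load_substitution_model()

  # tumoral antigens: random protein sequences
  antigens <- sprintf("TA%02d", 1:3)
  proteins <- stats::setNames(vapply(seq_along(antigens), function(i)
    paste(sample(.AA20, 120L, replace = TRUE), collapse = ""), character(1L)),
    antigens)

  # normal ligandome
  parents <- sprintf("N%03d", seq_len(25L))
  recs <- list()
  for (al in .LIG_ALLELES) {
    peps <- unique(vapply(seq_len(spec$n_ligandome), function(i)
      .gen_peptide(al, 9L), character(1L)))
    peps10 <- unique(vapply(seq_len(ceiling(spec$n_ligandome / 3)), function(i)
      .gen_peptide(al, 10L), character(1L)))
    all_p <- c(peps, peps10)
    recs[[al]] <- data.frame(
      peptide = all_p, allele = al,
      parent = sample(parents, length(all_p), replace = TRUE),
      presentation_score = stats::runif(length(all_p), 0.55, 1),
      affinity_percentile = stats::runif(length(all_p), 0, 1.9),
      stringsAsFactors = FALSE)
  }
  lig <- do.call(rbind, recs)
  rownames(lig) <- NULL

  # planted tumoral pMHCs and their near-duplicate normal neighbors
  tumoral <- data.frame(antigen = antigens,
                        peptide = vapply(antigens, function(ag)
                          substr(proteins[[ag]], 11L, 19L), character(1L)),
                        allele = c("A*02:01", "A*02:01", "B*07:02"),
                        stringsAsFactors = FALSE)
  neighbor_of <- function(pep, pos = 5L) {
    res <- strsplit(pep, "")[[1L]]
    d <- model$dist_sub[res[pos], ]
    res[pos] <- names(sort(d[setdiff(names(d), res[pos])]))[1L]
    paste(res, collapse = "")
  }
  ref_pep <- .gen_peptide("A*02:01", 10L)
  reference <- list(peptide = ref_pep, allele = "A*02:01")
  # candidate neighbors: predicted-only, modest presentation, structured
  # moderate-expression parents (one per candidate)
  cand_plant <- data.frame(
    peptide = vapply(tumoral$peptide, neighbor_of, character(1L)),
    allele = tumoral$allele,
    parent = c("NCAND1", "NCAND2", "NCAND3"),
    presentation_score = 0.6,
    affinity_percentile = stats::runif(3L, 0, 1),
    stringsAsFactors = FALSE)
  # reference neighbors: six observed pMHCs (substitutions at different
  # positions) whose parents tile every consensus tissue, so the reference
  # cross-reactivity profile is high everywhere
  ref_plant <- data.frame(
    peptide = vapply(4:9, function(p) neighbor_of(ref_pep, p), character(1L)),
    allele = "A*02:01",
    parent = sprintf("NREF%d", 1:6),
    presentation_score = 0.95,
    affinity_percentile = stats::runif(6L, 0, 1),
    stringsAsFactors = FALSE)
  observed_idx <- stats::runif(nrow(lig)) < 0.3
  observed <- rbind(lig[observed_idx, , drop = FALSE], ref_plant)
  predicted <- rbind(lig[!observed_idx, , drop = FALSE], cand_plant)

  # consensus tissue expression of parent antigens: reference-neighbor
  # parents are strongly expressed in tiled tissue blocks covering every
  # tissue; candidate-neighbor parents have moderate structured profiles
  all_parents <- c(parents, cand_plant$parent, ref_plant$parent)
  n_t <- spec$n_consensus_tissues
  raw <- matrix(pmax(stats::rnorm(length(all_parents) * n_t, 3, 1), 0),
                nrow = length(all_parents),
                dimnames = list(all_parents, sprintf("TIS%02d", seq_len(n_t))))
  for (k in 1:6) {
    width <- ceiling(0.3 * n_t)
    idx <- (((k - 1L) * ceiling(n_t / 6) + seq_len(width) - 1L) %% n_t) + 1L
    raw[sprintf("NREF%d", k), ] <- .profile2(n_t, idx, hi = 7, lo = 1, noise = 0.2)
  }
  for (k in 1:3)
    raw[sprintf("NCAND%d", k), ] <- .profile2(n_t, sample(n_t, ceiling(0.3 * n_t)),
                                              hi = 4, lo = 1, noise = 0.2)
  consensus <- median_center_zscore(expression_panel(raw, unit = "log2p1"))

  # predictor score tables over all tumoral peptides x alleles
  pep_all <- enumerate_peptides(proteins)
  grid <- merge(pep_all["peptide"], data.frame(allele = .LIG_ALLELES))
  grid <- grid[!duplicated(paste(grid$peptide, grid$allele)), ]
  base_h <- stats::runif(nrow(grid), 0, 0.9)
  base_d <- stats::runif(nrow(grid), 0, 0.9)
  planted_key <- paste(tumoral$peptide, tumoral$allele)
  hot <- paste(grid$peptide, grid$allele) %in% planted_key
  base_h[hot] <- stats::runif(sum(hot), 0.9, 1)
  base_d[hot] <- stats::runif(sum(hot), 0.85, 1)
  hlathena <- data.frame(peptide = grid$peptide, allele = grid$allele,
                         score = base_h, stringsAsFactors = FALSE)
  deepimmuno <- data.frame(peptide = grid$peptide, allele = grid$allele,
                           score = base_d, stringsAsFactors = FALSE)

  countries <- data.frame(country = sprintf("CTRY%d", 1:5),
                          population_size = c(3e7, 8e7, 1e8, 5e6, 2e8))
  af <- do.call(rbind, lapply(.LIG_ALLELES, function(al) {
    true_f <- stats::runif(1L, 0.02, 0.2)
    do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
      n_pop <- sample(1:3, 1L)
      data.frame(allele = al,
                 population = sprintf("%s_pop%d", countries$country[i], seq_len(n_pop)),
                 frequency = pmin(pmax(true_f + stats::rnorm(n_pop, 0, 0.01), 0), 1),
                 country = countries$country[i],
                 population_size = countries$population_size[i],
                 stringsAsFactors = FALSE)
    }))
  }))

  list(observed = observed, predicted = predicted, consensus_panel = consensus,
       proteins = proteins, tumoral = tumoral, reference = reference,
       hlathena = hlathena, deepimmuno = deepimmuno, allele_freq = af,
       model = model)
}

#' Generate a multi-omic evidence table
#'
#' Random draws from the closed evidence vocabularies for a gene set,
#' emulating curated essentiality, fusion, SNV/indel, copy-number and
#' therapeutic-development tables.
#'
#' @param spec a [sim_spec()].
#' @param genes gene symbols.
#' @return data.frame, one row per gene.
#' @export
gen_evidence <- function(spec, genes) {
  set.seed(spec$seed + 4000L)
  n <- length(genes)
  data.frame(
    gene = genes,
    h_rna = stats::runif(n, 0, 400),
    proteomics_mh_pct = stats::runif(n, 0, 100),
    antibody_class = sample(c("clinical", "preclinical", "none"), n, TRUE, c(.2, .3, .5)),
    car_class = sample(c("clinical", "preclinical", "none"), n, TRUE, c(.1, .2, .7)),
    essentiality = sample(c("histotype", "any", "none"), n, TRUE, c(.2, .2, .6)),
    fusion = sample(c("histotype", "any", "none"), n, TRUE, c(.1, .2, .7)),
    snv_indel = sample(c("histotype", "any", "none"), n, TRUE, c(.2, .3, .5)),
    cna = sample(c("histotype-rna-corr", "histotype", "none"), n, TRUE, c(.2, .3, .5)),
    cellline_protein = stats::runif(n) < 0.4,
    stringsAsFactors = FALSE)
}
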