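# End-to-end orchestration: runs the stages in dependency order on
# synthetic (or user-supplied) inputs, writes per-stage TSV outputs and a
# machine-readable run manifest.

#' Default pipeline configuration
#'
#' @param seed integer seed driving the simulation and every stochastic
#'   stage.
#' @param tpi_references list of numeric reference constants for the
#'   validation scores (`h_rna_ref`, `proteomics_mh_pct_ref`); the pipeline
#'   refuses to run the prioritization stage without them.
#' @param ... [scanact_config()] overrides.
#' @return list with `seed`, `spec`, `config`, `tpi_references`.
#' @export
default_pipeline_config <- function(seed = 1L,
                                    tpi_references = list(h_rna_ref = 50,
                                                          proteomics_mh_pct_ref = 50),
                                    ...) {
  list(seed = as.integer(seed), spec = sim_spec(seed = as.integer(seed)),
       config = scanact_config(...), tpi_references = tpi_references)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full target-discovery pipeline on synthetic inputs
#'
#' Stage order: simulate, malignancy calling, differential-expression
#' aggregation, monospecific nomination, "AND" and "AND-NOT" pair scoring,
#' peptide-MHC selection, cross-reactivity profiling, and target priority
#' indices.  Every stage writes a TSV under `out_dir`; a JSON manifest
#' records the seed, package version, configuration hash, and the MD5 of
#' every output so reruns can be verified bit-identically.
#'
#' @param pipeline_config from [default_pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(pipeline_config = default_pipeline_config(),
                         out_dir = tempfile("scanact_run_")) {
  if (is.null(pipeline_config$tpi_references$h_rna_ref) ||
      is.null(pipeline_config$tpi_references$proteomics_mh_pct_ref))
    stop("prioritization stage requires explicit numeric reference constants ",
         "(tpi_references$h_rna_ref, $proteomics_mh_pct_ref); none are defaulted silently")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  spec <- pipeline_config$spec
  cfg <- pipeline_config$config
  outputs <- character()

  # -- simulate ---------------------------------------------------------------
  cohort <- gen_cohort(spec)
  panels <- gen_normal_panels(spec)
  deg <- gen_deg_tables(spec, cohort)
  lig <- gen_ligandome(spec)
  outputs["deg_tables"] <- .write_tsv(deg, file.path(out_dir, "deg_tables.tsv"))

  # -- malignancy -------------------------------------------------------------
  calls <- call_malignancy(cohort$cells, cohort$states,
                           cohort$bulk_reference, cohort$normal_reference, cfg)
  outputs["malignancy"] <- .write_tsv(calls, file.path(out_dir, "malignancy_calls.tsv"))

  # -- DEG aggregation --------------------------------------------------------
  degcalls <- aggregate_deg_calls(deg, fdr = cfg$fdr_cutoff)
  outputs["deg_calls"] <- {
    p <- file.path(out_dir, "deg_calls.tsv"); write_deg_calls(degcalls, p); p
  }

  # tumor expression summaries shared by downstream stages
  tumor_cells <- cohort$cells$counts[, calls$malignant, drop = FALSE]
  sc_log <- cpm(tumor_cells, log2p1 = TRUE)
  sc_expr <- rowMeans(sc_log)
  bulk_expr <- rowMeans(log2(cohort$bulk_reference$values + 1))
  line_expr <- stats::setNames(rep(NA_real_, length(sc_expr)), names(sc_expr))

  # -- monospecific -----------------------------------------------------------
  mono <- nominate_mono_targets(
    up_genes = degcalls$up, comparisons = deg, surfaceome = panels$surfaceome,
    sc_expr = sc_expr, bulk_expr = bulk_expr, line_expr = line_expr,
    categorical_panels = panels$cat_panels, sc_zpanel = panels$zpanels$hpa_sc,
    protein_zpanels = panels$zpanels[c("gtex_prot", "hpm", "hpa_ihc_num")],
    references = panels$references, config = cfg)
  outputs["mono"] <- .write_tsv(mono, file.path(out_dir, "mono_targets.tsv"))

  # -- "AND" pairs ------------------------------------------------------------
  pool <- panels$genes$and_pool
  set.seed(pipeline_config$seed + 5000L)
  co <- tumor_coexpression(tumor_cells, pool, alpha = cfg$coexpr_alpha)
  nn <- normal_coexpression_N(co[, c("gene_i", "gene_j")], panels$zpanels,
                              alpha = cfg$coexpr_alpha)
  and_tab <- cbind(co[, c("gene_i", "gene_j", "rho_tumor")],
                   nn[, c("n_raw", "n_norm")],
                   ts_and(co$rho_tumor, nn$n_norm, cutoff = cfg$ts_and_cutoff))
  outputs["and_pairs"] <- {
    p <- file.path(out_dir, "and_pairs.tsv"); write_pair_table(and_tab, p); p
  }

  # -- "AND-NOT" pairs --------------------------------------------------------
  inhibitors <- inhibitor_pool(degcalls$down, panels$surfaceome, sc_expr)
  activators <- panels$genes$activators
  an_pairs <- expand.grid(activator = activators, inhibitor = inhibitors,
                          stringsAsFactors = FALSE)
  andnot_tab <- ts_and_not(an_pairs, panels$zpanels, alpha = cfg$coexpr_alpha,
                           selection_percentile = cfg$ts_andnot_percentile)
  outputs["andnot_pairs"] <- {
    p <- file.path(out_dir, "andnot_pairs.tsv"); write_pair_table(andnot_tab, p); p
  }

  # -- peptide-MHC selection --------------------------------------------------
  freqs <- world_allele_frequency(lig$allele_freq)
  peptides <- enumerate_peptides(lig$proteins)
  records <- score_pmhc_records(peptides, lig$hlathena, lig$deepimmuno, freqs)
  records <- select_candidate_pmhcs(records, k_peptides = cfg$top_k_peptides,
                                    ts_pct = cfg$ts_tcr_percentile,
                                    hlathena_min = cfg$hlathena_min)
  outputs["pmhc"] <- .write_tsv(records, file.path(out_dir, "pmhc_candidates.tsv"))

  # -- cross-reactivity -------------------------------------------------------
  index <- build_ligandome_index(lig$observed, lig$predicted,
                                 presentation_min = cfg$presentation_min,
                                 affinity_max = cfg$affinity_percentile_max)
  cand <- unique(rbind(lig$tumoral[, c("peptide", "allele")],
                       data.frame(peptide = lig$reference$peptide,
                                  allele = lig$reference$allele)))
  profiles <- lapply(seq_len(nrow(cand)), function(i)
    cr_profile(cand$peptide[i], cand$allele[i], index, lig$consensus_panel,
               lig$model, s_sim_threshold = cfg$s_sim_threshold))
  prof_mat <- do.call(rbind, lapply(profiles, `[[`, "profile"))
  rownames(prof_mat) <- paste(cand$peptide, cand$allele, sep = "|")
  ref_row <- nrow(cand)
  diffs <- vapply(seq_len(nrow(cand) - 1L), function(i)
    s_cr_diff(prof_mat[i, ], prof_mat[ref_row, ], prof_mat,
              alpha = cfg$s_cr_diff_alpha)$s_cr_diff, numeric(1L))
  scr_tab <- data.frame(peptide = cand$peptide[-ref_row],
                        allele = cand$allele[-ref_row],
                        s_cr_diff = diffs, acceptable = diffs <= 0,
                        stringsAsFactors = FALSE)
  outputs["pstract"] <- .write_tsv(scr_tab, file.path(out_dir, "crossreactivity.tsv"))

  # -- target priority indices ------------------------------------------------
  mono_sel <- mono[mono$selected, , drop = FALSE]
  if (nrow(mono_sel) >= 2L) {
    ev <- gen_evidence(spec, mono_sel$gene)
    refs <- pipeline_config$tpi_references
    v <- vapply(seq_len(nrow(ev)), function(i)
      suppressWarnings(v_car(ev[i, ], refs)), numeric(1L))
    tpi <- tpi_car(stats::setNames(mono_sel$ts_car, mono_sel$gene),
                   stats::setNames(v, ev$gene))
    outputs["tpi_car"] <- .write_tsv(tpi, file.path(out_dir, "tpi_car.tsv"))
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("scanact")),
    seed = pipeline_config$seed,
    config_hash = .hash_object(pipeline_config[c("seed", "config", "tpi_references")]),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
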