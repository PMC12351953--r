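mk_npanel <- function(...) {
  rows <- list(...)
  vals <- do.call(rbind, rows)
  colnames(vals) <- paste0("t", seq_len(ncol(vals)))
  toy_zpanel(vals)
}

test_that("N(g) sums dataset weights for candidates under the reference envelope", {
  z_pass <- mk_npanel(CGA1 = c(2, 2, 2), good = c(1, 1, 1), bad = c(3, 1, 1))
  ds <- list(hpa_rna = z_pass, gtex_rna = z_pass, hpa_ihc_num = z_pass,
             gtex_prot = z_pass, hpm = z_pass, hpa_sc = z_pass)
  res <- n_score(c("good", "bad", "ghost"), ds, "CGA1")
  expect_equal(res$n_score[res$gene == "good"], 9.5)      # 1+1+2+2+2+1.5
  expect_equal(res$n_score[res$gene == "bad"], 0)         # exceeds in one tissue, everywhere
  expect_equal(res$n_score[res$gene == "ghost"], 0)
  # exceeding in a single bulk dataset only costs that dataset's weight
  ds2 <- ds; ds2$hpa_rna <- mk_npanel(CGA1 = c(2, 2, 2), good = c(3, 1, 1),
                                      bad = c(3, 1, 1))
  expect_equal(n_score("good", ds2, "CGA1")$n_score, 8.5)
  expect_warning(n_score("good", list(hpa_rna = mk_npanel(x = c(1, 1))), "CGA1"),
                 "no reference")
})

test_that("TCR high-expression filter applies primary and relaxed rules", {
  genes <- paste0("g", 1:8)
  sc <- setNames(1:8, genes)             # q25 = 2.75
  bulk <- setNames(8:1, genes)
  line <- setNames(rep(NA_real_, 8), genes)
  ns <- setNames(c(rep(0, 7), 9.5), genes)
  res <- tcr_high_expression_filter(genes, sc, bulk, line, ns)
  expect_true(res$primary[res$gene == "g5"])    # both above q25
  expect_false(res$high_expression[res$gene == "g1"])  # sc below q25 fails both
  expect_true(res$relaxed[res$gene == "g8"])    # N >= 3.5 rescues
  expect_false(res$primary[res$gene == "g8"])   # bulk below q25, line missing
})

test_that("peptide enumeration counts follow the closed form and skips bad windows", {
  two <- enumerate_peptides(c(p10 = "ACDEFGHIKL"))
  expect_equal(sum(two$length == 9), 2)
  expect_equal(sum(two$length == 10), 1)
  one <- suppressWarnings(enumerate_peptides(c(p9 = "ACDEFGHIK")))  # no 10-mers
  expect_equal(nrow(one), 1)
  expect_equal(one$length, 9L)
  w <- testthat::capture_warnings(
    bad <- enumerate_peptides(c(px = "ACDEFGHIKLMNPQRSTVWYXAA")))
  expect_true(any(grepl("non-standard", w)))
  expect_false(any(grepl("X", bad$peptide)))
  w2 <- testthat::capture_warnings(enumerate_peptides(c(short = "ACD")))
  expect_true(all(grepl("shorter", w2)))
  # closed form: L - 8 nine-mers plus L - 9 ten-mers when windows are distinct
  set.seed(31)
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  for (L in c(12, 25, 40)) {
    s <- paste(sample(aa20, L, TRUE), collapse = "")
    expect_equal(nrow(enumerate_peptides(setNames(s, "p"))), (L - 8) + (L - 9))
  }
})

test_that("world allele frequency is a population-weighted country mean", {
  tab <- data.frame(allele = "A*01:01",
                    population = c("p1", "p2"),
                    frequency = c(0.2, 0.0),
                    country = c("X", "Y"),
                    population_size = c(1e6, 3e6))
  expect_equal(unname(world_allele_frequency(tab)["A*01:01"]), 0.05)
  single <- data.frame(allele = "B*07:02", population = "p", frequency = 0.1,
                       country = "Z", population_size = 5e6)
  expect_equal(unname(world_allele_frequency(single)["B*07:02"]), 0.1)
  # invariant to record order and to splitting a population into equal halves
  tab2 <- tab[2:1, ]
  expect_equal(world_allele_frequency(tab2), world_allele_frequency(tab))
  split_tab <- rbind(tab, within(tab[1, ], population <- "p1b"))
  expect_equal(world_allele_frequency(split_tab), world_allele_frequency(tab))
  # missing population size drops the country with a warning
  tab3 <- tab; tab3$population_size[2] <- NA
  expect_warning(out <- world_allele_frequency(tab3), "dropping")
  expect_equal(unname(out["A*01:01"]), 0.2)
})

test_that("TS_TCR/PC formula and monotonicity", {
  expect_equal(ts_tcr_pc(0.9, 0.6, 0.10), 1.65)
  expect_equal(ts_tcr_pc(0, 0, 0.5), 0)
  expect_equal(ts_tcr_pc(0.4, 0.3, 0), 0.7)    # F = 0 leaves the plain sum
  expect_gt(ts_tcr_pc(0.5, 0.5, 0.2), ts_tcr_pc(0.4, 0.5, 0.2))
  expect_gt(ts_tcr_pc(0.5, 0.5, 0.2), ts_tcr_pc(0.5, 0.5, 0.1))
  # bound: F in [0, 1] caps TS at twice the predictor sum
  expect_lte(ts_tcr_pc(0.7, 0.8, 1), 2 * (0.7 + 0.8))
})

test_that("candidate pMHC selection intersects rank, percentile and presentation rules", {
  # one antigen, 7 peptides with distinct cumulative frequencies
  recs <- data.frame(antigen = "AG", peptide = paste0("P", 1:7),
                     length = 9L, positions = "1",
                     allele = "A*01:01",
                     s_hlathena = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.99, 0.84),
                     s_deepimmuno = 0.5,
                     f_allele = seq(0.7, 0.1, by = -0.1),
                     stringsAsFactors = FALSE)
  recs$ts <- ts_tcr_pc(recs$s_hlathena, recs$s_deepimmuno, recs$f_allele)
  out <- select_candidate_pmhcs(recs, k_peptides = 5, ts_pct = 0, hlathena_min = 0.85)
  # peptide ranked 6th by cumulative frequency is excluded despite max TS
  expect_false(out$selected[out$peptide == "P6"])
  # presentation score below 0.85 excludes even top-ranked peptides
  expect_false(out$selected[out$peptide == "P7"])
  expect_true(all(out$selected[out$peptide %in% paste0("P", 1:5)]))
  # boundary: s_hlathena exactly 0.85 is retained
  recs2 <- recs[1, ]; recs2$s_hlathena <- 0.85
  out2 <- select_candidate_pmhcs(recs2, ts_pct = 0)
  expect_true(out2$selected)
  # ties at rank 5 keep all tied peptides
  recs3 <- recs; recs3$f_allele <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1)
  recs3$ts <- ts_tcr_pc(recs3$s_hlathena, recs3$s_deepimmuno, recs3$f_allele)
  out3 <- select_candidate_pmhcs(recs3, ts_pct = 0, hlathena_min = 0)
  expect_true(all(out3$selected[out3$peptide %in% paste0("P", 5:7)] ==
                    out3$selected[out3$peptide == "P5"]))
})

test_that("pMHC records missing predictor scores are excluded with a warning", {
  peps <- data.frame(antigen = "AG", peptide = c("AAAAAAAAA", "CCCCCCCCC"),
                     length = 9L, positions = "1", stringsAsFactors = FALSE)
  h <- data.frame(peptide = "AAAAAAAAA", allele = "A*01:01", score = 0.9)
  d <- data.frame(peptide = "AAAAAAAAA", allele = "A*01:01", score = 0.5)
  expect_warning(out <- score_pmhc_records(peps, h, d, c("A*01:01" = 0.1)),
                 "lack a predictor")
  expect_equal(nrow(out), 1)
  expect_equal(out$ts, (0.9 + 0.5) * 1.1)
})
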