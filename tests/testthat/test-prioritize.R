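test_that("H_RNA is the mean-times-percent-positive product and is linear", {
  expect_equal(h_rna(rep(0, 10)), 0)
  expect_equal(h_rna(c(4, 0)), 100)            # mean 2, 50% positive
  x <- c(1.2, 0, 3.4, 0.8)
  expect_equal(h_rna(2 * x), 2 * h_rna(x))     # doubling expression, same support
  expect_error(h_rna(numeric()), "at least one")
})

full_ev <- function(...) {
  ev <- list(h_rna = 100, proteomics_mh_pct = 80, antibody_class = "clinical",
             car_class = "clinical", essentiality = "histotype",
             fusion = "histotype", snv_indel = "histotype",
             cna = "histotype-rna-corr", cellline_protein = TRUE)
  mods <- list(...)
  ev[names(mods)] <- mods
  ev
}

test_that("V_CAR spans [0, 10] with the published item scores", {
  refs <- list(h_rna_ref = 50, proteomics_mh_pct_ref = 50)
  expect_equal(v_car(full_ev(), refs), 10)
  zero <- full_ev(h_rna = 0, proteomics_mh_pct = 0, antibody_class = "none",
                  car_class = "none", essentiality = "none", fusion = "none",
                  snv_indel = "none", cna = "none")
  expect_equal(v_car(zero, refs), 0)
  # essential in any (not the histotype) scores 0.5 alone
  only_any <- full_ev(h_rna = 0, proteomics_mh_pct = 0, antibody_class = "none",
                      car_class = "none", essentiality = "any", fusion = "none",
                      snv_indel = "none", cna = "none")
  expect_equal(v_car(only_any, refs), 0.5)
  # boundary: equal to the reference scores the full 2 points
  eq <- full_ev(h_rna = 50, proteomics_mh_pct = 0, antibody_class = "none",
                car_class = "none", essentiality = "none", fusion = "none",
                snv_indel = "none", cna = "none")
  expect_equal(v_car(eq, refs), 2)
  expect_warning(v_car(full_ev(cna = NA), refs), "missing")
  expect_error(v_car(full_ev(), list(h_rna_ref = 1)), "reference constants")
  expect_error(v_car(full_ev(essentiality = "sometimes"), refs), "unknown")
})

test_that("V_CAR and V_TCR/PC agree with brute-force lookups over the vocabularies", {
  refs <- list(h_rna_ref = 50, proteomics_mh_pct_ref = 50)
  dev <- c(clinical = 1, preclinical = 0.5, none = 0)
  ev3 <- c(histotype = 1, any = 0.5, none = 0)
  cna3 <- c("histotype-rna-corr" = 1, histotype = 0.5, none = 0)
  for (ab in names(dev)) for (es in names(ev3)) for (cn in names(cna3)) {
    ev <- full_ev(antibody_class = ab, essentiality = es, cna = cn)
    expected <- 2 + 2 + dev[[ab]] + 1 + ev3[[es]] + 1 + 1 + cna3[[cn]]
    expect_equal(v_car(ev, refs), expected)
    expected_t <- 2 + 1 + ev3[[es]] + 1 + 1 + cna3[[cn]]
    expect_equal(v_tcr_pc(ev, refs), expected_t)
  }
})

test_that("V_TCR/PC spans [0, 7] and the cell-line item scores 1 alone", {
  refs <- list(h_rna_ref = 50)
  expect_equal(v_tcr_pc(full_ev(), refs), 7)
  only_line <- full_ev(h_rna = 0, cellline_protein = TRUE, essentiality = "none",
                       fusion = "none", snv_indel = "none", cna = "none")
  expect_equal(v_tcr_pc(only_line, refs), 1)
  none <- full_ev(h_rna = 0, cellline_protein = FALSE, essentiality = "none",
                  fusion = "none", snv_indel = "none", cna = "none")
  expect_equal(v_tcr_pc(none, refs), 0)
})

test_that("TPI_CAR normalizes both components and preserves affine-invariant ranking", {
  ts <- c(a = 11.5, b = 5, c = 8)
  v <- c(a = 10, b = 0, c = 4)
  out <- tpi_car(ts, v)
  expect_equal(out$tpi[out$gene == "a"], 2)  # both pool maxima
  expect_equal(out$tpi[out$gene == "b"], 0)  # both pool minima
  expect_true(all(out$tpi >= 0 & out$tpi <= 2))
  out2 <- tpi_car(3 * ts + 7, v)             # affine rescale of raw scores
  expect_identical(out2$gene, out$gene)
  expect_equal(out2$tpi, out$tpi)
  expect_warning(tpi_car(ts["a"], v["a"]), "fewer than 2")
})

test_that("gated TPI averages pair scores per gene before normalizing", {
  pairs <- data.frame(gene_i = c("A", "A", "B"), gene_j = c("B", "C", "C"),
                      ts = c(1.5, 1.1, 1.9))
  v <- c(A = 2, B = 4, C = 0)
  out <- tpi_gate(pairs, v, gene_cols = c("gene_i", "gene_j"), score_col = "ts")
  expect_equal(out$mean_ts[out$gene == "A"], mean(c(1.5, 1.1)))
  expect_equal(out$mean_ts[out$gene == "B"], mean(c(1.5, 1.9)))
  expect_true(all(out$tpi >= 0 & out$tpi <= 2))
  # activator-only ranking for the AND-NOT design
  an <- data.frame(activator = c("A", "B"), inhibitor = c("X", "Y"), ts = c(1, 0.5))
  out2 <- tpi_gate(an, v[c("A", "B")], gene_cols = "activator", score_col = "ts")
  expect_identical(out2$gene[1], "A")
})

test_that("TCR/PC TPI components honor length normalization and bounds", {
  antigens <- c("AG1", "AG2", "AG3")
  n <- c(AG1 = 9.5, AG2 = 3.5, AG3 = 0)
  v <- c(AG1 = 7, AG2 = 2, AG3 = 0)
  pm <- data.frame(
    antigen = c("AG1", "AG1", "AG1", "AG2", "AG2"),
    allele = c("A*01:01", "B*07:02", "C*07:01", "A*01:01", "A*02:01"),
    f_allele = c(0.3, 0.2, 0.1, 0.05, 0.05),
    scr_acceptable = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  len <- c(AG1 = 100, AG2 = 100, AG3 = 100)
  out <- tpi_tcr_pc(antigens, n, v, pm, len)
  expect_equal(out$tpi[out$antigen == "AG1"], 5)   # maximal in every component
  expect_equal(out$hla_tot[out$antigen == "AG1"], 0.3 + 0.2 + 0.1)
  expect_equal(out$hla_tot[out$antigen == "AG2"], mean(c(0.05, 0.05)))
  expect_equal(out$pmhc_tot[out$antigen == "AG1"], 3 / 100)
  # doubling protein length halves the raw per-length counts
  len2 <- len; len2["AG1"] <- 200
  out2 <- tpi_tcr_pc(antigens, n, v, pm, len2)
  expect_equal(out2$pmhc_tot[out2$antigen == "AG1"],
               out$pmhc_tot[out$antigen == "AG1"] / 2)
  # degenerate single-antigen pool warns and zeroes the normalized terms
  w <- testthat::capture_warnings(one <- tpi_tcr_pc("AG1", n, v, pm, len))
  expect_true(all(grepl("degenerate", w)))
  expect_equal(one$tpi, 0)
})
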