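test_that("expression panels round-trip through TSV exactly", {
  m <- matrix(c(1.25, 0, 4.5, 2.125, 3, 0.875), nrow = 3,
              dimnames = list(c("TP53", "EGFR", "CD276"), c("liver", "lung")))
  p <- expression_panel(m, unit = "TPM")
  tf <- tempfile(fileext = ".tsv")
  write_expression_panel(p, tf)
  p2 <- read_expression_panel(tf, unit = "TPM")
  expect_equal(p2$values, p$values, tolerance = 1e-12)
  expect_identical(rownames(p2$values), rownames(p$values))
  expect_identical(colnames(p2$values), colnames(p$values))
})

test_that("sparse cell matrices round-trip through MTX triplets", {
  set.seed(1)
  m <- matrix(rpois(50, 1), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
  d <- tempfile()
  write_cell_counts_mtx(m, d)
  m2 <- read_cell_counts_mtx(file.path(d, "matrix.mtx"))
  expect_equal(as.matrix(m2), m, ignore_attr = TRUE)
  expect_identical(dimnames(m2), dimnames(m))
})

test_that("duplicate gene symbols are suffixed with a warning; bad input errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tA\tB", "MAGE\t1\t2", "MAGE\t3\t4"), tf)
  expect_warning(p <- read_expression_panel(tf, unit = "TPM"), "suffixed")
  expect_identical(rownames(p$values), c("MAGE", "MAGE.1"))
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tA", "G1\tnot_a_number"), tf2)
  expect_error(read_expression_panel(tf2, unit = "TPM"), "non-numeric")
})

test_that("median-centering and z-scoring match hand arithmetic", {
  # columns medians (0.5, 1.5, 2.5); row 1 centered -> (-0.5, 0.5, 1.5),
  # mean 0.5, sample SD 1 -> z = (-1, 0, 1); row 2 centered -> (0.5,-0.5,-1.5)
  p <- toy_panel(matrix(c(0, 1, 2, 1, 4, 1), nrow = 2))
  z <- median_center_zscore(p)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(z$values[2, ]), c(1, 0, -1), tolerance = 1e-12)
  expect_equal(z$unit, "zscore")
})

test_that("z-scored rows have mean 0 and sample SD 1; flat rows are flagged", {
  set.seed(2)
  m <- rbind(matrix(rnorm(50, 5, 2), nrow = 5), rep(1, 10))
  rownames(m) <- paste0("g", 1:6)
  z <- median_center_zscore(toy_panel(m))
  expect_true(all(abs(rowMeans(z$values[1:5, ])) < 1e-9))
  expect_true(all(abs(apply(z$values[1:5, ], 1, sd) - 1) < 1e-9))
  # rows matching the column-median profile are flat after centering:
  # they are zeroed and flagged rather than producing NaN
  m2 <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3),
              g4 = c(2, 4, 6))
  z2 <- median_center_zscore(toy_panel(m2))
  expect_identical(z2$zero_sd, c("g1", "g2", "g3"))
  expect_true(all(z2$values[c("g1", "g2", "g3"), ] == 0))
  expect_equal(unname(z2$values["g4", ]), c(-1, 0, 1))
  # antisymmetric input row stays antisymmetric about 0
  p2 <- toy_panel(matrix(c(-2, 0, 2), nrow = 1, dimnames = list("s", NULL)))
  # single row, three columns; column medians equal the row, so center first
  z2 <- median_center_zscore(toy_panel(rbind(s = c(2, 3, 4), f = c(3, 3, 3))))
  expect_equal(unname(z2$values["s", 1]), -unname(z2$values["s", 3]))
  expect_error(median_center_zscore(toy_panel(matrix(1:3, ncol = 1))), "single-column")
})

test_that("bulk categorization threshold is inclusive and monotone", {
  grouping <- c(t1 = "G1", t2 = "G1", t3 = "G2", t4 = "G2")
  m <- matrix(c(4, 4, 3.999, 3.999,   0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("hi", "zero"), names(grouping)))
  cat4 <- categorize_bulk_expression(toy_panel(m, grouping = grouping))
  expect_identical(unname(cat4$values["hi", ]), c("M-H", "ND-L"))
  expect_identical(unname(cat4$values["zero", ]), c("ND-L", "ND-L"))
  # monotone in the threshold: raising it never creates an M-H call
  cat5 <- categorize_bulk_expression(toy_panel(m, grouping = grouping), threshold = 5)
  expect_true(all(cat5$values == "ND-L" | cat4$values == "M-H"))
})

test_that("IHC tissue and tissue-group aggregation follows the four rules and hierarchy", {
  cats <- list(tA = c("Low", "Not Detected"),      # ND-L
               tB = c("Medium", "High"),            # M-H
               tC = c("Medium", "Medium"),          # Medium
               tD = c("Low", "Medium"))             # Variable
  lab <- aggregate_ihc_tissue_group(cats)
  expect_identical(unname(lab), c("ND-L", "M-H", "Medium", "Variable"))
  groups <- c(tA = "G1", tB = "G1", tC = "G2", tD = "G2")
  glab <- aggregate_ihc_tissue_group(cats, groups)
  expect_identical(glab[["G1"]], "M-H")       # M-H beats ND-L
  expect_identical(glab[["G2"]], "Variable")  # Variable beats Medium
  expect_error(aggregate_ihc_tissue_group(list(t = "Sky-high")), "unknown")
})

test_that("IHC numeric recoding and alias resolution behave", {
  expect_identical(unname(ihc_numeric(c("Not Detected", "Low", "Medium", "High"))),
                   c(1, 2, 3, 4))
  expect_error(ihc_numeric("Absent"), "unknown")
  al <- data.frame(alias = c("OLD1", "OLD2"), symbol = c("NEW1", "NEW2"))
  expect_warning(out <- resolve_gene_aliases(c("OLD1", "KEEP"), al), "passed through")
  expect_identical(out, c("NEW1", "KEEP"))
})

test_that("the package-wide quantile convention is linear interpolation", {
  # type-7: h = 1 + p (n - 1); for 0..10 at p = .9, h = 10 exactly
  expect_equal(scanact_quantile(0:10, 0.90), 9)
  expect_equal(scanact_quantile(1:10, 0.90), 9.1)
  expect_equal(scanact_quantile(c(0.1, 0.2, 0.3, 0.4), 0.25), 0.175)
})
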