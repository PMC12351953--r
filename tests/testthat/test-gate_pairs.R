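test_that("modified odds ratios follow the published zero/infinity rules", {
  z <- rbind(gi = c(2, 2, 2, 0, 0, 0), gj = c(0, 0, 0, 2, 2, 2))
  colnames(z) <- paste0("t", 1:6)
  expect_equal(or_mod_and(z, "gi", "gj"), 0)          # d=0, b=3, c=3
  z0 <- rbind(gi = rep(0, 4), gj = rep(0, 4)); colnames(z0) <- paste0("t", 1:4)
  expect_equal(or_mod_and(z0, "gi", "gj"), 0)         # d=0, b*c=0
  z2 <- rbind(gi = c(2, 2, 2, 0), gj = c(2, 2, 0, 2)); colnames(z2) <- paste0("t", 1:4)
  expect_equal(or_mod_and(z2, "gi", "gj"), 2)         # d=2, b=1, c=1
  zI <- rbind(gi = c(2, 2), gj = c(2, 2)); colnames(zI) <- c("t1", "t2")
  expect_identical(or_mod_and(zI, "gi", "gj"), Inf)   # d>0, b*c=0
  # AND-NOT variant
  expect_identical(or_mod_andnot(z0, "gi", "gj"), Inf)  # d=0, b=0
  zb <- rbind(gi = c(2, 2, 2), gj = c(2, 2, 2)); colnames(zb) <- paste0("t", 1:3)
  expect_identical(or_mod_andnot(zb, "gi", "gj"), Inf)  # b=0, d=3
  expect_equal(or_mod_andnot(z, "gi", "gj"), 0)         # d=0, b=3
})

test_that("odds ratios equal brute-force 2x2 enumeration over all binary patterns", {
  for (k in c(3, 5, 8)) {
    patterns <- expand.grid(rep(list(c(0, 2)), k))
    set.seed(k)
    for (trial in 1:25) {
      zi <- unlist(patterns[sample(nrow(patterns), 1), ])
      zj <- unlist(patterns[sample(nrow(patterns), 1), ])
      z <- rbind(gi = zi, gj = zj); colnames(z) <- paste0("t", 1:k)
      expect_equal(or_mod_and(z, "gi", "gj"), brute_or_and(zi, zj))
      expect_equal(or_mod_andnot(z, "gi", "gj"), brute_or_andnot(zi, zj))
    }
  }
})

mk_gate_panels <- function(pair_profile_i, pair_profile_j, n_extra = 2) {
  # one correlation panel per tag, all holding the same two planted rows
  vals <- rbind(gi = pair_profile_i, gj = pair_profile_j,
                matrix(rnorm(n_extra * length(pair_profile_i)), n_extra,
                       dimnames = list(paste0("x", seq_len(n_extra)), NULL)))
  colnames(vals) <- paste0("t", seq_along(pair_profile_i))
  p <- toy_zpanel(vals)
  list(hpa_rna = p, gtex_rna = p, hpa_sc = p, gtex_prot = p,
       hpa_ihc_num = p, hpm = p)
}

test_that("raw N sums weighted per-dataset scores and N_norm flips min-max endpoints", {
  set.seed(21)
  n_t <- 30
  anti <- c(rep(2, 15), rep(-1, 15))
  panels <- mk_gate_panels(anti, rev(anti))
  pairs <- data.frame(gene_i = c("gi", "x1", "ghost"), gene_j = c("gj", "x2", "gj"))
  res <- suppressWarnings(normal_coexpression_N(pairs, panels))
  # mutually exclusive pair: all four correlation datasets reward (+1+1+1.5+2),
  # both OR datasets see disjoint z>1 supports (+2+2) -> N = 9.5
  expect_equal(res$n_raw[1], 9.5)
  # absent gene contributes 0 from every dataset
  expect_equal(res$n_raw[3], 0)
  # endpoints: pool max -> N_norm -1, pool min -> +1
  expect_equal(res$n_norm[which.max(res$n_raw)], -1)
  expect_equal(res$n_norm[which.min(res$n_raw)], 1)
  expect_true(all(res$n_norm >= -1 & res$n_norm <= 1))
})

test_that("TS_AND arithmetic, bounds and selection cutoff", {
  expect_equal(ts_and(0.8, -0.5)$ts_and, 1.3)
  expect_true(ts_and(0.8, -0.5)$selected)
  expect_false(ts_and(0, 0)$selected)
  expect_equal(ts_and(1, -1)$ts_and, 2)   # global maximum
})

test_that("TS_AND is swap-symmetric while TS_AND-NOT is not", {
  set.seed(22)
  act <- c(rep(2, 4), rep(-0.5, 8))
  inh <- c(rep(2.5, 6), rep(-0.8, 6))
  panels <- mk_gate_panels(act, inh)
  # swap symmetry of the AND score
  p12 <- data.frame(gene_i = "gi", gene_j = "gj")
  p21 <- data.frame(gene_i = "gj", gene_j = "gi")
  n12 <- suppressWarnings(normal_coexpression_N(rbind(p12, p12), panels))$n_raw[1]
  n21 <- suppressWarnings(normal_coexpression_N(rbind(p21, p21), panels))$n_raw[1]
  expect_equal(n12, n21)
  # AND-NOT raw scores change under swap (I and A are direction-specific)
  a12 <- suppressWarnings(ts_and_not(
    data.frame(activator = c("gi", "x1"), inhibitor = c("gj", "x2")), panels))
  a21 <- suppressWarnings(ts_and_not(
    data.frame(activator = c("gj", "x1"), inhibitor = c("gi", "x2")), panels))
  expect_false(isTRUE(all.equal(a12$ts_raw[1], a21$ts_raw[1])))
})

test_that("the AND-NOT raw maximum 19 is reached when every dataset rewards with I = 1", {
  # inhibitor always at/above activator, perfectly correlated, z>1 together
  act <- c(rep(1.5, 6), rep(-1, 6))
  inh <- act + 0.2
  panels <- mk_gate_panels(act, inh, n_extra = 2)
  pairs <- data.frame(activator = c("gi", "x1"), inhibitor = c("gj", "x2"))
  res <- suppressWarnings(ts_and_not(pairs, panels))
  expect_equal(res$ts_raw[1], 19)
  expect_equal(res$ts_norm[which.max(res$ts_raw)], 1)
})

test_that("tumor co-expression zeroes non-significant pairs and keeps planted ones", {
  set.seed(23)
  n_cells <- 300
  mu <- matrix(20, 6, n_cells)
  u <- rnorm(n_cells)
  mu[1, ] <- mu[1, ] * exp(u); mu[2, ] <- mu[2, ] * exp(u)  # planted pair
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow = 6,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:n_cells)))
  res <- tumor_coexpression(counts, paste0("g", 1:6))
  planted <- res$gene_i == "g1" & res$gene_j == "g2"
  expect_gt(res$rho_tumor[planted], 0)
  # self-pairing sanity through the estimator: identical gene duplicated
  counts2 <- rbind(counts, g1b = counts["g1", ])
  res2 <- tumor_coexpression(counts2, c("g1", "g1b"))
  expect_equal(res2$rho[1], 1)
  expect_true(res2$padj[1] < 0.05)
  expect_error(tumor_coexpression(counts[, 1:10], paste0("g", 1:3)), ">= 20")
})

test_that("under the null at n = 500 cells at least 95% of pairs are zeroed", {
  set.seed(24)
  counts <- matrix(rnbinom(20 * 500, mu = 15, size = 2), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:500)))
  res <- tumor_coexpression(counts, paste0("g", 1:20))
  expect_gte(mean(res$rho_tumor == 0), 0.95)
})

test_that("inhibitor pool takes downregulated surfaceome genes strictly below the median", {
  down <- paste0("d", 1:5)
  sc <- setNames(c(0, 1, 2, 3, 4), down)   # median 2
  pool <- inhibitor_pool(down, surfaceome = c(down[1:4], "other"), sc)
  expect_identical(pool, c("d1", "d2"))    # d3 at median excluded; d5 not surfaceome
  expect_error(inhibitor_pool(character(), "s", sc), "no downregulated")
})

test_that("pair tables serialize infinities as the token Inf", {
  tf <- tempfile(fileext = ".tsv")
  write_pair_table(data.frame(a = "g1", b = "g2", or_mod = Inf), tf)
  expect_match(readLines(tf)[2], "\tInf$")
})
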