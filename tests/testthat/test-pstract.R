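test_that("positional entropy hits its closed forms", {
  expect_equal(residue_entropy(c("AAA", "ACA", "AGA"))[1], 0)  # constant column
  aa20 <- rownames(load_substitution_model()$sim)
  uniform <- vapply(aa20, function(r) paste0(r, "A"), character(1))
  expect_equal(residue_entropy(uniform)[1], 1, tolerance = 1e-12)
  half <- c("AA", "CA")
  expect_equal(residue_entropy(half)[1], log(2) / log(20), tolerance = 1e-12)
  expect_equal(residue_entropy(half)[1], 0.2314, tolerance = 1e-4)
  expect_warning(e <- residue_entropy("AAAA"), "fewer than 2")
  expect_equal(e, rep(0, 4))
  expect_error(residue_entropy(c("AA", "AAA")), "one length")
})

lig_row <- function(pep, allele = "A*01:01", parent = "P1", pres = 0.9, aff = 1) {
  data.frame(peptide = pep, allele = allele, parent = parent,
             presentation_score = pres, affinity_percentile = aff,
             stringsAsFactors = FALSE)
}

test_that("ligandome filtering applies the observed-override and boundary rules", {
  obs <- lig_row("AAAAAAAAA", pres = 0.1)                # observed, low score: kept
  pred <- rbind(lig_row("CCCCCCCCC", pres = 0.5),        # boundary <= 0.5: removed
                lig_row("DDDDDDDDD", pres = 0.8),        # kept
                lig_row("EEEEEEEEE", pres = 0.9, aff = 2.5),  # affinity >= 2: removed
                lig_row("FFFFFFFF", pres = 0.9),         # 8-mer: removed
                lig_row("GGGGGGGGG", allele = "A*01", pres = 0.9))  # bad allele
  idx <- suppressWarnings(build_ligandome_index(obs, pred))
  expect_setequal(idx$records$peptide, c("AAAAAAAAA", "DDDDDDDDD"))
  expect_true(idx$records$observed[idx$records$peptide == "AAAAAAAAA"])
  # duplicate (peptide, allele, parent) collapses to one record
  idx2 <- suppressWarnings(build_ligandome_index(rbind(obs, obs), pred))
  expect_equal(sum(idx2$records$peptide == "AAAAAAAAA"), 1)
  # an HLA- prefix is normalized away
  obs3 <- lig_row("HHHHHHHHH", allele = "HLA-B*07:02")
  idx3 <- suppressWarnings(build_ligandome_index(obs3, pred[0, ]))
  expect_identical(idx3$records$allele, "B*07:02")
})

test_that("S_sim endpoints, brute-force oracle and symmetry hold", {
  model <- toy_model()
  H <- rep(0.5, 3)
  pool <- c("AAA", "ACD", "CDE", "DDD", "AAC")
  sims <- s_sim_pool("AAA", pool, model, H)
  # the pool member equal to the tumoral peptide maximizes both components
  expect_equal(unname(sims["AAA"]), 2)
  expect_equal(min(sims), 0)   # pool minimum on both components scales to 0
  expect_true(all(sims >= 0 & sims <= 2))
  # independent brute-force recomputation to 1e-12
  for (p in pool)
    expect_equal(unname(sims[p]), unname(brute_s_sim("AAA", p, pool, model, H)),
                 tolerance = 1e-12)
  # symmetry: swapping tumoral and normal roles over the same pool
  pool2 <- c("ACD", "CDE")
  s_ab <- brute_s_sim("AAA", "ACD", pool2, model, H)
  # recompute with roles swapped but pool fixed: positional contributions are
  # symmetric in the two peptides, so the unscaled components agree
  comp <- function(a, b, dm) mean(1 / (1 + dm[cbind(strsplit(a, "")[[1]],
                                                    strsplit(b, "")[[1]])]) * (1 + H))
  expect_equal(comp("AAA", "ACD", model$dist_sub), comp("ACD", "AAA", model$dist_sub))
  expect_error(s_sim_pool("AAA", character(), model, H), "empty")
})

test_that("S_sim decreases when a positional substitution distance grows", {
  model <- toy_model()
  H <- rep(0, 3)
  # order pool partners by their distance to 'A' at position 1
  d <- sort(model$dist_sub["A", c("C", "D", "E")])
  near <- paste0(names(d)[1], "AA"); far <- paste0(names(d)[3], "AA")
  pool <- c(near, far, "WWW")
  sims <- s_sim_pool("AAA", pool, model, H)
  expect_gt(sims[near], sims[far])
})

test_that("with the shipped substitution fixture identical residues score maximal similarity", {
  model <- load_substitution_model()
  for (r in rownames(model$sim))
    expect_equal(max(model$sim[r, ]), model$sim[r, r])
  expect_true(all(model$dist_sub >= 0))
  expect_equal(unname(diag(model$dist_embed)), rep(0, 20))
})

test_that("S_CR arithmetic covers the observed bonus and multiplicative zero", {
  E <- c(t1 = 1.0, t2 = 0, t3 = -0.4)
  obs <- s_cr(0.5, E, observed = TRUE)
  expect_equal(unname(obs["t1"]), 1.25)
  expect_equal(unname(s_cr(0.5, E, observed = FALSE)["t1"]), 1.0)
  expect_equal(unname(obs["t2"]), 0)        # zero expression kills the score
  expect_lt(unname(obs["t3"]), 0)           # below-median tissue: negative, low risk
})

test_that("cross-reactivity profiles take elementwise maxima and flag empty sets", {
  model <- load_substitution_model()
  panel <- toy_zpanel(rbind(P1 = c(1, 0.2, -0.5), P2 = c(0.1, 2, 0.3)))
  colnames(panel$values) <- c("t1", "t2", "t3")
  obs <- rbind(lig_row("AAAAAAAAA", parent = "P1", pres = 0.5),
               lig_row("AAAAAAAAC", parent = "P2", pres = 0.5))
  idx <- build_ligandome_index(obs, obs[0, ])
  # threshold below the pool minimum so both normal pMHCs contribute
  prof <- cr_profile("AAAAAAAAA", "A*01:01", idx, panel, model,
                     s_sim_threshold = -1)
  s1 <- s_cr(0.5, panel$values["P1", ], TRUE)
  s2 <- s_cr(0.5, panel$values["P2", ], TRUE)
  expect_equal(prof$profile, pmax(s1, s2))
  expect_false(prof$no_crossreactive)
  # no similar normal peptide: floor profile with the flag set
  prof0 <- cr_profile("WWWWWWWWW", "A*01:01", idx, panel, model,
                      s_sim_threshold = 2.5)
  expect_true(prof0$no_crossreactive)
  expect_true(all(prof0$profile == 0))
  # absent allele stratum behaves the same way
  prof1 <- cr_profile("AAAAAAAAA", "C*07:01", idx, panel, model)
  expect_true(prof1$no_crossreactive)
})

test_that("S_CR Diff is 0 on self, 2/n above and -1/n below by one sigma", {
  n <- 5
  ref <- setNames(rep(1, n), paste0("t", 1:n))
  pool <- rbind(ref, ref + rnorm(n, 0, 1), ref - rnorm(n, 0, 1))
  sigma <- apply(pool, 2, sd)
  expect_equal(s_cr_diff(ref, ref, pool)$s_cr_diff, 0)
  expect_true(s_cr_diff(ref, ref, pool)$acceptable)
  up <- ref; up["t1"] <- ref["t1"] + sigma["t1"]
  expect_equal(s_cr_diff(up, ref, pool)$s_cr_diff, 2 / n)
  down <- ref; down["t1"] <- ref["t1"] - sigma["t1"]
  expect_equal(s_cr_diff(down, ref, pool)$s_cr_diff, -1 / n)
  # asymmetry: the upward excursion moves the mean exactly alpha times faster
  expect_equal(s_cr_diff(up, ref, pool)$s_cr_diff,
               -2 * s_cr_diff(down, ref, pool)$s_cr_diff)
  # zero-variance tissues are excluded with a warning
  pool0 <- pool; pool0[, "t2"] <- 1
  expect_warning(res <- s_cr_diff(up, ref, pool0), "zero-variance")
  expect_equal(res$n_tissues_used, n - 1)
  expect_error(s_cr_diff(up, ref[1:3], pool), "missing tissues")
})
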