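# Shared toy fixtures, built in code.

toy_panel <- function(values, unit = "log2p1", grouping = NULL) {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("t", seq_len(ncol(values)))
  expression_panel(values, unit = unit, grouping = grouping)
}

# z-scored panel built directly from a value matrix (unit tag only; used
# where tests control the z values themselves)
toy_zpanel <- function(values) toy_panel(values, unit = "zscore")

# tiny residue substitution model over a reduced alphabet embedded in the
# full 20-residue space: similarity 1 on the diagonal, fixed off-diagonals
toy_model <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(7)
  emb <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(aa, paste0("PC", 1:3)))
  d <- as.matrix(dist(emb))
  sim <- exp(-d)
  dimnames(sim) <- list(aa, aa)
  structure(list(sim = sim, dist_sub = max(sim) - sim,
                 embedding = emb, dist_embed = d),
            class = "ResidueSubstitutionModel")
}

# independent brute-force recomputation of one S_sim value (used as oracle)
brute_s_sim <- function(tumoral, normal, pool, model, H) {
  comp <- function(pt, pn, dm) {
    a <- strsplit(pt, "")[[1]]; b <- strsplit(pn, "")[[1]]
    s <- 0
    for (i in seq_along(a)) s <- s + 1 / (1 + dm[a[i], b[i]]) * (1 + H[i])
    s / length(a)
  }
  sp <- sapply(pool, comp, pt = tumoral, dm = model$dist_sub)
  sa <- sapply(pool, comp, pt = tumoral, dm = model$dist_embed)
  mm <- function(x) if (max(x) == min(x)) rep(0, length(x)) else (x - min(x)) / (max(x) - min(x))
  (mm(sp) + mm(sa))[match(normal, pool)]
}

# brute-force 2x2 enumeration oracle for the modified odds ratios
brute_or_and <- function(z_i, z_j, zcut = 1) {
  d <- sum(z_i > zcut & z_j > zcut)
  b <- sum(z_i > zcut & z_j <= zcut)
  cc <- sum(z_i <= zcut & z_j > zcut)
  if (d == 0 && b * cc == 0) 0 else d / (b * cc)
}
brute_or_andnot <- function(z_a, z_i, zcut = 1) {
  d <- sum(z_a > zcut & z_i > zcut)
  b <- sum(z_a > zcut & z_i <= zcut)
  if (b == 0) Inf else d / b
}
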