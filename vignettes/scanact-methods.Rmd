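---
title: "Scoring engineered T-cell therapy targets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring engineered T-cell therapy targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanact)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices made where the design was
genuinely open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Adoptive T-cell therapies recognize either a surface protein (CAR-T), a pair
of surface proteins combined through Boolean logic ("AND" requires both;
"AND-NOT" is blocked by an inhibitory antigen), or a peptide presented on an
HLA class I molecule (TCR-T, peptide-centric CAR-T). A usable target must be
high and homogeneous on malignant cells and low everywhere that matters in
normal tissue; for pMHC targets the peptide must also be presentable,
immunogenic, common across HLA haplotypes, and free of cross-reactive
look-alikes in the normal ligandome. Each stage of the package scores one of
these requirements; every stage consumes plain tables so external predictors
plug in without re-running their models.

## Malignant-cell classification

Copy-number states inferred per gene and cell (1 = complete loss, 3 = neutral,
6 = gain beyond two alleles) are capped at 5, mapped to $(s-3)/2 \in [-1,1]$
and squared, giving losses and gains equal weight. The tumor CNA profile is
the gene-wise mean over the CD45⁻ cells in the top 10% of per-cell burden
(`ceiling(0.10 n)` cells; ties broken by cell order — a choice the published
procedure leaves open, fixed here so runs are reproducible). A cell "has CNA" when
its Spearman correlation with that profile is strictly above the sample's 25th
percentile. Independently, the bulk-similarity score compares each cell with
the mean bulk tumor profile and the mean normal-cell profile (Spearman, shared
genes only, at least 50). The final call is the published conjunction:
CD45⁻ **and** (CNA detected **or** similarity > 0).

Assumptions worth knowing: the percentile rule presumes most CD45⁻ cells in a
tumor sample are malignant — in a sample dominated by normal cells the 25th
percentile falls inside the tumor distribution and specificity degrades. CNA
burden is averaged over *all* genes (neutral genes included); restricting to
non-neutral genes is a plausible alternative the interface does not currently
expose.

## Differential-expression aggregation

The package never fits the DE models; it aggregates their tables. A gene is
*up* if significantly up (log2FC > 0, BH-adjusted p < 0.25 — the lenient
screening threshold) in at least one comparison; *down* if significantly down
at least once and never significantly up, judged separately within each
reference class (tumor-microenvironment comparisons vs normal-tissue-panel
comparisons) and then unioned. A `strict_joint` option applies "never up"
across both classes, since the published phrasing leaves the final union
ambiguous. The normal-bias filter drops genes whose significant comparisons
favor normal cells strictly more often than tumor cells; ties keep the gene.
Log2 fold changes on CPM means use the 0.01 pseudocount.

## Monospecific CAR scoring

Candidates are upregulated surfaceome genes (HLA class I/II removed via a
config list) that survive the normal-bias filter and a high-expression rule:
at or above the candidate pool's median in single-cell *and* bulk data, or
single-cell *and* cell lines, or single-cell alone when both externals lack
the gene. Two filter families compare candidates to *tested CAR-T reference
targets*:

- *Permissive*: count tissue groups with Medium-High expression
  (log₂(TPM+1) ≥ 4 for RNA; the categorical hierarchy
  M-H > Variable > Medium > ND-L for immunohistochemistry); pass when the
  count is strictly below the references' 90th percentile.
- *Stringent*: on z-scored panels (column-median-centered, then gene-wise
  z-scored with the sample SD), pass when expression stays strictly below the
  per-tissue reference maximum in every retained tissue, and — for the
  single-cell panel — when the number of cell types with z > 1 does not
  exceed the references' 75th percentile. Lymphoid cells, tumor-like stromal
  cells, and gonadal/placental cell types are excluded (tolerable depletion,
  transcriptional similarity, immune privilege); the exclusion lists are
  config entries, applied uniformly to both stringent conditions.

`TS_CAR` sums the verdicts: bulk RNA ±1, the four protein datasets ±2,
single-cell RNA ±1.5, absent 0, so the range is [−11.5, 11.5] and protein
evidence dominates by design. Selection is inclusive at the references' 25th
percentile. With fewer than four reference scores the percentile is too
unstable and an explicit numeric cutoff is required.

All named percentiles package-wide use type-7 (linear interpolation)
quantiles, and z-scoring uses the n−1 sample SD; both conventions are fixed so
tests are exact. Zero-variance genes are zeroed and flagged rather than
propagating NaN, and are treated as score 0 by correlation-based stages.

## Logic-gated pair scoring

*Tumor co-expression.* The published pipeline uses a sparse-count
co-expression estimator; its output can be ingested as a table. The built-in
default is Spearman correlation on log₂(CPM+1) with the t-approximation
p-value. A permutation p-value was considered and rejected: with a feasible
number of permutations the p-value floor of 1/(B+1), multiplied across a
pool of hundreds of pairs by the BH correction, can never clear the 0.05
threshold, so no pair would ever be retained. Library sizes are computed on
the full count matrix before subsetting to the pair pool; normalizing within
the pool alone induces compositional anti-correlation between genuinely
co-expressed genes (this failure mode is covered by a test). Correlations
with BH-adjusted p ≥ 0.05 are set to 0.

*Normal co-expression.* Pearson correlations across tissues/samples for the
quantitative panels (the tissue-proteomics panel first drops genes with more
than 25% missing values); for the two low-column-count protein panels a
modified odds ratio over z > 1 calls replaces correlation. For "AND" pairs
mutual exclusivity is rewarded (negative ρ, or OR = 0) and co-expression
penalized with the same ±1/±2/±1.5 weights; the sum N is min-max scaled to
[−1, 1] *with a sign flip* (`N_norm`), so positive values mean normal
co-expression risk, and `TS_'AND' = ρ_Tumor − N_norm` with selection at ≥ 1.
The min-max pool is all computed pairs of the run, not only those with
nonzero tumor correlation — the alternative would make a pair's score depend
on which other pairs happened to be significant.

For "AND-NOT" pairs the reward direction inverts — an inhibitor co-expressed
with its activator across normal tissue is protective — and rewards are
magnified by (1 + I), penalties by (1 + A), where I is the fraction of dataset
columns with inhibitor z at or above activator z and A the fraction with
activator strictly above. (The published definition of A contains an obvious
copy-paste slip — "activator above the activator" — which the attached
z-score inequality disambiguates.) The odds ratio here is d/b with
OR = Inf (including d = b = 0) marking a suitable pair; infinities are
serialized as the token `"Inf"`, never floating-point, in output tables.
Normalized scores above the pool's 99th percentile are selected.

## Peptide-MHC targetability

`N(g)` compares a candidate with cancer-germline-antigen reference targets:
below the reference maximum in every tissue group earns the dataset weight
(+1 bulk, +2 protein, +1.5 single-cell; no penalties), so `N(g) ∈ [0, 9.5]`
and the 3.5 admission cutoff requires clearing more than the two bulk panels.
Candidate peptides are all distinct 9/10-mers of each antigen (windows with
non-standard residues skipped). World HLA allele frequencies average
population studies within a country, then weight countries by population
size. `TS_TCR/PC = (S_pres + S_imm)(1 + F_allele)` keeps both predictor scores
on their native [0, 1] scales; the allele-frequency factor at most doubles
the score. The 99th-percentile TS filter is applied per antigen — the
published description sits inside the per-antigen ranking paragraph — with a
global-scope option exposed; cumulative-frequency ties at rank 5 keep all
tied peptides.

## Cross-reactivity (PS-TRACT)

The unified normal ligandome merges observed (mass-spectrometry) and
predicted records, deduplicated on (peptide, allele, parent); predicted-only
records need affinity percentile < 2.0 and presentation score > 0.5, while
observation overrides the presentation floor. Positional entropy per
(allele, length) stratum uses natural-log Shannon entropy normalized by
log 20 — the published 0-to-1 range forces the normalization and makes the
base irrelevant.

Similarity between a tumoral and a normal peptide sums two components — one
from a binding-energy-covariance substitution matrix, one from a 9-dimensional
physicochemical residue embedding — each the positional mean of
$\frac{1}{1+dist}(1+H_i)$, min-max scaled within the comparison pool (all
normal peptides of that allele and length; a global-scaling option exists).
Entropy weighting up-weights positions where the ligandome tolerates
variation, i.e. positions a TCR is less likely to read. The shipped
substitution tables are deterministic *synthetic* stand-ins (filenames say
so); the published matrices drop in through `load_substitution_model()`, and
published similarity values (e.g. the MAGEA3/titin pair) are only
reproducible with them.

Normal pMHCs with `S_sim > 1.15` are scored per tissue,
`S_CR = (P + 0.5)·E·1.25^{observed}`, where E is the parent antigen's
median-centered z-scored consensus expression — so below-median tissues give
negative scores, read as low risk. The profile of a tumoral pMHC is the
per-tissue maximum; tissues with no cross-reactive peptide get a flagged
floor of 0, preventing silent optimism. Benchmarking against the reference
pMHC uses the mean standardized difference with α = 2 on excursions above the
reference; σ_j is computed over candidates *plus* the reference (the
published scope is unstated), zero-variance tissues are excluded with a
warning, and `S_CR Diff ≤ 0` is acceptable.

## Target priority indices

`H_RNA` multiplies mean log₂(CPM+1) in tumor cells by the percentage of
positive cells, rewarding homogeneous antigens. Validation scores sum closed
-vocabulary evidence items (therapeutic-development status, cell-line
essentiality at the Chronos ≤ −1 level, fusions, SNV/indels, copy-number
events with expression correlation); reference constants (the comparator
antigen's `H_RNA` and proteomics prevalence) must be supplied explicitly —
there is no silent default, and the pipeline refuses to run prioritization
without them. Every TPI term is min-max normalized within the histotype pool
(matching every other normalization in the framework); degenerate pools
normalize to 0 with a warning rather than NaN. For gated designs the per-gene
score is the mean over selected pairs containing the gene (both genes for
"AND", the activator for "AND-NOT").

## The synthetic generator

`sim_spec()` fixes the study conditions: a 520-cell sample that is 77%
malignant (the regime the percentile-based CNA rule assumes), negative
binomial counts with size 2, a 30-gene tumor signature at log2FC 2, two
40-gene CNA blocks (gain and loss) in 95% of tumor cells with 2% one-step
state noise, PTPRC restricted to immune classes, ten "AND" pairs driven by
per-pair lognormal latent factors, and two "AND-NOT" plants whose inhibitors
share the activator's normal-tissue support at a higher level. Normal panels
plant mutually exclusive supports with pair-specific random tissue splits —
deterministic splits would make *cross*-pair combinations accidentally
exclusive and create false planted positives. Reference targets get
expression envelopes tiling every tissue so filter thresholds are defined
everywhere. The ligandome draws peptides from position-specific distributions
(anchor positions 2 and C-terminal nearly constant; others broad), plants a
single-substitution neighbor for each tumoral peptide, and gives the
reference pMHC six observed neighbors whose parents tile the consensus
tissues, so candidate profiles compare favorably by construction.

What the generator does **not** emulate: ambient RNA, doublets, batch
structure, realistic gene-gene correlation beyond the planted factors,
ligandome length/allele biases, or real substitution statistics. Passing
tests therefore demonstrate that the scoring rules recover structure they are
designed to detect at realistic effect sizes — not that the thresholds are
optimal for any particular cohort.

Problem sizes were chosen so the whole suite and the acceptance script run in
well under a minute: 520 cells × ~210 genes, 190 "AND" pairs, 200 "AND-NOT"
pairs, ~60 peptides per ligandome stratum. All randomness flows from the
single spec seed; generators re-seed deterministically (seed + fixed offsets)
so each can be called independently.

## Known limitations

- The stringent filters inherit an artifact of within-gene z-scoring: a gene
  that is uniformly low across tissues still produces z-scores with unit
  variance, so "below the reference maximum in every tissue" can fail on
  noise for genes with no real signal. Reference envelopes covering every
  tissue mitigate but do not remove this.
- `S_sim` is pool-relative: adding or removing normal peptides changes every
  score, so thresholds calibrated on one ligandome version do not transfer
  exactly to another.
- The double use of the immunohistochemistry source (categorical in the
  permissive filter, numeric in the stringent filter) follows the published
  four-protein-dataset accounting; it means one underlying dataset
  contributes up to ±4 of the TS_CAR range.
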