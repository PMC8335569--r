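---
title: "Identifying somatic mutation-driven immune cells: methods and design"
author: "mutcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying somatic mutation-driven immune cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutcell)
```

## The problem and the model

Somatic mutations in protein-coding regions can create neoantigens, and the
immune cells reacting to them infiltrate the tumor. With a cohort that has
both whole-exome variant calls and bulk RNA-seq, one can ask, gene by gene:
*which infiltrating cell types differ systematically between patients who
carry a non-silent mutation of this gene and patients who do not?* `mutcell`
answers this with a fixed chain of classical statistics rather than a joint
model, which keeps every step auditable:

1. a binary mutation matrix *M* (gene × sample; 1 = any non-silent variant);
2. a relative cell-abundance matrix *A* (cell × sample) inferred from
   expression;
3. per gene, a two-class SAM test of each cell's abundance against the
   mutation vector;
4. row z-scoring of the dysregulated cells and binarization at |z| > 2 into
   disjoint up/down response matrices;
5. per cell, a Fisher exact test of the 2 × 2 mutation × response table,
   Benjamini–Hochberg corrected within the gene;
6. optionally, a Cox risk score over a gene's driven cells, median-split
   into high/low-risk survival groups.

The implicit assumptions are worth stating. The SAM step assumes cell
abundance is approximately location-shifted between mutation classes with
comparable scatter; the permutation null only requires exchangeability of
samples under the null. The binarization step reframes "response" as an
*extreme* per-sample abundance (beyond 2 row SDs), so the Fisher step asks
whether extreme responders concentrate among mutated samples — a deliberately
conservative notion that tolerates heavy-tailed abundance distributions but
requires the mutated fraction to be well below one half for upward responses
to be callable at all (with half the cohort shifted, the row SD inflates
until nothing exceeds 2). The Cox step assumes proportional hazards linear
in the abundances.

## Inferring cell abundance

`ssgsea_score()` implements single-sample gene-set enrichment: per sample,
genes are ranked by descending expression and a set's score is the summed
difference between the weighted cumulative fraction of set genes
(weight `(N - rank + 1)^alpha`) and the unweighted cumulative fraction of
non-set genes. Because only within-sample ranks enter, the score is
invariant to any per-sample monotone transform — log-scale versus linear
FPKM, library-size rescaling, and quantile shifts all give identical scores,
which is why the pipeline accepts "expression units" loosely.

Parameters:

* `alpha` (default 0.25, dimensionless ≥ 0): the rank-weight exponent.
  0 gives the plain ECDF difference; 0.25 is the de-facto standard
  compromise that up-weights top-ranked genes without letting a single
  outlier gene dominate.
* `normalize` (default `TRUE`): divides the whole matrix by its global
  max − min, putting scores of differently sized signatures on one scale.
  Normalization is global, so it never changes within-row z-scores
  downstream.

Ties in expression are broken by ascending gene identifier, making scores
bit-reproducible. Signature genes absent from the matrix are dropped per set
(reported); a set with no genes present scores `NA` with a warning, and a
set covering *every* expressed gene is an error (its complement, needed for
the miss fraction, is empty). Abundance matrices from external deconvolution
tools (xCell, CIBERSORT) can be supplied instead via `import_abundance()`;
their algorithms are treated as interchangeable backends and are not
re-implemented here.

## The mutation matrix

`classify_nonsilent()` recognises the nine canonical MAF
`Variant_Classification` tokens for protein-altering variants (nonsense,
missense, frameshift insertions/deletions, splice site, nonstop,
translation start site, in-frame insertions/deletions), case-insensitively;
everything else — silent, UTR, intron, unknown tokens — is non-damaging.
`build_mutation_matrix()` computes each gene's mutation frequency over the
*declared sample universe* (normally the expression-matched samples), not
over the mutated samples that happen to appear in the MAF, so that mutation
status is defined for every analysed sample. The frequency filter (default
1%) is *inclusive*: a gene mutated in exactly 1% of samples is retained.
TCGA-style barcodes are reconciled by truncation to a configurable prefix
(default 15 characters, the sample level), since mutation and expression
assays carry different suffixes.

## The SAM step

`sam_statistic()` is the Tusher two-class unpaired statistic with the pooled
scatter denominator and a fudge factor `s0`. `estimate_s0()` chooses `s0`
from `{0}` and the 5%-step quantiles of the per-cell scatters by minimising
the coefficient of variation of windowed median absolute deviations of *d*
across scatter quantiles. Cell panels are small (tens of rows, not
thousands of genes), so the window count adapts as
`max(2, min(10, floor(n/5)))` rather than the hundred windows customary for
genome-wide arrays. Degenerate panels fall back deterministically (all
scatters equal → that value; a single row → its own scatter, with a
warning).

`sam_test()` draws `n_perm` (default 1000) label permutations preserving
class sizes, pools all permuted |d*| across cells into one null, and
computes per-cell p-values with a pseudo-count,
`p = (1 + #{|d*| ≥ |d|}) / (1 + n_perm × n_cells)`, followed by BH
q-values across cells. Pooling is what makes ~30–64 cells give usable
p-value resolution; the cost is a mild exchangeability-across-cells
assumption under the null. `s0` is held fixed at its observed estimate
across permutations, the standard SAM practice. Two numerical details
ensure reproducibility: the seed is mandatory, and the permutation null is
drawn over a canonical (sorted-identifier) sample arrangement, so applying
the same sample permutation to both inputs provably returns identical
results.

## Association and multiple testing

`zscore_rows()` standardises with the sample SD (n − 1); constant rows
become zeros and are flagged rather than producing NaNs. `binarize()` is
strict above (`z > t`) and inclusive below (`z ≤ −t`), with `t = 2.0` —
up and down events are disjoint for any positive threshold. Only the matrix
matching a cell's SAM direction is tested (up matrix if d > 0), so direction
is decided by the abundance shift, not by the Fisher table.

`fisher_exact_2x2()` computes the two-sided p by minimum-likelihood
summation over the margin-fixed table family, counting tables whose
hypergeometric probability is within a 1 + 1e−7 relative factor of the
observed one (guarding against ties lost to floating-point). The odds ratio
is the sample estimate ad/bc (`Inf` when bc = 0 with ad > 0); a zero margin
is degenerate and returns p = 1 with an `NA` odds ratio. BH correction is
applied per gene across its tested cells by default, mirroring the
gene-at-a-time workflow; a `global_fdr` flag pools across genes for users
who prefer a cohort-wide guarantee.

`cooc_mutex()` applies the same exact test to each unordered gene pair's
joint mutation table, labelling pairs co-occurring (OR > 1, p < α) or
mutually exclusive (OR < 1, p < α).

## The risk signature

`fit_cox()` delegates the partial-likelihood maximisation to the `survival`
package with Breslow tie handling by default (the simpler deterministic
choice; Efron available by flag). Zero-variance cells are dropped with a
warning, exact collinearity is resolved by dropping later-indexed
duplicates, and convergence failure is an error suggesting fewer cells —
with |S| approaching the event count the model is not identifiable anyway.
Risk scores are the raw linear predictor Σ β_k a_k over the driven cells
(a `zscore` flag switches to standardized abundances for users whose
abundance units differ wildly across cells). `median_split()` sends ties at
the median to the low-risk group, a deterministic convention; all-equal
scores are a "degenerate signature" error. The log-rank comparison and
Kaplan–Meier curves come from `survival::survdiff`/`survfit`.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` produces the statistical structure the method assumes:
iid Bernoulli mutation status per gene, unit-Gaussian baseline abundance
per cell, additive mean shifts (in SD units) in mutated samples for each
planted (gene, cell) pair, and exponential survival with hazard
exp(Σ β_c a_c) under independent exponential censoring calibrated to a
target censoring fraction. In expression mode it also emits a gene × sample
matrix in which each cell's signature genes track that cell's abundance
(`coupling`, default 1) against a background of unrelated genes with
heterogeneous dispersions (per-gene SD uniform on 0.5–4 by default), plus
the matching GMT, so the full expression → score → association path is
exercised.

Two generator choices deserve their rationale. First, the heterogeneous
background dispersion and moderate coupling are not cosmetic: a rank-based
score *saturates* once a cell's signature genes all reach the top of the
ranking, and with a homogeneous tight background even modest abundance
shifts pin every signature gene above the background, compressing planted
effects in score space below the z > 2 response threshold. Keeping
signature shifts comparable to the spread of background genes holds the
rank map in its linear regime — which is also the realistic situation, as
log-scale expression data show order-of-magnitude differences in per-gene
dispersion. Second, `dropout_genes()` removes a random gene subset as a
prefix of one seeded permutation, so for a fixed seed the removed sets are
nested across increasing fractions; the subsets remain uniformly
distributed while the robustness curve is measured on coupled rather than
independent removals, reducing its Monte-Carlo variance.

What the generator does *not* emulate: count noise and mean–variance
coupling of real RNA-seq, correlated cell abundances (real infiltrates
co-vary strongly), signature overlap between related cell types, mutation
co-occurrence structure, and non-proportional hazards. Passing calibration
on these cohorts therefore demonstrates that the chain of statistics is
correctly implemented and calibrated under its own assumptions — not that
those assumptions hold in any particular tumor cohort.

## Calibration studies and problem sizes

The test suite and `scripts/acceptance.R` measure, at sizes chosen to make
Monte-Carlo error small while keeping a laptop run comfortable:

* exactness of the Fisher p against full enumeration (all tables with
  margins ≤ 12) and of BH against direct step-up (1000 random vectors);
* agreement of the ssGSEA scorer with a literal running-sum oracle to
  1e−12, and its monotone-transform invariance;
* type-I behaviour of the whole identification chain on null cohorts
  (200 samples, 30 cells, 10 genes at 20% frequency, 1000 permutations,
  50 seeds) and recovery of planted +2 SD effects at 30% frequency
  (sensitivity and empirical FDR over 50 seeds);
* Cox coefficient recovery (planted β = 1, −1, 0; 500 samples, 25 seeds)
  with null-cell CI coverage;
* the gene-dropout robustness curve at 5–20% removal in 5% steps through
  the full expression path (150 samples, 10 cells, 400 genes, 6 seeds);
* byte-identical pipeline outputs for a fixed seed.

## Known limitations

* Upward responses of very frequently mutated genes (mutated fraction
  approaching 50%) are structurally hard to call through z > 2
  binarization, as discussed above; the SAM step still reports such cells
  as dysregulated.
* The per-gene BH correction controls FDR within each gene's cell panel;
  across hundreds of genes the summary table's expected number of false
  gene–cell pairs grows accordingly (use `global_fdr = TRUE` when that
  matters).
* Abundance scores are *relative*; Cox coefficients are per score unit and
  not comparable across scoring backends.
* One mutation gene is tested at a time; co-mutation confounding (e.g. two
  co-occurring drivers sharing credit for one cell response) is visible only
  through the co-occurrence module, not adjusted for.
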