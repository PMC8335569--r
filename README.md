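# mutcell

Identification of somatic mutation-driven tumor-infiltrating immune cells
from paired genomic and transcriptome data.

Tumor somatic mutations can generate neoantigens that trigger immune cell
responses in the tumor microenvironment, but which infiltrating cell types
respond to which mutated genes is rarely obvious from either data type
alone. `mutcell` integrates two matrices over a common sample cohort — a
binary gene × sample somatic-mutation matrix (built from MAF variant calls)
and a cell × sample relative-abundance matrix (inferred from bulk expression
by single-sample gene-set enrichment, or imported from any deconvolution
tool) — and reports, per mutated gene, the cell types whose abundance is
statistically driven by that gene's mutation status. It is aimed at cancer
genomics analysts working with TCGA-style cohorts (whole-exome MAF +
RNA-seq + clinical follow-up).

## Method

For each gene *g* retained by the mutation-frequency filter (non-silent
variants only; default frequency ≥ 1%):

1. **Differential abundance (SAM).** Every cell type's abundance row is
   tested between mutated and wild-type samples with the moderated statistic

   *d* = (x̄₁ − x̄₀) / (s + s₀),

   where *s* is the pooled scatter and *s₀* a data-driven fudge factor
   stabilising low-variance rows. Significance comes from a pooled
   permutation null (1000 label permutations by default) with
   Benjamini–Hochberg q-values; cells with q < 0.05 are dysregulated.
2. **Binarization.** Dysregulated cells' rows are z-scored across all
   samples; entries with z > 2 (up) or z ≤ −2 (down) become per-sample
   response events, giving disjoint binary up/down matrices.
3. **Fisher association.** Per dysregulated cell, the 2 × 2 table of
   mutation status × binary response (from the matrix matching the cell's
   SAM direction) is tested by the two-sided Fisher exact test; BH-adjusted
   p < 0.05 within the gene calls the cell *driven* by the mutation.
4. **Risk signature.** The driven cells *S* of a gene define a prognostic
   score per patient, Riskscore = Σ_{k∈S} β_k a_k, with β_k from a
   multivariate Cox model of overall survival on the cell abundances;
   patients split at the median score into high/low-risk groups compared by
   the log-rank test and Kaplan–Meier curves.

Supporting tools: pairwise mutation co-occurrence/mutual-exclusivity tests,
oncoprint waterfall / heat-map / KM plots (each emitting an assertable
layout table), a synthetic-cohort generator with planted ground truth, and
a gene-dropout robustness experiment.

## Worked example

On a synthetic 200-patient cohort where mutations of `G001` (31.5% mutated)
shift the abundance of `cell05` and `cell09` by +2.5 SD, and `cell05` also
carries a planted survival hazard:

```r
library(mutcell)

truth <- cohort_truth(
  planted   = data.frame(gene = "G001", cell = c("cell05", "cell09"),
                         direction = 1, effect = 2.5),
  mut_freq  = 0.3,
  surv_beta = c(cell05 = 0.9), censor_rate = 0.25)
cohort <- generate_cohort(n_samples = 200, n_cells = 12, n_genes = 4,
                          truth, seed = 7)

assoc <- find_driven_cells(cohort$abundance, cohort$mutations,
                           n_perm = 1000, seed = 7)
assoc
#> Mutation-driven immune cell identification
#>   4 gene(s), 200 sample(s); SAM q < 0.05, Fisher FDR < 0.05, |z| > 2
#>   1 gene(s) with driven cells
#>  gene          cells cell_count mutation_rate
#>  G001 cell05, cell09          2         0.315

assoc$genes[["G001"]][, c("cell", "direction", "odds_ratio", "p", "fdr", "driven")]
#>     cell direction odds_ratio            p          fdr driven
#> 2 cell09        up        Inf 0.0002422486 0.0004844972   TRUE
#> 1 cell05        up        Inf 0.0008244953 0.0008244953   TRUE
```

Both planted cells — and nothing else — are recovered: each responds in the
"up" direction, the infinite odds ratio meaning every extreme (z > 2)
responder is a mutated sample. The per-gene detail table is the same shape
users get from the pipeline's `details/<gene>.tsv`. The driven cells then
form a risk signature:

```r
cells <- with(driven_pairs(assoc), cell[gene == "G001"])
risk  <- cell_risk_model(cohort$abundance, cells, cohort$survival, gene = "G001")
risk
#> Immune-cell risk signature for G001
#>   cells: cell09, cell05
#>   groups: 100 high / 100 low risk
#>   log-rank chi-square = 85.311, p = 2.55e-20
round(coef(risk), 3)
#> cell09 cell05
#> -0.059  0.955
```

The Cox fit recovers the planted hazard (β ≈ 0.96 for `cell05`, ≈ 0 for the
non-prognostic `cell09`), and the median split separates survival sharply.
`plot(risk, plot_spec("km.pdf"))` draws the Kaplan–Meier curves. For real
cohorts, replace the generator with `read_maf()` / `build_mutation_matrix()`,
`read_expression()` + `read_gmt()` + `ssgsea_score()` (or
`import_abundance()` for xCell/CIBERSORT scores), and `read_survival()`; or
drive everything from files via `run_config()` + `run_all()`.

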