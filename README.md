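# pooltox

Toxicogenomics analysis of **multi-lot pooled-hepatocyte** exposure studies.

When primary human hepatocytes pooled from multiple donors are exposed to a
hepatotoxicant (the motivating design: five lots A–E, each a pool of 5–10
donors, treated with vehicle, a low dose, and a high dose, five replicates
per arm, ~15,000 genes profiled by RNA-seq), the scientific questions are:

1. Which genes respond in each lot, and how consistently across lots?
2. Do *gene sets* — liver injury modules, pathways, published toxicity
   feature sets — show coordinated activation?
3. How reproducible are the answers from lot to lot?

`pooltox` implements that analysis for anyone working with multi-batch
expression studies of toxicant response: per-lot differential expression,
permutation-based gene-set scoring, and a battery of lot-consistency
analytics, plus a synthetic study generator with known ground truth so the
whole pipeline can be validated end to end.

## Methods at a glance

- **Fold change.** Per gene and lot, `FC = mean(log2 expr, treated) −
  mean(log2 expr, control)`.
- **Significance.** Welch's unequal-variance t-test on log2 expression,
  Benjamini–Hochberg FDR; a gene is differentially expressed (DE) when
  `q ≤ 0.1` (boundary inclusive).
- **Gene-set scores.** For a set *S* with measured members *m(S)*:
  - AAFC (aggregated absolute fold change) `= mean over m(S) of |FC|` —
    direction-blind injury-module score;
  - AFC (aggregated fold change) `= mean over m(S) of FC` — signed, for
    pathways.
- **Permutation null.** 10,000 random gene subsets of the same size, drawn
  without replacement from the lot's measured universe; the set's
  `z = (raw − null_mean)/null_sd`, its empirical p-value uses the add-one
  rule `p = (1 + #{null ≥ raw})/(n_perm + 1)`. A module is **activated**
  when `z ≥ 2`.
- **Merged lot.** The unweighted average of per-lot FC (or per-set z) — the
  consensus column in heat maps and correlation plots.
- **Consistency.** DE overlap matrix, genes DE in *every* lot, Pearson
  correlations of FC vectors (all genes vs common genes), cross-lot sample
  SD profiles with threshold fractions, top-k up/down tables, and
  transporter/CYP panel tables with sign-consistency flags.

## Worked example

```r
library(pooltox)

cfg <- synthetic_config(n_genes = 2000, n_core_de = 100,
                        n_lot_specific_de = 150,
                        injected_sets = c(bile_duct_proliferation = 1.0),
                        n_null_sets = 3, set_size = 30, seed = 7)
gen <- generate_study(cfg)
gen$study
#> ExpressionStudy: 2000 genes x 75 samples
#>   lots: A, B, C, D, E
#>   conditions: control, low, high

tabs <- fold_change_tables(gen$study, q_max = 0.1)
sapply(tabs, function(t) sum(t$significant))
#>   A   B   C   D   E
#> 233 227 229 228 249

res <- score_collection(lapply(tabs, function(t) setNames(t$log2_fc, t$gene)),
                        gen$sets, "AAFC", n_perm = 1000, seed = 7)
round(res$z_matrix, 2)
#>                             A     B     C     D     E merged
#> bile_duct_proliferation 12.86 12.24 11.39 10.07 11.15  11.54
#> null_set_01             -1.44 -0.57 -1.27 -0.03 -0.01  -0.66
#> null_set_02             -0.15 -0.22 -0.67 -1.93 -0.41  -0.68
#> null_set_03             -1.07  1.13 -1.93 -0.60 -1.19  -0.73

rep <- consistency_report(tabs)
rep
#> ConsistencyReport over 5 lot(s)
#>   per-lot DE counts: 233, 227, 229, 228, 249
#>   common genes: 54
```

Reading the output: each lot calls ~230 genes DE; the injected
bile-duct-proliferation module is activated in every lot (z ≥ 10, far above
the z ≥ 2 threshold) while the three uninjected sets stay near z = 0; 54
genes are DE in all five lots, and on those common genes the lots correlate
strongly (r ≈ 0.91–0.93 pairwise, 0.97 against the merged consensus).

A full run — DE tables, module/pathway scores, feature-set summaries,
consistency report, manifest — is one call (or the bundled CLI
`inst/exec/pooltox`):

```r
run_pipeline(pipeline_config(seed = 7),
             "expression.tsv", "samples.tsv",
             c(injury_module = "modules.gmt"), out_dir = "results/")
```

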