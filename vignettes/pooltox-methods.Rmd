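---
title: "Methods: multi-lot pooled-hepatocyte toxicogenomics with pooltox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-lot pooled-hepatocyte toxicogenomics with pooltox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Pooled primary human hepatocytes — several donors combined into one culture
lot — are a compromise between single-donor cultures (high inter-individual
variability) and immortalized lines (poor physiological relevance). A
toxicant study on several such lots yields a three-way design: lot ×
treatment condition (vehicle control, low dose, high dose) × replicate.
`pooltox` takes gene × sample log2 expression matrices from such a design
and answers three questions: which genes respond per lot, which *gene sets*
(injury modules, pathways, toxicity feature sets) respond, and how
consistent the answers are across lots.

The package deliberately starts from gene-level log2 expression.
Read-level processing (pseudoalignment, transcript abundance estimation,
bootstrap variance modelling) is upstream of its scope; any quantifier that
produces a genes × samples log2 matrix can feed it.

## Differential expression

Within one lot, the per-gene log2 fold change is the difference of arm
means,

$$\mathrm{FC}_g = \overline{x}_{g,\mathrm{treated}} -
\overline{x}_{g,\mathrm{control}},$$

on log2-transformed expression, so FC is directly interpretable as log2 of
a fold ratio. Significance uses Welch's unequal-variance t-test per gene
with Welch–Satterthwaite degrees of freedom, followed by Benjamini–Hochberg
adjustment; a gene is called DE at `q ≤ 0.1` (inclusive: a gene exactly at
the threshold is called).

Choosing Welch on log2 values as the per-gene test is a design decision:
with five replicates per arm and no access to transcript-level bootstrap
uncertainty, an unequal-variance location test is the simplest defensible
model, it is isolated behind one function (`welch_test()`), and it is
validated against `stats::t.test()` in the test suite. Genes with zero
variance in both arms get p = 1 when the means agree and p = 0 otherwise —
the latter can only arise in degenerate synthetic input, never in noisy
data. The package adopts log2 (not natural log) throughout because fold
changes and panel tables in this field are conventionally displayed on the
log2 scale.

## Gene-set scoring

Two aggregated statistics score a set $S$ against a lot's FC map, using
only the members measured in that lot:

- **AAFC** $= \frac{1}{|m(S)|}\sum_{g \in m(S)} |\mathrm{FC}_g|$,
  direction-blind; used for injury modules, where genes in one
  histopathology module may move in either direction.
- **AFC** $= \frac{1}{|m(S)|}\sum_{g \in m(S)} \mathrm{FC}_g$, signed; used
  for pathways, where net direction is the display of interest.

AAFC ≥ |AFC| always (triangle inequality); the tests quantify this over
random instances.

### Permutation null, z-score, p-value

The null hypothesis is that the set is an arbitrary collection of measured
genes. The null distribution is built by drawing `n_perm` (default 10,000)
random subsets of the same size, uniformly **without replacement from the
same lot's measured universe** — not the union across lots, since each
lot's FC distribution is its own reference — and scoring each with the same
statistic. Then

$$z = \frac{\mathrm{raw} - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}},
\qquad
p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{raw}\}}{n_{\mathrm{perm}} + 1}.$$

Design decisions here:

- The z-score is defined self-consistently from the same permutation null
  as the p-value (rather than any external normalization), which makes the
  activation threshold `z ≥ 2` testable: on null data, set z-scores are
  approximately standard normal, and the test suite checks |mean z| < 0.1
  and SD(z) ∈ [0.9, 1.1] over 500 random sets.
- The empirical p uses the add-one rule so p = 0 is impossible, and counts
  ties as exceedances (`≥`, the conservative reading of "null score greater
  than the observed score").
- A **degenerate null** (all null scores identical, e.g. a constant |FC|
  universe, or the set being the whole universe) yields z = 0 with a
  warning rather than a division by zero.
- Sets with fewer than `min_genes = 3` measured members are reported as NA
  rather than scored: a mean over one or two fold changes is a gene-level,
  not a set-level, statistic.
- For AFC a signed display value `z_signed` is also reported (the
  z-magnitude of |raw| against the |null|, carrying the sign of raw), so
  up- and down-regulated pathways sort symmetrically in heat maps.

A set scored across lots gets a **merged** z: the unweighted mean of the
per-lot z-scores. With one lot the merged column equals that lot.

### Feature-set toxicity scores

Published liver-toxicity feature sets (e.g. predictive toxicogenomics
space, toxicity module genes) are scored per lot as plain mean |FC| over
measured members — no permutation — and summarized across lots by mean and
sample SD. The membership lists are user-supplied GMT inputs; the package
ships none.

### Over-representation analysis

A generic one-sided hypergeometric ORA (`ora_enrichment()`) is provided as
plumbing for annotation-based enrichment: `P(X ≥ overlap)` for each set
against the DE list within the measured universe, BH-adjusted across sets.
Its results depend entirely on the annotation collection supplied; it makes
no attempt to reproduce any specific annotation service's output.

## Lot-consistency analytics

- **Overlap matrix**: pairwise intersection counts of per-lot DE sets,
  diagonal = per-lot counts.
- **Common genes**: the intersection across *all* lots.
- **Merged FC**: per-gene unweighted mean across lots, over the genes
  measured in every lot.
- **Correlations**: Pearson r between per-lot FC vectors plus the merged
  column, computed on the all-gene universe and again restricted to the
  common genes (the two regimes differ sharply in practice: common genes
  correlate much better). The merged column *includes* each lot's own
  contribution; the alternative (leave-one-lot-out merging) was considered
  and rejected to mirror the conventional display, and because with five
  lots the difference is a modest, easily reasoned-about inflation.
- **SD profiles**: per-gene sample SD across lots, summarized as the
  fraction of genes **strictly below** each threshold (default 0.5 and
  1.0) — "below" is read strictly.
- **Cross-lot stats**: mean and **sample SD (n−1)**. The n−1 convention was
  fixed by recomputing published per-lot panel rows: printed SDs reproduce
  under n−1 (e.g. the CYP26B1 row: per-lot −2.98, −5.48, −4.07, −3.10,
  −6.86 → SD 1.66 at 2 dp), not under n. Report tables round half away
  from zero at 2 decimals; raw full-precision values are always written
  alongside.
- **Top-k tables**: k largest / smallest merged FC (default 10), ties
  broken by gene symbol ascending for determinism.
- **Sign consistency**: `consistent_up` iff FC > 0 in every lot,
  `consistent_down` iff FC < 0 in every lot, otherwise `mixed`; an exact
  zero breaks consistency. Panel tables star genes that are consistent in
  every lot yet significant in none — the "weak but reproducible" pattern
  that matters for transporters.

## The synthetic study generator

`generate_study()` emulates the pooled-hepatocyte design so every stage is
testable with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `n_lots` | 5 | hepatocyte lots (A–E) |
| `n_replicates` | 5 | replicates per lot × condition |
| `n_genes` | 15000 | measured genes |
| `baseline_mean`, `baseline_sd` | 6.0, 2.0 | per-gene baseline log2 expression |
| `residual_sd` | 0.25 | replicate noise SD (log2 units) |
| `n_core_de` | 800 | shared core DE genes |
| `effect_mean`, `effect_sd`, `effect_min` | 1.0, 0.5, 0.2 | \|log2 FC\| magnitude distribution, random sign |
| `n_lot_specific_de` | 1500 | DE genes private to each lot |
| `lot_effect_sd` | 0.3 | SD of the N(1, ·) multiplicative per-lot jitter on shared effects |
| `low_dose_factor` | 0.15 | scaling of effects in the low-dose arm |
| `injected_sets` | 3 sets at 1.0 / 0.8 / 0.5 | set-level signal: mean \|effect\| injected into members |

Control replicates are baseline + N(0, residual_sd); high-dose replicates
add the lot's true FC; low-dose replicates add `low_dose_factor ×` that FC.
The true FC of a gene in a lot is (core effect + injected effect) × lot
jitter, plus the lot-specific effect where applicable; genes in no effect
class have true FC exactly zero in every lot. One master seed drives a
derived sub-seed per phase (baselines, DE architecture, sets, per-lot
effects, noise) so partial regeneration is stable and identical seeds give
byte-identical output.

**What the generator emulates**: the design arithmetic (5 × 3 × 5 = 75
samples), a shared core of responding genes visible in every lot,
lot-to-lot heterogeneity (jittered shared effects plus disjoint private DE
genes — which qualitatively reproduces the pattern of modest all-gene
correlations alongside high common-gene correlations), and set-level
signal. **What it does not emulate**: count-level sampling noise and
mean–variance coupling, donor demographics, dose–response viability,
correlated co-expression within modules beyond the injected mean shift, and
annotation structure. Passing tests therefore demonstrate correctness of
the *analytics* under a Gaussian log2 model, not robustness to every
property of real RNA-seq. Residual SD 0.25 and the effect distribution are
the package's own choices of a realistic regime: they put the smallest
simulated effects (|FC| ≈ 0.2) near the detection boundary at n = 5
(standard error of an FC ≈ 0.25·√(2/5) ≈ 0.16), so both easy and hard genes
exist, while typical core effects (|FC| ≈ 1) are comfortably detectable.

With these conditions the per-lot DE call recovers true DE genes with
precision ≈ 0.93 and recall ≈ 0.75–0.81 — most misses sit in the deliberate
near-boundary tail of the effect distribution. The tests assert precision
≥ 0.8 and recall ≥ 0.75 per lot.

## Numerical choices and degenerate inputs

- `q ≤ 0.1`, `z ≥ 2`, and heat-map band `|v| ≤ 0.6` are all boundary
  **inclusive**.
- BH adjustment delegates to `stats::p.adjust(method = "BH")` and is
  verified against an independent brute-force step-up implementation in the
  tests.
- Zero-variance FC vectors in correlations give NA cells, not errors.
- `n_lots = 1` degrades gracefully: consistency analytics that need ≥ 2
  lots are omitted (NULL) rather than faked.
- Gene identifiers are case-sensitive strings, never aliased or mapped;
  TSV (not CSV) is canonical since set descriptions may contain commas.

## Problem sizes in the test and acceptance runs

Simulation-based tests use scaled studies: 2,000 genes, 100 core DE genes,
150 lot-specific genes per lot, sets of 30 genes, 1,000 permutation draws,
and 20 seeds for power estimates — sizes chosen so the full suite runs in
well under a minute while keeping every rate estimate's Monte-Carlo error
far from the asserted bounds. Effect sizes and noise are the generator
defaults throughout; only counts are scaled. The exactly enumerable
permutation cases use universes of ≤ 12 genes where all subsets can be
listed. `scripts/acceptance.R` recomputes the headline quantities at these
same sizes from a fresh seed supplied on the command line.

## Known limitations

- The Gaussian log2 model ignores count overdispersion; on real data a
  count-aware upstream DE method can be substituted by feeding its log2 FCs
  into the scoring and consistency stages directly.
- Permutation nulls treat genes as exchangeable; correlated member genes
  (co-expression) make the null anti-conservative for tightly co-regulated
  sets. The module z should be read as a screening statistic, not a
  calibrated familywise error rate.
- The merged-lot correlation includes each lot in the consensus (see
  above), inflating lot-vs-merged r relative to a leave-one-out convention.
- Published per-lot table rows are reproduced at their printed 2-dp
  precision; rows whose printed summaries are not self-consistent with
  their printed per-lot values (rounding artifacts in the source tables)
  are excluded from assertions.
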