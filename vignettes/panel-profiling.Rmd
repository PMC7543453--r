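---
title: "Methods: profiling a disease gene panel across cell culture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling a disease gene panel across cell culture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelprofiler)
```

## The problem and the model

Disease modeling needs a cell type that endogenously expresses the gene
under study. Given bulk RNA-seq of the same donors across several candidate
cell types, `panelprofiler` classifies each gene of a disease panel by the
cell type with its highest expression, and backs the call up with
pathway-level coverage, similarity to reference expression profiles, and
qPCR validation statistics. This vignette documents the procedures, their
assumptions, and every tunable that matters.

## Normalization and the detection floor

Counts are normalized to RPKM, `count / (libsize/1e6) / (length_bp/1000)`,
where the library size is the column total of the supplied matrix — reads
assigned to genes outside the matrix are unknowable at this stage, so the
matrix total is the operative definition of sequencing depth. TPM
length-normalizes first and then scales each sample to 1e6; columns sum to
a constant, which makes TPM the right unit for cross-dataset rank
comparisons, and within one sample RPKM and TPM differ only by a positive
factor (so argmax calls agree between the two).

The detection floor (default **0.5 RPKM**) zeroes values *strictly below*
the threshold: 0.49 becomes 0, 0.50 survives. Flooring is idempotent and
never increases a value. It applies to RPKM only; TPM is used un-floored by
the similarity stage, since rank correlations should see the full profile.

**Floor stage.** The floor is applied per sample *before* donor averaging
(`floor_stage = "sample"`), and a gene is `NOT_DETECTABLE` only when every
floored per-sample value is zero — i.e. no single sample shows credible
expression. Flooring the donor means instead is available as
`floor_stage = "mean"`; the argmax call is unaffected in practice because
averaging two floored values and flooring an average differ only near the
threshold.

## Classification and summaries

Per gene, the donor-mean profile over cell types is rescaled so its maximum
is 100 %; the gene is assigned to the argmax cell type. Classification is
scale-invariant, so it is insensitive to any per-gene scale ambiguity left
by normalization. Exact ties are broken deterministically by the canonical
cell-type order (PBMC, LB, F, iPSC, CN) and flagged — ties are measure-zero
on real data but must not silently depend on column order.

Summaries count genes per category; percentages are `100 * count /
panel_size`, rounded half-away-from-zero to one decimal (the convention of
the summary tables this output style follows). Genes belonging to several
disease groups count once in the overall summary and once in each group;
per-group percentages use that group's own size. The category counts always
partition the panel.

## Gene-set coverage

For each gene set, the member genes present in the expression matrix are
scanned per cell type for mean expression **strictly greater than 3 RPKM**
(default `min_expr = 3`; at exactly 3.0 a gene is not counted). Counts are
normalized to the reference cell type's covered count (`normalize_to =
"covered"`, reference `CN` by default); `"total"` normalizes to the set's
gene count in the matrix instead, and `term_total` is always reported so
either reading is recoverable. A reference count of zero leaves the
normalized values undefined (`NA`, flagged) rather than infinite.

## Similarity to reference profiles

Bulk samples and reference columns are compared by Spearman's rank
correlation over their shared genes (at least 3 required; no expression
filter — the statistic is already insensitive to monotone transforms, so no
log transform is applied either). Significance per (bulk group, reference)
pair comes from a one-sided (greater) rank-sum test of that pair's ρ values
against the **pooled background of all comparisons** — by default every
entry of the ρ matrix, including the tested group's own (`background =
"all"`); `"others"` excludes them. Results are reported as −log₁₀ p, with p
floored at the smallest positive double so the transform stays finite; raw
p is always reported alongside, and a Benjamini–Hochberg column is optional
(no correction is applied by default).

**Exact vs approximate p.** For test sets of up to 10 values the p-value is
the exact tail probability of the rank-sum statistic over all
`choose(m+n, m)` subsets of the combined midranks, computed by a size × sum
dynamic program (doubled midranks are integers, so the count is exact; ties
are thereby handled as the exact conditional permutation null). Larger test
sets use the normal approximation with the standard tie correction; the two
agree within 0.02 at the crossover sizes. With the default two donors per
cell type the exact path is always taken.

**Ordination.** Classical (Torgerson) MDS double-centers −D²/2 and takes
the top-k eigenpairs (default k = 3); negative eigenvalues — expected when
the dissimilarity is `1 − Spearman ρ`, the default metric — are truncated
with a warning, `euclidean-log1p` being the alternative metric.

## qPCR analysis

ΔCT is the mean of the detected target replicates minus the mean over
housekeeping genes of their replicate-mean CTs (default GAPDH and TBP;
averaging CTs is geometric-mean normalization in expression space).
Not-detected replicates are dropped, never imputed to a max-cycle value; a
(gene, line) with no detected replicate is flagged `nd`. Per gene, the
reference line is the minimum-ΔCT (highest-expressing) line, set to
relative expression 1 exactly; other lines get `2^(−ΔΔCT)`. The
construction is invariant to any constant CT offset per line, which is what
housekeeping normalization is for.

Replicate-level ΔCT values feed a per-gene one-way fixed-effects ANOVA
across cell lines; pairwise comparisons are corrected by Tukey's HSD by
default (the conventional follow-up to a one-way ANOVA when all pairs are
compared), with Holm-adjusted pooled-SD t tests as the alternative. Stars
map adjusted p at 0.05 / 0.01 / 0.001 / 0.0001. The all-flat plate (zero
variance everywhere) reports p = 1 with a warning rather than failing.

## The synthetic-data generator

The generator emulates the targeted study design: a panel profiled in
**5 cell types × 2 donors** of bulk RNA-seq. Counts are negative binomial
with variance μ + αμ² (α = 0 degenerates to Poisson); each gene's planted
winner cell type has `fold_change` times the baseline mean, and
`NOT_DETECTABLE` genes have mean zero. Defaults, chosen once as a realistic
regime for a targeted panel: `fold_change = 10` (the order of cell-type
specificity seen for strongly specific marker genes), `nb_dispersion = 0.1`
(typical biological-replicate overdispersion in bulk RNA-seq),
`base_mean = 50` counts, `library_size = 1e6` per sample over the panel,
per-gene baseline factors log-normal with SD 0.8 on the log2 scale, and
gene lengths log-uniform in 500–10 000 bp so RPKM and TPM differ
nontrivially. The canonical 168-gene fixture (`canonical_fixture()`) plants
the category distribution 50 CN / 41 F / 26 LB / 22 iPSC / 14 PBMC / 15 ND
across disease groups of 65 + 30 + 18 + 55 genes.

Reference profiles are generated from the bulk generative log-means through
a latent Gaussian channel with correlation `rho` (default 0.95); at
`rho = 1` the reference preserves the bulk mean ranks exactly. qPCR plates
follow `CT = base_ct − log2(relative abundance) + N(0, noise_sd)` with flat
housekeeping genes (noise default 0.15 cycles, a typical triplicate SD);
at zero noise, ΔΔCT inverts the model exactly.

What the generator does **not** emulate: donor-specific biology and batch
effects, gene–gene correlation, length biases of library preparation,
ambient contamination of the reference, or amplification-efficiency
differences between qPCR primers. Tests passing on synthetic data therefore
demonstrate the pipeline's correctness and recovery behavior under the
stated generative model, not the biological validity of any particular real
dataset.

## Numerical choices and degenerate inputs

- Gene identity is the trimmed, case-sensitive symbol string; no alias
  resolution beyond the panel's explicit alias column. Aligning identifier
  namespaces (symbol vs Ensembl) is the caller's responsibility.
- Floats serialize at 6 significant digits; a write–read cycle is
  bit-stable after the first serialization.
- Samples with zero total counts, genes missing length entries, duplicate
  ids, unknown disease-group labels, CT ≤ 0 and malformed GMT lines are all
  rejected at the boundary with the offending record named.
- Degenerate rank-sum backgrounds (all values identical) give p = 1 with a
  warning; degenerate ANOVA (zero variance, equal means) likewise.
- Percentage rounding is half-away-from-zero, so printed percentages match
  the usual hand-rounding of ratios.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the canonical 168-gene × 10-sample fixture for end-to-end recovery, 20–100
gene matrices for property checks, 20 seeds for the reference-recovery
sweep, and brute-force enumeration oracles up to `choose(20, 8)` subsets.
These sizes were chosen to exercise every code path with comfortable
margins while keeping the full suite in the seconds range.

## Known limitations

- The argmax call has no uncertainty attached; near-ties between cell
  types are flagged only when exact. A bootstrap over donors would need
  more than two donors per cell type.
- The pooled-background rank-sum test treats ρ entries as exchangeable
  under the null, ignoring their correlation through shared samples and
  genes; its p-values are calibrated for ranking references, not for
  strict error control.
- Coverage treats gene sets as flat lists: no ontology-graph propagation
  and no enrichment statistics.
- The qPCR model assumes perfect doubling per cycle (no Pfaffl efficiency
  correction).
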