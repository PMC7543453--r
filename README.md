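# panelprofiler

Choosing a cell culture model for a genetic disease starts with a simple
question: does the candidate cell type actually express the gene you want to
study? `panelprofiler` answers it systematically for a whole panel of disease
genes profiled across several candidate cell types — e.g. patient-derived
PBMCs and fibroblasts, immortalized lymphoblasts, iPSCs, and iPSC-derived
cortical neurons for motor neuron disorders (hereditary spastic paraplegia,
ALS, SMA). It is aimed at disease modelers who have bulk RNA-seq of the
candidate cell types (plus optional qPCR validation plates and a single-cell
reference) and need a defensible, reproducible call of the best-expressing
model per gene.

## What it computes

**Normalization.** From a gene × sample count matrix with gene lengths,
RPKM = count / (libsize/10⁶) / (length/10³) and TPM (length-normalize first,
then scale each sample to 10⁶, so columns sum to a constant). A detection
floor sets RPKM values strictly below 0.5 to 0 — such genes count as not
expressed in that sample.

**Panel classification.** Per gene: floor per sample, average the donors of
each cell type, rescale so the top cell type is 100 %, and assign the gene
to its argmax cell type — or `NOT_DETECTABLE` when every floored value is
zero. Summaries report counts and percentages per category, overall and
within each disease group (a gene in several groups counts once overall and
once per group).

**Gene-set coverage.** Per gene set and cell type, the number of member
genes with mean expression > 3 RPKM, normalized to a reference cell type's
covered count — a pathway-level view of which model covers a biological
process.

**Reference similarity.** Spearman ρ between every bulk sample and every
reference cell-type profile (TPM, shared genes, midrank ties), then a
one-sided rank-sum test of each (bulk group, reference) cell against the
pooled background of all comparisons, reported as −log₁₀ p (exact
enumeration for small groups). Classical Torgerson MDS provides the sample
ordination.

**qPCR validation.** ΔCT against the mean of two housekeeping genes
(GAPDH, TBP by default), ΔΔCT relative to the lowest-ΔCT (highest
expressing) cell line with relative expression 2^(−ΔΔCT) (reference = 1),
and per-gene one-way ANOVA with Tukey HSD (or Holm) pairwise comparisons.

**Simulation.** A seeded negative binomial generator (variance μ + αμ²)
plants a winning cell type per gene at a configurable fold change and emits
every input the pipeline consumes — counts, sample sheet, panel, GMT
catalog, correlated reference TPM profiles, triplicate qPCR plates — with
ground truth, so the whole pipeline is testable without any external data.

## Worked example

```r
library(panelprofiler)

fx  <- canonical_fixture(seed = 1)       # 168-gene synthetic panel
sim <- simulate_counts(fx$config)        # 5 cell types x 2 donors
res <- run_classification(sim$counts, sim$sheet, fx$panel)
res$summary
#> <classification_summary> panel of 168 genes
#>        category  n  pct
#>            PBMC 14  8.3
#>              LB 26 15.5
#>               F 41 24.4
#>            iPSC 22 13.1
#>              CN 50 29.8
#>  NOT_DETECTABLE 15  8.9
#>   HSP (n = 65): PBMC 3 (4.6%), LB 10 (15.4%), F 19 (29.2%), iPSC 2 (3.1%), CN 26 (40.0%), NOT_DETECTABLE 5 (7.7%)
#>   ...
```

Each row is one candidate model: `n` genes of the panel have their highest
(donor-averaged, floored) expression in that cell type, `pct` is the share
of the 168-gene panel. Here 50 genes (29.8 %) are best expressed in
cortical neurons, 41 (24.4 %) in fibroblasts, and 15 genes (8.9 %) are not
detectable in any model — the simulator planted exactly this distribution
and the pipeline recovers it. The per-disease lines repeat the bookkeeping
within each disease group (e.g. 26 of the 65 HSP genes, 40.0 %, are
CN-highest).

The end-to-end runner chains every stage from a JSON config and writes the
TSV tables plus `summary.json`:

```sh
Rscript inst/scripts/profiler.R simulate --seed 1 --outdir fixtures/
Rscript inst/scripts/profiler.R run --config run.json --outdir results/
```

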