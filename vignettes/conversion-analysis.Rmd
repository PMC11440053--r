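---
title: "Models and methods behind convtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind convtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

convtrace analyses single-nucleus RNA-seq experiments in which human glial
progenitor cells (hGPCs/OPCs) are directly reprogrammed into induced
dopamine neurons by forced expression of three conversion factors (Ascl1,
Lmx1a, Nurr1) plus REST knock-down, while every starting cell is tagged
with a heritable 20-nt viral barcode. This vignette explains each model the
package implements, the tunable parameters and their defaults, and the
design decisions taken where more than one reasonable implementation
exists.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_counts()`, `simulate_transgenes()`,
`simulate_barcode_reads()`, `simulate_conversion()`) produces fully
ground-truthed datasets with the statistical structure the analysis
assumes. It is first-class, tested code, not a fixture: every downstream
claim the test suite makes is evaluated against its known truth.

**Populations.** Five glial subpopulations (`OPC1`–`OPC5`) plus one
neuronal population. Default starting proportions are
0.30/0.20/0.24/0.10/0.16. The cycling population (`OPC3`, 24%) and the
bipotent population (`OPC4`, 10%) carry their literature proportions; the
astrocyte-committed population is commonly reported nearer 6%, but 0.16
closes the simplex against the other four defaults and all proportions are
configurable. The neuronal fraction per timepoint defaults to 0 at day 0,
0.21 one day after induction, rising to 0.76 at day 21; intermediate days
are interpolated monotonically.

**Counts.** Per-gene baseline abundances are log-normal
(`abundance_sdlog = 1`); marker genes are elevated by their configured
fold (4–10, 12–20 markers per population, disjoint between the neuronal
and glial sets); library sizes are log-normal with mean 4,634 UMIs (the
reported median); counts are negative binomial with size `dispersion = 2`.
The negative binomial is the standard overdispersion model for UMI counts;
nothing downstream depends on that choice beyond realistic variance.
Mitochondrial features are present (prefix `MT-`, class `"Mito"`) and pinned
to ~0.4% of counts so that the 1% QC rule removes a realistic small tail
rather than everything or nothing.

**Transgenes.** Integrated copies per cell and factor are Poisson with mean
`moi` (default 1.5, within the experimental 1–2 per vector). Observed UMIs
are a binomial thinning, at `transgene_capture_rate`, of
`copies * transgene_expr_per_copy` molecules, so zero copies never produce
UMIs and capture rate 1 detects every transduced cell. The fraction of
triple-transduced cells converges to $(1-e^{-\mathrm{moi}})^3$. By default
transgene load is independent of conversion outcome, which makes the
generator a null model for the transgene-association analyses; linked
scenarios are constructed explicitly in tests.

**Clones and conversion.** `n_clones` (default 66) multi-cell clones are
planted. Each clone has an origin cluster drawn from the starting
proportions, 1–4 members at day 0 and a geometric post-window size (mean
≈ 6, truncated at 30), giving the long-tailed clone-size distribution such
experiments report, with a handful of large clones. Every post-window
member converts with probability
`conversion_base_rate * cluster_conversion_effect[origin]`; all effects
equal to 1 is the exchangeable null. Every remaining cell carries its own
singleton barcode, so a cell has a clone id exactly when it carries a
barcode. Labels are perturbed *before* counts are drawn, so the emitted
matrix is always consistent with the truth table (which is written to a
separate file no analysis module reads).

**Barcode reads.** R1 is the 16-nt cell barcode plus a 12-nt UMI (10x v3
layout); R2 is an 8-nt random prefix, the 5' flank `GTCGTGA`, the 20-nt
clone barcode, the 3' flank `CTCGAC`, the static 12-nt library ID, and
random sequence to 98 nt. The library ID sits immediately 3' of the flank;
its exact position is not constrained elsewhere, so the extractor simply
reads the 12 nt after the match. A `barcode_capture_rate` fraction of cells
(default 0.6) yields reads; 40% of emitted reads are motif-free decoys.
Substitution errors hit R2 at `seq_error_rate`, default 0.001 — a typical
modern Illumina substitution rate, and consistent with treating the ~60%
detection rate as pure capture rather than read loss. R1 is emitted
error-free because real pipelines consume cell barcodes that the upstream
cell caller has already corrected.

**What the generator does not emulate:** ambient RNA, doublets, batch
effects, UMI collisions, indels in reads, or clone growth dynamics beyond
the two analysis windows. Tests passing on this generator therefore say
nothing about robustness to those artefacts on real data.

## QC, normalization and feature selection

Cells are kept when their detected-gene count lies in the inclusive band
[1,000, 12,000] and their mitochondrial read fraction is at most 1%
(strictly more than 1% is excluded). Transgene features count toward
neither rule, and are likewise excluded from the per-cell totals used for
library-size normalization and from variable-gene selection, so transgene
load cannot distort the embedding — the matrices still carry the transgene
rows, scaled by the same per-cell factor, for the transgene analyses.
Normalization is counts-per-`scale_factor` (default $10^4$) followed by
`log1p`; the target total is a convention, not a fitted quantity.

Variable genes use the vst ranking: a loess trend (span 0.3, degree 2) of
log10 variance on log10 mean, counts standardized by the trend-predicted
standard deviation, clipped at $\sqrt{n}$, and ranked by the variance of
the clipped values, with ties broken by gene identifier so selection is
deterministic. The default of 4,000 genes follows the analysis the package
reimplements; tests use smaller panels.

## Clustering and annotation

Scaled (z-scored, clipped at ±10) variable genes go through PCA (default
25 components, computed from the smaller Gram matrix), a k-nearest-neighbor
graph (default k = 20, the common convention; the exact k is not critical
and is exposed), Jaccard shared-neighbor edge weights pruned below 1/15,
and Louvain community detection at resolution 0.3. The Louvain seed is
fixed and exposed; cluster labels are reported in descending size order so
"1" is always the largest cluster. Batch integration is a deliberate
no-op pass-through here: the generator produces no batch structure, and on
real multi-run data an external integration (e.g. Harmony with its own
settings) would slot in between PCA and the neighbor graph.

Annotation scores every reference marker set with the module score below
and labels each cluster by the arg-max mean score; ties go to the first
listed set and are logged. Differential expression between groups is a
two-sided rank-sum test (normal approximation with tie and continuity
corrections — equivalent to `wilcox.test(exact = FALSE)` — implemented
vectorized in the package and cross-checked against the stats
implementation in tests), with Benjamini–Hochberg adjustment and a 0.05
FDR significance flag.

## Module scores

The score of a gene set in a cell is the mean normalized expression of the
set minus the mean of expression-matched control genes: all genes are
binned into 24 near-equal-occupancy bins by average expression, and each
set gene contributes 100 control draws (with replacement, seeded) from the
non-set genes of its bin. Excluding set genes from the control pool keeps
the score an unbiased contrast in small gene universes; with genome-scale
universes the distinction is negligible. The score is exactly invariant to
adding a constant to all genes of a cell. Defaults (24 bins, 100 controls)
follow the convention of the tool this scheme mirrors.

## Differential cluster abundance

For two conditions A and B the per-cluster statistic is
$\log_2 \frac{\hat p_{B,c}}{\hat p_{A,c}}$ where each cluster×condition
count receives a pseudo-count of 0.5 cells before proportions are formed
(so empty cells are defined and shrunk). The null comes from permuting
condition labels at fixed group sizes; the two-sided p-value uses the
add-one estimator $(1 + \#\{|s^*| \ge |s|\})/(n_{\mathrm{perm}}+1)$, which
can never be exactly zero. Confidence intervals are percentile bootstrap
over cells resampled within each condition, and BH adjustment runs across
clusters. Permutation and bootstrap streams derive from per-stage
sub-seeds, and the bootstrap iterates conditions in sorted level order, so
swapping which condition is called A only negates the statistics and
leaves every p-value unchanged. When a day-0 sample is compared against
the first post-induction week, the post-window timepoints are pooled as a
plain union of cells.

## Transgene analysis

A cell is positive for a factor at ≥1 UMI. The `any` density group is
inclusive of triple-positive cells, but the outcome comparison is between
the disjoint groups "all three factors" and "partial" (one or two), with a
two-sided Fisher exact test on the 2×2 group-by-neuron table (verified
against full hypergeometric enumeration in tests). Additional cassettes in
the feature table (shRNA, rtTA) are counted and reported but never enter
the three-factor logic. Transgene UMI thresholds do not scale with cell
depth; the fixed ≥1 rule is implemented as stated.

## Barcode pipeline

Extraction scans R2 for `GTCGTGA[ACGT]{20}CTCGAC` (first match wins;
optionally one substitution per flank), and records the R1 cell barcode and
UMI, the 20-mer, and the 12 nt after the 3' flank as library ID (empty and
counted when the read is too short). Counts are distinct
(cell, barcode, UMI) molecules, not reads, matching UMI-based axis
conventions. Error correction is directional and cell-local: within each
cell, a barcode merges into a barcode of strictly greater count at edit
distance ≤ 1, candidates processed in descending-count order with
lexicographic tie-break, merged counts adding. A single pass can leave new
merges possible when count ties break, so passes repeat to a fixpoint;
this makes the operation idempotent and equal to a transitive-closure
formulation of the same rule, which the tests assert against a brute-force
union-find oracle. Barcodes in different cells are never compared, and the
total UMI count per cell is conserved.

Cells are then restricted to the whitelist and the QC-retained set, and
each cell is assigned its top-count barcode subject to `min_umi` and an
optional `purity` share; ties leave the cell unassigned with a flag rather
than guessing. Multiply-infected cells are therefore kept by default with
their dominant barcode — the purity knob exists to drop them instead.
Clone identity is the post-correction barcode; the library ID is recorded
for provenance but never used for identity.

## Clonal conversion model

Each qualifying clone (≥1 glial cell at day 0 and ≥1 cell in the D2–D7
window) contributes a row: its day-0 composition over glial clusters (a
point on the simplex) and the fraction of its post-window cells annotated
neuron. The model is weighted least squares without intercept,

$$\mathrm{conversion}_i = \sum_c \beta_c\, x_{ic} + \varepsilon_i,
\qquad \sum_c x_{ic} = 1,$$

with weights equal to the number of post-window cells. Because the
design rows sum to one, each $\beta_c$ is directly the conversion rate of
clones founded in cluster $c$, and the equal-rates null is exactly the
intercept-only model, so the global equality test is the F comparison of
those two fits. A cluster never observed at day 0 yields an `NA`
coefficient with a warning rather than a silently dropped column. A
univariate per-cluster mode (simple weighted regression, reported as the
predicted conversion of a pure clone) is available since the original
description does not say whether the fit was joint; the joint fit is the
default because it is the minimal faithful reading of "cluster as a
continuous variable summing to 1". Per-cluster distributions for the
box-plot view attribute a clone's conversion either to every cluster among
its day-0 cells (default) or only to pure clones; quartiles are type-7
(linear interpolation) and values outside [Q1, Q3] are listed as outliers,
matching the plotted convention.

## Numerical and engineering choices

* One global seed fans out to named sub-streams (`substream_seed`), so
  stage reordering never changes within-stage randomness and the whole
  pipeline is reproducible byte-for-byte (manifest digests are compared in
  tests).
* Permutation exceedance uses a $10^{-12}$ tolerance so ties at the
  observed statistic count as exceeding.
* PCA uses the smaller of the two Gram matrices and a deterministic sign
  convention (largest-magnitude coordinate positive).
* Degenerate inputs fail loudly: empty marker sets, missing transgene
  features, fewer clones than clusters, empty whitelist intersections and
  unpaired FASTQ files are all errors with informative messages.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: 3,000 cells per side for the
abundance null, 3,000 day-0 cells with a ~150-gene panel for the
five-population recovery, 100 planted clones for rate recovery, 5,000
cells for the capture-rate estimate, and a complete end-to-end run at 200
cells per timepoint. The defaults of `sim_config()` describe the study
conditions (cell numbers per timepoint are the one knob tests scale).

## Known limitations

* The directional collapse is a deterministic stand-in for message-passing
  clustering; on pathological count ties the resulting partition is
  rule-defined rather than globally optimal.
* The abundance test treats cells as exchangeable within condition — it is
  not replicate-aware; with biological replicates a mixed-model approach
  would be preferable.
* The clonal regression assumes post-window cells are independent given
  the founding cluster; within-clone correlation is absorbed by the
  weights, not modelled.
* Annotation assumes reference marker sets discriminate the populations;
  overlapping sets degrade to ties, which are logged.
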