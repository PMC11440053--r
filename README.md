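# convtrace

Analysis toolkit for single-nucleus RNA-seq studies of **direct
glia-to-neuron conversion with viral lineage barcodes**. The motivating
experiment reprograms human glial progenitor cells (hGPCs/OPCs) into
induced dopamine neurons by dox-induced expression of three conversion
factors (Ascl1, Lmx1a, Nurr1) plus REST knock-down, while tagging every
starting cell with a heritable random 20-nt barcode so that clones can be
followed from the glial starting state (day 0) through the first week of
conversion. The questions the package answers, per dataset:

* Which glial subpopulations are present, in what proportions, and do
  those proportions shift between conditions or over time?
* Does conversion require co-expression of all three factors?
* Do all glial subtypes convert at similar rates, or is one predisposed?

It is aimed at computational biologists analysing such reprogramming
experiments, and at methodologists who want a fully ground-truthed
simulator for clone-resolved single-cell data.

## What it implements

* **Synthetic-data generator** (`sim_config()`, `simulate_dataset()`):
  negative-binomial counts for five OPC subpopulations plus a growing
  neuronal population, Poisson-MOI transgene copies, clone-structured
  barcode FASTQ reads with the cassette
  `GTCGTGA[ACGT]{20}CTCGAC` + 12-nt library ID, decoys and sequencing
  errors — all with a ground-truth table for validation.
* **QC / clustering** (`qc_filter()`, `normalize_log()`, `select_hvg()`,
  `cluster_cells()`, `annotate_clusters()`, `de_wilcoxon()`,
  `module_score()`, `pseudobulk_trend()`): inclusive 1,000–12,000
  detected-gene band, >1% mito exclusion, log normalization, vst variable
  genes, PCA + SNN + Louvain, marker-based annotation, rank-sum DE with BH
  correction, binned-control module scores.
* **Differential cluster abundance** (`permutation_proportion_test()`):
  per-cluster statistic log2(p̂_B/p̂_A) with a 0.5-cell pseudo-count,
  permutation p-values with the add-one estimator, percentile-bootstrap
  CIs, BH across clusters.
* **Transgene analysis** (`call_tf_positive()`,
  `neuron_fraction_by_group()`, ...): TF-positive at ≥1 UMI; Fisher exact
  comparison of neuron fractions between all-three and partial groups.
* **Barcode pipeline** (`extract_barcodes()`, `correct_barcodes()`,
  `filter_whitelist()`, `assign_clones()`, ...): motif extraction, UMI
  counting, cell-local directional edit-distance-1 collapse, whitelist
  filtering, clone calling, detection rates and clone summaries.
* **Clonal conversion model** (`build_clone_composition()`,
  `fit_conversion_model()`): weighted least squares, without intercept, of
  each clone's neuronal conversion fraction on its day-0 cluster
  composition — coefficients are per-cluster conversion rates
  (`conversion ~ Σ_c β_c x_c`, `Σ_c x_c = 1`) — plus an F-test of rate
  equality. Returns a classed model object with `print`/`summary`/`coef`/
  `confint`/`predict` methods.
* **Orchestration** (`pipeline_config()`, `run_all()`, and a thin CLI at
  `inst/cli/convtrace.R`) with deterministic seed fan-out and a JSON run
  manifest.

## Worked example

Simulate a full experiment (400 cells at each of D0, D2, D3, D5, D7, D14,
D21), run QC, cluster and annotate, test abundance shifts between day 0
and the post-induction pool, and fit the clonal conversion model:

```r
library(convtrace)

cfg <- sim_config(n_cells_per_timepoint = 400, seed = 1)
sim <- simulate_counts(cfg)
sim <- simulate_transgenes(cfg, sim)

qc <- qc_filter(sim$counts, feature_class = sim$feature_class)
print(qc$report)
#> QC report: 2800 cells in, 2712 retained
#>   removed: 79 low-gene, 0 high-gene, 9 high-mito
#>   survivors: median UMI 4547.5 , median genes 1227

fc   <- sim$feature_class[match(rownames(qc$counts), rownames(sim$counts))]
norm <- normalize_log(qc$counts, feature_class = fc)
hvg  <- select_hvg(qc$counts[, colnames(norm)], 500, fc)
cl   <- cluster_cells(norm, hvg, seed = 1)
cl   <- annotate_clusters(norm, cl, default_marker_spec())
#> annotation:
#>        1        2        3        4        5        6
#> "neuron"   "OPC1"   "OPC3"   "OPC2"   "OPC5"   "OPC4"
```

All six simulated populations are recovered. The largest cluster is the
induced-neuron population (cells pooled across timepoints), and the
abundance test shows it is the one strongly differential population
between day 0 and the post-induction window:

```r
meta <- sim$truth[match(colnames(norm), sim$truth$cell), ]
permutation_proportion_test(as.character(cl$cell_type),
                            ifelse(meta$timepoint == "D0", "D0", "post"),
                            a = "D0", b = "post", n_perm = 1000, seed = 1)
#> Permutation test of cluster proportions: B=post vs A=D0 (1000 permutations)
#>  cluster n_a  n_b   prop_a  prop_b  log2fd        p  ci_lo   ci_hi    p_adj
#>   neuron   0 1134 0.001285 0.48712  8.5660 0.000999  8.505  8.6233 0.001499
#>     OPC1 109  309 0.281491 0.13289 -1.0829 0.000999 -1.351 -0.8045 0.001499
#>     ...
```

(The neuron log2 fold-difference is large and positive — the cluster is
essentially absent at D0 — while every glial cluster shrinks as cells
convert.) Finally, the clonal model: with the default null generator all
five glial clusters convert at statistically indistinguishable rates,

```r
ct  <- data.frame(clone_id = meta$clone_id, cell = meta$cell,
                  timepoint = meta$timepoint,
                  cluster = as.character(cl$cell_type))
ct  <- ct[grepl("^clone_", ct$clone_id), ]
fit <- fit_conversion_model(build_clone_composition(ct))
print(fit)
#> Clonal conversion model (joint, 63 clones)
#>        rate     se     lo     hi
#> OPC1 0.5500 0.0607 0.4284 0.6716
#> OPC2 0.4464 0.0726 0.3011 0.5917
#> OPC3 0.5165 0.0569 0.4025 0.6305
#> OPC4 0.4500 0.1215 0.2069 0.6931
#> OPC5 0.5625 0.0607 0.4409 0.6841
#> Equality of rates: F(4, 58) = 0.524, p = 0.7183
```

Each `rate` is the estimated probability that a post-induction cell of a
clone founded in that cluster is a neuron (the generator's base rate here
is 0.5); the F-test does not reject equality, i.e. no glial subpopulation
is preferentially convertible — the expected answer under the null
generator, and the package detects planted deviations from it (see
`tests/testthat/test-clonal.R`).

The same stages are scriptable:

```sh
Rscript inst/cli/convtrace.R simulate --out sim_dir --seed 1
Rscript inst/cli/convtrace.R run-all  --out run_dir --seed 1
```

## Documentation

The methods vignette (`vignettes/conversion-analysis.Rmd`) describes the
generative model, every statistical procedure, parameter defaults with
their rationale, numerical choices and known limitations.
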