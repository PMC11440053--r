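# Generator: determinism, population structure, transgene model, barcode reads

small_cfg <- function(...) {
  sim_config(n_cells_per_timepoint = 150, n_genes = 150, seed = 42, ...)
}

test_that("same configuration and seed reproduce the dataset byte for byte", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_dataset(small_cfg(), d1)
  simulate_dataset(small_cfg(), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cluster fractions, neuron gating and per-timepoint totals follow the config", {
  cfg <- sim_config(n_cells_per_timepoint = 3000, timepoints = "D0",
                    neuron_fraction_by_timepoint = c(D0 = 0),
                    n_genes = 150, n_clones = 0, seed = 7)
  sim <- simulate_counts(cfg)
  expect_false(any(sim$truth$is_neuron))
  expect_equal(nrow(sim$truth), 3000)
  # empirical fractions within the exact binomial 99% CI of the targets
  for (cl in names(cfg$cluster_proportions)) {
    k <- sum(sim$truth$population == cl)
    ci <- binom.test(k, 3000, conf.level = 0.99)$conf.int
    expect_true(ci[1] <= cfg$cluster_proportions[[cl]] &&
                  cfg$cluster_proportions[[cl]] <= ci[2], label = cl)
  }
  # conservation across timepoints on a multi-timepoint run
  sim2 <- simulate_counts(small_cfg())
  expect_true(all(table(sim2$truth$timepoint) == 150))
  # mitochondrial features present and labelled
  expect_true(any(sim2$feature_class == "Mito"))
  expect_true(all(grepl("^MT-", rownames(sim2$counts)[sim2$feature_class == "Mito"])))
})

test_that("marker genes are elevated in their own population", {
  cfg <- sim_config(n_cells_per_timepoint = 800, timepoints = "D0",
                    neuron_fraction_by_timepoint = c(D0 = 0),
                    n_genes = 150, n_clones = 0, seed = 3)
  sim <- simulate_counts(cfg)
  in_cl <- sim$truth$population == "OPC3"
  expect_gt(mean(sim$counts["TOP2A", in_cl]), 2 * mean(sim$counts["TOP2A", !in_cl]))
  expect_gt(mean(sim$counts["VCAN", sim$truth$population == "OPC1"]),
            2 * mean(sim$counts["VCAN", in_cl]))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(cluster_proportions = c(OPC1 = 0.6, OPC2 = 0.5)), "sum to 1")
  expect_error(sim_config(barcode_capture_rate = 1.4), "probabilities")
  expect_error(sim_config(library_id = "ACGT"), "12 nt")
  expect_error(sim_config(barcode_len = 19), "fixed at 20")
  expect_error(sim_config(dispersion = 0), "positive")
})

test_that("transgene copies follow the Poisson MOI model", {
  cfg <- sim_config(n_cells_per_timepoint = 10000, timepoints = "D0",
                    neuron_fraction_by_timepoint = c(D0 = 0), n_genes = 150,
                    n_clones = 0, moi = 1.5, seed = 5)
  sim <- simulate_transgenes(cfg, simulate_counts(cfg))
  copies <- as.matrix(sim$truth[, paste0("copies_", cfg$transgene_names)])
  umis <- as.matrix(sim$counts[cfg$transgene_names, ])
  # copies = 0 implies zero observed UMIs
  expect_true(all(t(umis)[copies == 0] == 0))
  # fraction of triple-transduced cells matches (1 - e^-moi)^3
  k <- sum(rowSums(copies >= 1) == 3)
  ci <- binom.test(k, nrow(copies), conf.level = 0.99)$conf.int
  expect_true(ci[1] <= (1 - exp(-1.5))^3 && (1 - exp(-1.5))^3 <= ci[2])
  # moi = 0: all transgene rows empty
  cfg0 <- small_cfg(moi = 0)
  sim0 <- simulate_transgenes(cfg0, simulate_counts(cfg0))
  expect_equal(sum(sim0$counts[cfg0$transgene_names, ]), 0)
  # capture 1: every cell with at least one copy shows at least one UMI
  cfg1 <- small_cfg(transgene_capture_rate = 1)
  sim1 <- simulate_transgenes(cfg1, simulate_counts(cfg1))
  copies1 <- as.matrix(sim1$truth[, paste0("copies_", cfg1$transgene_names)])
  umis1 <- t(as.matrix(sim1$counts[cfg1$transgene_names, ]))
  expect_true(all(umis1[copies1 >= 1] >= 1))
})

test_that("error-free barcode reads all carry the motif and clones share one 20-mer", {
  cfg <- small_cfg(seq_error_rate = 0, decoy_fraction = 0)
  sim <- simulate_counts(cfg)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  wl <- tempfile()
  simulate_barcode_reads(cfg, sim$truth, r1, r2, wl)
  reads <- read_fastq_pair(r1, r2)
  expect_true(all(grepl("GTCGTGA[ACGT]{20}CTCGAC", reads$seq2)))
  expect_true(all(nchar(reads$seq1) == 28))
  expect_setequal(readLines(wl), sim$truth$cell)
  # every cell of a planted clone carries the identical barcode
  planted <- subset(sim$truth, grepl("^clone_", clone_id))
  expect_gt(nrow(planted), 0)
  per_clone <- tapply(planted$barcode, planted$clone_id, function(b) length(unique(b)))
  expect_true(all(per_clone == 1))
  unlink(c(r1, r2, wl))
})

test_that("the captured-cell fraction matches the configured capture rate", {
  cfg <- sim_config(n_cells_per_timepoint = 5000, timepoints = "D0",
                    neuron_fraction_by_timepoint = c(D0 = 0), n_genes = 150,
                    barcode_capture_rate = 0.6, seed = 11)
  sim <- simulate_counts(cfg)
  r1 <- tempfile(fileext = ".fastq.gz"); r2 <- tempfile(fileext = ".fastq.gz")
  info <- simulate_barcode_reads(cfg, sim$truth, r1, r2)
  k <- length(info$captured_cells)
  ci <- binom.test(k, nrow(sim$truth), conf.level = 0.999)$conf.int
  expect_true(ci[1] <= 0.6 && 0.6 <= ci[2])
  unlink(c(r1, r2))
})

test_that("clonal conversion follows base rate and cluster effects", {
  # base rate 1: every post-window clone member is a neuron
  cfg <- small_cfg(conversion_base_rate = 1)
  tr <- simulate_counts(cfg)$truth
  post <- subset(tr, grepl("^clone_", clone_id) & timepoint %in% cfg$post_timepoints)
  expect_true(all(post$is_neuron))
  # null effects: conversion exchangeable across origin clusters
  cfg0 <- sim_config(n_cells_per_timepoint = 600, n_genes = 150,
                     n_clones = 66, conversion_base_rate = 0.5, seed = 8)
  tr0 <- simulate_counts(cfg0)$truth
  post0 <- subset(tr0, grepl("^clone_", clone_id) & timepoint %in% cfg0$post_timepoints)
  kw <- kruskal.test(split(as.numeric(post0$is_neuron), post0$clone_origin))
  expect_gt(kw$p.value, 0.01)
})
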