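# Barcode extraction, error correction, whitelist filtering, clone calling

write_pair <- function(r1, r2) {
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  convtrace:::write_fastq(sprintf("r%03d", seq_along(r1)), r1, f1)
  convtrace:::write_fastq(sprintf("r%03d", seq_along(r2)), r2, f2)
  c(f1, f2)
}

test_that("a constructed motif read is parsed field by field", {
  cb <- strrep("C", 16); umi <- strrep("G", 12)
  r2 <- paste0("AC", "GTCGTGA", strrep("A", 20), "CTCGAC", strrep("T", 12))
  fq <- write_pair(paste0(cb, umi), r2)
  rec <- extract_barcodes(fq[1], fq[2])
  expect_equal(nrow(rec$records), 1)
  expect_equal(rec$records$cell_barcode, cb)
  expect_equal(rec$records$umi, umi)
  expect_equal(rec$records$viral_barcode, strrep("A", 20))
  expect_equal(rec$records$library_id, strrep("T", 12))
  # a read without the motif is skipped and counted
  fq2 <- write_pair(rep(paste0(cb, umi), 2),
                    c(r2, strrep("A", 60)))
  rec2 <- extract_barcodes(fq2[1], fq2[2])
  expect_equal(nrow(rec2$records), 1)
  expect_equal(rec2$n_skipped, 1)
  # R2 too short for the library ID: record kept, empty id, counted
  fq3 <- write_pair(paste0(cb, umi),
                    paste0("GTCGTGA", strrep("A", 20), "CTCGAC", "TTT"))
  rec3 <- extract_barcodes(fq3[1], fq3[2])
  expect_equal(rec3$records$library_id, "")
  expect_equal(rec3$n_short_library_id, 1)
  # unpaired FASTQ errors with an index
  fq4 <- write_pair(rep(paste0(cb, umi), 3), rep(r2, 3))
  one <- tempfile(fileext = ".fastq")
  convtrace:::write_fastq("r001", r2, one)
  expect_error(extract_barcodes(fq4[1], one), "unpaired")
})

test_that("extraction recovers exactly the motif-bearing simulated reads", {
  cfg <- sim_config(n_cells_per_timepoint = 120, n_genes = 150, seed = 15,
                    seq_error_rate = 0, decoy_fraction = 0.4)
  sim <- simulate_counts(cfg)
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  info <- simulate_barcode_reads(cfg, sim$truth, f1, f2)
  rec <- extract_barcodes(f1, f2)
  expect_equal(nrow(rec$records), info$n_motif)
  expect_equal(rec$n_skipped, info$n_decoy)
  # with zero errors the records match the generator truth exactly
  truth_bc <- sim$truth$barcode[match(rec$records$cell_barcode, sim$truth$cell)]
  expect_identical(rec$records$viral_barcode, truth_bc)
  expect_true(all(rec$records$library_id == cfg$library_id))
  unlink(c(f1, f2))
})

test_that("directional ED-1 collapse merges into the dominant barcode", {
  b1 <- strrep("A", 20)
  b2 <- paste0("C", strrep("A", 19))            # 1 substitution from b1
  mat <- data.frame(cell_barcode = "cellX", viral_barcode = c(b1, b2),
                    umi_count = c(100, 2))
  res <- correct_barcodes(mat)
  expect_equal(nrow(res$matrix), 1)
  expect_equal(res$matrix$viral_barcode, b1)
  expect_equal(res$matrix$umi_count, 102)
  expect_equal(res$log$from, b2)
  # distance 2: untouched
  b3 <- paste0("CC", strrep("A", 18))
  mat2 <- data.frame(cell_barcode = "cellX", viral_barcode = c(b1, b3),
                     umi_count = c(100, 2))
  expect_equal(nrow(correct_barcodes(mat2)$matrix), 2)
  # equal counts never merge
  mat3 <- data.frame(cell_barcode = "cellX", viral_barcode = c(b1, b2),
                     umi_count = c(5, 5))
  expect_equal(nrow(correct_barcodes(mat3)$matrix), 2)
})

test_that("collapse equals the brute-force directional closure on random cells", {
  set.seed(33)
  for (rep in 1:8) {
    # star-structured sets: true barcodes with satellites at edit distance 1
    n_true <- sample(2:6, 1)
    centers <- convtrace:::random_dna(n_true, 20)
    bc <- centers
    cnt <- sample(20:120, n_true)
    for (i in seq_len(n_true)) {
      for (s in seq_len(sample(0:3, 1))) {
        v <- strsplit(centers[i], "")[[1]]
        p <- sample(20, 1)
        v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
        bc <- c(bc, paste(v, collapse = ""))
        cnt <- c(cnt, sample(1:5, 1))
      }
    }
    keep <- !duplicated(bc)
    bc <- bc[keep]; cnt <- cnt[keep]
    mat <- data.frame(cell_barcode = "c1", viral_barcode = bc, umi_count = cnt)
    res <- correct_barcodes(mat)
    # partition: map each input barcode to its surviving representative
    part <- brute_collapse_partition(bc, cnt)
    n_groups_oracle <- length(unique(part))
    expect_equal(nrow(res$matrix), n_groups_oracle)
    # totals conserved
    expect_equal(sum(res$matrix$umi_count), sum(cnt))
    # idempotence
    res2 <- correct_barcodes(res$matrix)
    expect_equal(res2$matrix, res$matrix)
  }
})

test_that("barcodes are never merged across cells", {
  b1 <- strrep("A", 20); b2 <- paste0("C", strrep("A", 19))
  mat <- data.frame(cell_barcode = c("c1", "c2"), viral_barcode = c(b1, b2),
                    umi_count = c(100, 1))
  res <- correct_barcodes(mat)
  expect_equal(nrow(res$matrix), 2)
  expect_equal(nrow(res$log), 0)
})

test_that("whitelist filtering removes exactly the right cells", {
  mat <- data.frame(cell_barcode = c("w1", "w2", "x1", "w1"),
                    viral_barcode = convtrace:::random_dna(4, 20),
                    umi_count = c(3, 1, 9, 2))
  res <- filter_whitelist(mat, c("w1", "w2"))
  expect_equal(res$report$n_removed_whitelist, 1)
  expect_equal(nrow(res$matrix), 3)
  res2 <- filter_whitelist(mat, c("w1", "w2", "x1"), retained_cells = c("w1"))
  expect_equal(res2$report$n_removed_not_retained, 2)
  expect_error(filter_whitelist(mat, "zz"), "survives")
  # whitelist = everything: nothing removed
  res3 <- filter_whitelist(mat, unique(mat$cell_barcode))
  expect_equal(res3$report$n_removed_whitelist, 0)
})

test_that("clone assignment keeps top barcodes and flags ties", {
  bcs <- convtrace:::random_dna(3, 20)
  mat <- data.frame(
    cell_barcode = c("c1", "c2", "c2", "c3", "c3"),
    viral_barcode = c(bcs[1], bcs[1], bcs[2], bcs[2], bcs[3]),
    umi_count = c(4, 5, 2, 3, 3))
  res <- assign_clones(mat)
  a <- res$assignments
  expect_true(a$assigned[a$cell == "c1"])
  expect_equal(a$barcode[a$cell == "c2"], bcs[1])
  expect_false(a$assigned[a$cell == "c3"])
  expect_equal(a$reason[a$cell == "c3"], "tie")
  # purity and min_umi thresholds
  res2 <- assign_clones(mat, min_umi = 5)
  expect_equal(sum(res2$assignments$assigned), 1)
  res3 <- assign_clones(mat, purity = 0.8)
  expect_false(res3$assignments$assigned[res3$assignments$cell == "c2"])
})

test_that("planted clones are recovered from noisy reads", {
  cfg <- sim_config(n_cells_per_timepoint = 350, n_genes = 150, seed = 19,
                    seq_error_rate = 0.005, n_clones = 66,
                    barcode_capture_rate = 0.9)
  sim <- simulate_counts(cfg)
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  wl <- tempfile()
  simulate_barcode_reads(cfg, sim$truth, f1, f2, wl)
  rec <- extract_barcodes(f1, f2)
  corr <- correct_barcodes(count_barcode_umis(rec))
  filt <- filter_whitelist(corr$matrix, wl)
  res <- assign_clones(filt$matrix,
                       data.frame(cell = sim$truth$cell,
                                  timepoint = sim$truth$timepoint,
                                  cluster = sim$truth$population))
  a <- res$assignments[res$assignments$assigned, ]
  truth_bc <- sim$truth$barcode[match(a$cell, sim$truth$cell)]
  expect_gte(mean(a$barcode == truth_bc), 0.95)
  # clone table covers the planted multi-cell clones that were captured
  planted <- unique(sim$truth$barcode[grepl("^clone_", sim$truth$clone_id)])
  sizes <- table(res$clone_table$clone_id)
  expect_gt(sum(names(sizes) %in% planted & sizes >= 2), 40)
  unlink(c(f1, f2, wl))
})

test_that("detection rate and clone summaries report sensibly", {
  all_cells <- sprintf("c%02d", 1:40)
  det <- barcode_detection_rate(all_cells, all_cells)
  expect_equal(det$fraction[det$group == "overall"], 1)
  ann <- stats::setNames(rep(c("OPC1", "neuron"), 20), all_cells)
  det2 <- barcode_detection_rate(all_cells[1:20], all_cells, ann)
  expect_equal(nrow(det2), 3)
  empty <- barcode_detection_rate(character(0), character(0))
  expect_true(is.na(empty$fraction))

  ct <- data.frame(clone_id = c(rep("bc1", 5), "bc2", "bc2"),
                   cell = sprintf("c%02d", 1:7),
                   timepoint = c("D2", "D2", "D3", "D5", "D7", "D0", "D7"),
                   cluster = c(rep("neuron", 5), "OPC1", "neuron"))
  cs <- clone_summary(ct)
  one <- cs$clones[cs$clones$clone_id == "bc1", ]
  expect_equal(one$size, 5)
  expect_equal(one$n_cell_types, 1)
  expect_false(one$before_and_after)
  expect_true(cs$clones$before_and_after[cs$clones$clone_id == "bc2"])
})
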