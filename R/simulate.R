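# Synthetic-data generator. Generation order inside simulate_counts() is
# labels -> clones/conversion -> counts, so the emitted matrix is always
# consistent with the clone-perturbed ground truth. Every stochastic step
# draws from its own sub-seed derived from config$seed (see substream_seed),
# so adding stages never perturbs earlier ones.

# population label skeleton: one row per cell with timepoint, population
# (OPC cluster or "neuron") and a 16-nt cell barcode used as the cell id
simulate_labels <- function(config) {
  set.seed(substream_seed(config$seed, "labels"))
  tps <- config$timepoints
  n <- config$n_cells_per_timepoint
  clusters <- names(config$cluster_proportions)
  rows <- lapply(tps, function(tp) {
    frac <- config$neuron_fraction_by_timepoint[[tp]]
    is_neu <- stats::runif(n) < frac
    origin <- sample(clusters, n, replace = TRUE, prob = config$cluster_proportions)
    data.frame(
      timepoint = tp,
      population = ifelse(is_neu, "neuron", origin),
      origin_cluster = origin,
      is_neuron = is_neu
    )
  })
  truth <- do.call(rbind, rows)
  # distinct 16-nt cell barcodes as cell ids (10x v3 layout)
  repeat {
    cb <- random_dna(nrow(truth), 16L)
    if (!anyDuplicated(cb)) break
  }
  truth <- cbind(cell = cb, truth)
  rownames(truth) <- NULL
  truth
}

#' Assign lineage clones and simulate clonal neuronal conversion
#'
#' Plants `n_clones` multi-cell clones: each clone has an origin glial
#' cluster, one or more member cells at the first timepoint (relabelled to
#' the origin cluster) and one or more members in the post-induction window.
#' Each post-window member converts to a neuron with probability
#' `conversion_base_rate * cluster_conversion_effect[origin]` (capped at 1);
#' with all effects equal to 1 conversion is exchangeable across clusters.
#' Every remaining cell receives a singleton clone (its own barcode), so a
#' cell carries a viral barcode if and only if it has a clone id.
#'
#' @param config A [sim_config()].
#' @param truth A ground-truth data.frame (as produced by
#'   [simulate_counts()], or its internal label skeleton).
#' @return `truth` with `clone_id`, `barcode`, `clone_origin` columns and
#'   updated `population`/`is_neuron` for clone members.
#' @export
simulate_conversion <- function(config, truth) {
  set.seed(substream_seed(config$seed, "clones"))
  clusters <- names(config$cluster_proportions)
  d0 <- config$timepoints[1L]
  eff <- config$cluster_conversion_effect
  truth$clone_id <- NA_character_
  truth$clone_origin <- NA_character_

  d0_pool <- which(truth$timepoint == d0 & !truth$is_neuron)
  post_pool <- which(truth$timepoint %in% config$post_timepoints)
  for (i in seq_len(config$n_clones)) {
    origin <- sample(clusters, 1L, prob = config$cluster_proportions)
    n_d0 <- 1L + min(stats::rgeom(1L, 0.5), 3L)
    n_post <- 1L + min(stats::rgeom(1L, config$clone_geom_p), config$clone_size_max - 1L)
    n_d0 <- min(n_d0, length(d0_pool))
    n_post <- min(n_post, length(post_pool))
    if (n_d0 < 1L || n_post < 1L) break
    id <- sprintf("clone_%03d", i)
    m_d0 <- if (length(d0_pool) == 1L) d0_pool else sample(d0_pool, n_d0)
    m_post <- if (length(post_pool) == 1L) post_pool else sample(post_pool, n_post)
    d0_pool <- setdiff(d0_pool, m_d0)
    post_pool <- setdiff(post_pool, m_post)
    truth$clone_id[m_d0] <- id
    truth$clone_origin[m_d0] <- origin
    truth$population[m_d0] <- origin
    truth$origin_cluster[m_d0] <- origin
    truth$is_neuron[m_d0] <- FALSE
    conv <- stats::runif(n_post) < min(1, config$conversion_base_rate * eff[[origin]])
    truth$clone_id[m_post] <- id
    truth$clone_origin[m_post] <- origin
    truth$origin_cluster[m_post] <- origin
    truth$is_neuron[m_post] <- conv
    truth$population[m_post] <- ifelse(conv, "neuron", origin)
  }
  single <- which(is.na(truth$clone_id))
  truth$clone_id[single] <- sprintf("s_%05d", seq_along(single))
  truth$clone_origin[single] <- truth$origin_cluster[single]
  # one distinct barcode per clone, drawn from a library of ~n_barcodes_library
  ids <- unique(truth$clone_id)
  repeat {
    bc <- random_dna(length(ids), config$barcode_len)
    if (!anyDuplicated(bc)) break
  }
  truth$barcode <- bc[match(truth$clone_id, ids)]
  truth
}

#' Simulate a negative-binomial UMI count matrix with ground truth
#'
#' Emits a features-by-cells sparse count matrix for five glial
#' subpopulations plus a neuronal population whose per-timepoint share is
#' set by the configuration. Marker genes are elevated by their configured
#' fold within their population; mitochondrial features are present and
#' labelled; per-cell library sizes are log-normal and per-gene counts are
#' negative binomial. Output is reproducible byte-for-byte for a fixed
#' seed. Clone structure and clonal conversion are applied to the ground
#' truth before counts are drawn, so matrix and truth always agree.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (dgCMatrix, features x cells),
#'   `feature_class` (`"Gene Expression"` or `"Mito"`), and `truth`
#'   (one row per cell; written separately and never read by the analysis
#'   modules).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  truth <- simulate_labels(config)
  truth <- simulate_conversion(config, truth)

  set.seed(substream_seed(config$seed, "counts"))
  marker_genes <- unique(unlist(lapply(config$marker_spec, names)))
  if (length(marker_genes) > config$n_genes)
    stop_ct("n_genes smaller than the number of marker genes")
  n_fill <- config$n_genes - length(marker_genes)
  genes <- c(marker_genes, sprintf("G%04d", seq_len(n_fill)))
  mito <- sprintf("MT-%02d", seq_len(config$n_mito))
  feats <- c(genes, mito)
  feature_class <- c(rep("Gene Expression", length(genes)), rep("Mito", length(mito)))

  base <- stats::rlnorm(length(feats), meanlog = 0, sdlog = config$abundance_sdlog)
  names(base) <- feats
  # pin the mitochondrial share of the expected library
  endo_sum <- sum(base[genes])
  base[mito] <- base[mito] / sum(base[mito]) * endo_sum *
    config$mito_share / (1 - config$mito_share)

  pops <- c(names(config$cluster_proportions), "neuron")
  profiles <- sapply(pops, function(p) {
    f <- rep(1, length(feats))
    names(f) <- feats
    ms <- config$marker_spec[[p]]
    if (!is.null(ms)) f[names(ms)] <- ms
    a <- base * f
    a / sum(a)
  })

  lib <- stats::rlnorm(nrow(truth),
                       meanlog = log(config$mean_umi_per_cell) - config$umi_sdlog^2 / 2,
                       sdlog = config$umi_sdlog)
  counts <- matrix(0L, nrow = length(feats), ncol = nrow(truth),
                   dimnames = list(feats, truth$cell))
  for (p in pops) {
    idx <- which(truth$population == p)
    if (!length(idx)) next
    mu <- outer(profiles[, p], lib[idx])
    counts[, idx] <- stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  list(counts = counts, feature_class = feature_class, truth = truth)
}

#' Add Poisson-MOI transgene features to a simulated dataset
#'
#' Integrated copies per cell and factor are Poisson with mean `moi`;
#' observed UMIs are a binomial thinning (at `transgene_capture_rate`) of
#' `copies * transgene_expr_per_copy` molecules, so cells with zero copies
#' never show transgene UMIs and, at capture rate 1, every cell with at
#' least one copy does.
#'
#' @param config A [sim_config()].
#' @param sim Result of [simulate_counts()].
#' @return `sim` with transgene rows appended to `counts`, `"Transgene"`
#'   classes appended, and per-factor copy columns added to `truth`.
#' @export
simulate_transgenes <- function(config, sim) {
  set.seed(substream_seed(config$seed, "transgenes"))
  n <- ncol(sim$counts)
  tg <- config$transgene_names
  copies <- matrix(stats::rpois(n * length(tg), config$moi), nrow = length(tg),
                   dimnames = list(tg, colnames(sim$counts)))
  molecules <- copies * config$transgene_expr_per_copy
  umis <- matrix(stats::rbinom(length(molecules), molecules, config$transgene_capture_rate),
                 nrow = nrow(molecules), dimnames = dimnames(molecules))
  sim$counts <- rbind(sim$counts, Matrix::Matrix(umis, sparse = TRUE))
  sim$feature_class <- c(sim$feature_class, rep("Transgene", length(tg)))
  for (i in seq_along(tg)) sim$truth[[paste0("copies_", tg[i])]] <- copies[i, ]
  sim
}

#' Simulate lineage-barcode FASTQ reads and the cell-barcode whitelist
#'
#' R1 carries the 16-nt cell barcode followed by a 12-nt UMI; R2 carries a
#' random prefix, the 5' flank, the clone's 20-nt barcode, the 3' flank,
#' the static 12-nt library ID and random sequence to the configured read
#' length. A `barcode_capture_rate` fraction of cells yields reads;
#' `decoy_fraction` of all reads lack the motif entirely; R2 bases are
#' substituted at `seq_error_rate`.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth with `cell` and `barcode` columns.
#' @param out_fastq_r1,out_fastq_r2 Output FASTQ paths (`.gz` honoured).
#' @param out_whitelist Output path for the cell-barcode whitelist TSV.
#' @return Invisibly, a list with `n_reads`, `n_motif`, `n_decoy` and
#'   `captured_cells`.
#' @export
simulate_barcode_reads <- function(config, truth, out_fastq_r1, out_fastq_r2,
                                   out_whitelist = NULL) {
  set.seed(substream_seed(config$seed, "barcode_reads"))
  captured <- truth$cell[stats::runif(nrow(truth)) < config$barcode_capture_rate]
  cell_bc <- rep(NA_character_, 0); umi <- character(0); r2 <- character(0)
  if (length(captured)) {
    n_umi <- 1L + stats::rpois(length(captured), max(config$mean_barcode_umis - 1, 0))
    cell_of_umi <- rep(captured, n_umi)
    umi_seq <- random_dna(length(cell_of_umi), 12L)
    n_reads <- 1L + stats::rpois(length(cell_of_umi), 0.3)
    cell_bc <- rep(cell_of_umi, n_reads)
    umi <- rep(umi_seq, n_reads)
    vb <- truth$barcode[match(cell_bc, truth$cell)]
    prefix <- random_dna(length(cell_bc), 8L)
    core <- paste0(prefix, config$flank5, vb, config$flank3, config$library_id)
    pad <- config$read_len_r2 - nchar(core)
    r2 <- paste0(core, random_dna(length(core), max(pad[1L], 0L)))
  }
  n_real <- length(r2)
  n_decoy <- if (config$decoy_fraction >= 1) stop_ct("decoy_fraction must be < 1") else
    round(config$decoy_fraction / (1 - config$decoy_fraction) * n_real)
  motif <- paste0(config$flank5, "[ACGT]{", config$barcode_len, "}", config$flank3)
  if (n_decoy > 0L) {
    d2 <- random_dna(n_decoy, config$read_len_r2)
    bad <- grepl(motif, d2)
    while (any(bad)) {
      d2[bad] <- random_dna(sum(bad), config$read_len_r2)
      bad <- grepl(motif, d2)
    }
    cell_bc <- c(cell_bc, sample(truth$cell, n_decoy, replace = TRUE))
    umi <- c(umi, random_dna(n_decoy, 12L))
    r2 <- c(r2, d2)
  }
  n_tot <- length(r2)
  ord <- sample.int(max(n_tot, 1L))[seq_len(n_tot)]
  ids <- sprintf("read_%06d", seq_len(n_tot))
  r2 <- mutate_seqs(r2[ord], config$seq_error_rate)
  r1 <- paste0(cell_bc[ord], umi[ord])
  write_fastq(ids, r1, out_fastq_r1)
  write_fastq(ids, r2, out_fastq_r2)
  if (!is.null(out_whitelist)) writeLines(truth$cell, out_whitelist)
  invisible(list(n_reads = n_tot, n_motif = n_real, n_decoy = n_decoy,
                 captured_cells = captured))
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the full generator (counts, transgenes, clones/conversion, barcode
#' reads) and writes the MTX triplet, per-cell metadata, ground truth,
#' FASTQ pair, whitelist and a JSON echo of the configuration into `dir`.
#' The ground-truth table is a separate file that no analysis module reads.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list with the in-memory `sim` object and all paths.
#' @export
simulate_dataset <- function(config, dir) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  sim <- simulate_transgenes(config, sim)
  paths <- list(
    counts = file.path(dir, "counts"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    r1 = file.path(dir, "barcode_R1.fastq.gz"),
    r2 = file.path(dir, "barcode_R2.fastq.gz"),
    whitelist = file.path(dir, "whitelist.tsv"),
    config = file.path(dir, "config.json")
  )
  write_counts_mtx(sim$counts, paths$counts, sim$feature_class)
  meta <- data.frame(cell = sim$truth$cell, timepoint = sim$truth$timepoint,
                     condition = ifelse(sim$truth$timepoint == config$timepoints[1L],
                                        config$timepoints[1L], "ALNRi"))
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  simulate_barcode_reads(config, sim$truth, paths$r1, paths$r2, paths$whitelist)
  cfg <- unclass(config)
  cfg$marker_spec <- lapply(cfg$marker_spec, as.list)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, paths = paths, config = config))
}
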