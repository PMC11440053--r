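#' Assemble and validate a pipeline configuration
#'
#' @param paths Named list of input/output paths (`counts`, `metadata`,
#'   `fastq_r1`, `fastq_r2`, `whitelist`, `outdir`; any may be NULL when
#'   `simulate` is TRUE because the generator then provides them).
#' @param simulate Run the synthetic generator first (default TRUE when no
#'   counts path is given).
#' @param sim Generator configuration ([sim_config()]).
#' @param qc QC thresholds ([qc_thresholds()]).
#' @param n_hvg,n_pcs,resolution,k_neighbors Clustering parameters.
#' @param marker_sets Reference marker sets for annotation; defaults to
#'   [default_marker_spec()].
#' @param n_perm,n_boot Permutation-test parameters.
#' @param d0_label,post_labels Clonal-analysis windows.
#' @param seed Global seed; each stage derives its own sub-seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), simulate = is.null(paths$counts),
                            sim = sim_config(), qc = qc_thresholds(),
                            n_hvg = 4000L, n_pcs = 25L, resolution = 0.3,
                            k_neighbors = 20L, marker_sets = default_marker_spec(),
                            n_perm = 1000L, n_boot = 1000L,
                            d0_label = "D0", post_labels = c("D2", "D3", "D5", "D7"),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$paths$outdir)) stop_ct("paths$outdir is required")
  if (!cfg$simulate) {
    for (p in c("counts", "metadata", "fastq_r1", "fastq_r2", "whitelist")) {
      if (is.null(cfg$paths[[p]]))
        stop_ct("paths$", p, " is required when simulate = FALSE")
      if (!file.exists(cfg$paths[[p]]) && !dir.exists(cfg$paths[[p]]))
        stop_ct("missing input for stage '", p, "': ", cfg$paths[[p]])
    }
  }
  cfg$sim$seed <- substream_seed(seed, "simulate")
  structure(cfg, class = "pipeline_config")
}

#' Run the full conversion-analysis pipeline
#'
#' Executes (optional) simulation, QC, normalization, HVG selection,
#' clustering and annotation, the cluster-proportion permutation test
#' (pre vs pooled post window), transgene calling and Fisher comparison,
#' the barcode pipeline and the clonal conversion model, writing tabular
#' outputs plus a JSON manifest (seeds, input digests, per-stage row
#' counts) into the output directory. Any stage failure halts with the
#' stage name; partial outputs keep a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("convtrace")),
                   seed = config$seed, stages = list())
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop_ct("stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- list(ok = TRUE)
    out
  }

  paths <- config$paths
  if (config$simulate) {
    simdir <- file.path(outdir, "simulated")
    gen <- stage("simulate", simulate_dataset(config$sim, simdir))
    paths$counts <- gen$paths$counts
    paths$metadata <- gen$paths$metadata
    paths$fastq_r1 <- gen$paths$r1
    paths$fastq_r2 <- gen$paths$r2
    paths$whitelist <- gen$paths$whitelist
  }

  dat <- stage("read", read_counts_mtx(paths$counts))
  meta <- stage("read", read_metadata_tsv(paths$metadata))

  qc <- stage("qc", qc_filter(dat$counts, config$qc, dat$feature_class))
  fc <- dat$feature_class[match(rownames(qc$counts), rownames(dat$counts))]
  res$qc <- qc$report
  manifest$stages$qc$n_retained <- qc$report$n_retained
  jsonlite::write_json(unclass(qc$report), file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  norm <- stage("normalize", normalize_log(qc$counts, feature_class = fc))
  hvg <- stage("hvg", select_hvg(qc$counts[, colnames(norm), drop = FALSE],
                                 n_hvg = config$n_hvg, feature_class = fc))
  # batch-integration hook: identity pass-through (synthetic data has no batch)
  clus <- stage("cluster", cluster_cells(norm, hvg, n_pcs = config$n_pcs,
                                         resolution = config$resolution,
                                         k_neighbors = config$k_neighbors,
                                         seed = substream_seed(config$seed, "louvain")))
  clus <- stage("annotate", annotate_clusters(norm, clus, config$marker_sets,
                                              module_score_params(
                                                seed = substream_seed(config$seed, "score"))))
  res$clusters <- clus
  meta <- meta[match(colnames(norm), meta$cell), ]
  meta$cluster <- as.character(clus$cell_type)
  write_stage_tsv(data.frame(cell = names(clus$cluster),
                             cluster = as.character(clus$cluster),
                             cell_type = as.character(clus$cell_type)),
                  file.path(outdir, "clusters.tsv"), "cluster",
                  clus$params)

  res$proportions <- stage("proportions", {
    in_cmp <- meta$timepoint %in% c(config$d0_label, config$post_labels)
    permutation_proportion_test(
      meta$cluster[in_cmp],
      ifelse(meta$timepoint[in_cmp] == config$d0_label, config$d0_label, "post"),
      a = config$d0_label, b = "post",
      n_perm = config$n_perm, n_boot = config$n_boot,
      seed = substream_seed(config$seed, "proportions"))
  })
  write_stage_tsv(as.data.frame(res$proportions), file.path(outdir, "proportions.tsv"),
                  "proportions", list(n_perm = config$n_perm))

  res$transgenes <- stage("transgenes", {
    calls <- call_tf_positive(qc$counts[, colnames(norm), drop = FALSE],
                              feature_class = fc)
    fisher <- neuron_fraction_by_group(
      calls, stats::setNames(meta$cluster == "neuron", meta$cell))
    list(calls = calls, fisher = fisher)
  })
  write_stage_tsv(res$transgenes$calls, file.path(outdir, "tf_calls.tsv"),
                  "transgenes", list())

  res$barcodes <- stage("barcodes", {
    rec <- extract_barcodes(paths$fastq_r1, paths$fastq_r2)
    mat <- count_barcode_umis(rec)
    corr <- correct_barcodes(mat)
    filt <- filter_whitelist(corr$matrix, paths$whitelist, colnames(norm))
    assign_clones(filt$matrix, meta)
  })
  write_stage_tsv(res$barcodes$clone_table, file.path(outdir, "clone_table.tsv"),
                  "barcodes", list())

  res$clonal <- stage("clonal", {
    comp <- build_clone_composition(res$barcodes$clone_table,
                                    d0_label = config$d0_label,
                                    post_labels = config$post_labels)
    list(composition = comp, fit = fit_conversion_model(comp))
  })
  write_stage_tsv(as.data.frame(res$clonal$composition),
                  file.path(outdir, "clone_composition.tsv"), "clonal", list())

  ins <- paths[setdiff(names(paths)[!vapply(paths, is.null, logical(1))], "outdir")]
  manifest$inputs <- lapply(ins, function(p) {
    f <- if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE) else p
    stats::setNames(as.list(unname(tools::md5sum(f))), basename(f))
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
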