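#' Parameters for binned-control module scoring
#'
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl_per_gene Control genes sampled per set gene (default 100).
#' @param seed Seed for control-gene sampling.
#' @return A validated list of class `module_score_params`.
#' @export
module_score_params <- function(n_bins = 24L, n_ctrl_per_gene = 100L, seed = 1L) {
  if (n_bins < 1L || n_ctrl_per_gene < 1L)
    stop_ct("n_bins and n_ctrl_per_gene must be >= 1")
  structure(list(n_bins = n_bins, n_ctrl_per_gene = n_ctrl_per_gene,
                 seed = as.integer(seed)),
            class = "module_score_params")
}

#' Per-cell gene-module score with expression-matched controls
#'
#' All genes are binned into `n_bins` groups of (near-)equal size by their
#' average expression; for each gene in the set, `n_ctrl_per_gene` control
#' genes are sampled (with replacement, seeded) from the non-set genes of
#' its bin (falling back to the whole bin when the set spans it). The
#' score of a cell is the mean expression of the set genes minus the mean
#' expression of the pooled control draws. Adding a constant to all genes
#' of a cell therefore cancels exactly.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param gene_set Character vector of set genes.
#' @param params A [module_score_params()].
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, params = module_score_params()) {
  if (!length(gene_set)) stop_ct("empty gene set")
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(norm))
  if (!length(present)) stop_ct("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set))
    warn_ct(length(gene_set) - length(present), " set gene(s) absent; using ",
            length(present))
  genes <- rownames(norm)
  avg <- Matrix::rowMeans(norm)
  # deterministic equal-occupancy binning by (average, gene id) rank
  ord <- order(avg, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) / (length(genes) / min(params$n_bins, length(genes))))
  names(bin) <- genes
  set.seed(params$seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- setdiff(genes[bin == bin[[g]]], present)
    if (!length(pool)) pool <- genes[bin == bin[[g]]]  # set spans the whole bin
    pool[sample.int(length(pool), params$n_ctrl_per_gene, replace = TRUE)]
  }))
  w <- table(ctrl)
  ctrl_mean <- as.vector(Matrix::crossprod(norm[names(w), , drop = FALSE],
                                           as.numeric(w))) / sum(w)
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  stats::setNames(set_mean - ctrl_mean, colnames(norm))
}
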