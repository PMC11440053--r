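#' Pseudobulk expression trend across timepoints
#'
#' Mean normalized expression per gene per timepoint, plus a monotonicity
#' report: the Spearman correlation of the per-timepoint means against the
#' timepoint rank. Constant genes get a trend of 0; with a single
#' timepoint the trend is NA.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param metadata data.frame with `cell` and `timepoint` columns.
#' @param genes Genes to profile; unknown genes are listed in a warning and
#'   skipped.
#' @return List with `table` (long data.frame: gene, timepoint, mean) and
#'   `trend` (gene, spearman_rho).
#' @export
pseudobulk_trend <- function(norm, metadata, genes) {
  unknown <- setdiff(genes, rownames(norm))
  if (length(unknown))
    warn_ct("unknown genes skipped: ", paste(unknown, collapse = ", "))
  genes <- setdiff(genes, unknown)
  if (!length(genes)) stop_ct("no known genes to profile")
  meta <- metadata[match(colnames(norm), metadata$cell), ]
  tps <- order_timepoints(meta$timepoint)
  means <- sapply(tps, function(tp)
    Matrix::rowMeans(norm[genes, which(meta$timepoint == tp), drop = FALSE]))
  if (length(genes) == 1L) means <- matrix(means, nrow = 1L,
                                           dimnames = list(genes, tps))
  tab <- data.frame(gene = rep(genes, times = length(tps)),
                    timepoint = rep(tps, each = length(genes)),
                    mean = as.vector(means))
  rho <- apply(means, 1L, function(m) {
    if (length(m) < 2L) return(NA_real_)
    if (stats::sd(m) == 0) return(0)
    stats::cor(m, seq_along(m), method = "spearman")
  })
  list(table = tab, trend = data.frame(gene = genes, spearman_rho = as.vector(rho)))
}
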