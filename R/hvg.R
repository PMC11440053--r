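#' Select highly variable genes by variance-stabilizing ranking
#'
#' Implements the standard vst scheme: a loess trend of log10 variance on
#' log10 mean is fitted across genes on raw counts, counts are standardized
#' by the trend-predicted standard deviation, clipped at `sqrt(n_cells)`,
#' and genes are ranked by the variance of the clipped standardized values.
#' Ties are broken by gene identifier, so the selection is deterministic.
#' Transgene features never enter the ranking.
#'
#' @param counts Features-by-cells raw count matrix.
#' @param n_hvg Number of genes to return (default 4000); clamped with a
#'   warning when fewer genes are available.
#' @param feature_class Optional per-feature class vector.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of selected gene names, most variable first.
#' @export
select_hvg <- function(counts, n_hvg = 4000L, feature_class = NULL,
                       loess_span = 0.3) {
  keep <- endogenous_rows(counts, feature_class)
  m <- counts[keep, , drop = FALSE]
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  v <- Matrix::rowSums(m^2) / (n - 1) - mu^2 * n / (n - 1)
  usable <- v > 0 & mu > 0
  genes <- rownames(m)
  std_var <- stats::setNames(rep(0, nrow(m)), genes)
  if (sum(usable) >= 4L) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = loess_span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    mt <- methods::as(m[usable, , drop = FALSE], "CsparseMatrix")
    mu_u <- mu[usable]
    # variance of clipped standardized values, computed sparse-aware:
    # zeros contribute (0 - mu)/sd (never clipped for non-negative mu)
    z0 <- pmax(pmin(-mu_u / sd_exp, clip), -clip)
    sum_z <- z0 * (n - Matrix::rowSums(mt != 0))
    sum_z2 <- z0^2 * (n - Matrix::rowSums(mt != 0))
    tm <- Matrix::t(mt)  # cells x genes, column access per gene
    p <- tm@p
    xs <- tm@x
    for (j in seq_len(ncol(tm))) {
      if (p[j + 1L] == p[j]) next
      z <- (xs[(p[j] + 1L):p[j + 1L]] - mu_u[j]) / sd_exp[j]
      z <- pmax(pmin(z, clip), -clip)
      sum_z[j] <- sum_z[j] + sum(z)
      sum_z2[j] <- sum_z2[j] + sum(z^2)
    }
    std_var[usable] <- (sum_z2 - sum_z^2 / n) / (n - 1)
  }
  variable <- genes[std_var > 0]  # constant genes are never selected
  if (n_hvg > length(variable)) {
    warn_ct("n_hvg (", n_hvg, ") exceeds available variable genes (",
            length(variable), "); returning all")
    n_hvg <- length(variable)
  }
  ord <- order(-std_var[variable], variable)
  variable[ord][seq_len(n_hvg)]
}
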