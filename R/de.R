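#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided rank-sum test on normalized expression using the
#' normal approximation with tie correction and continuity correction, the
#' log2 fold-change of group mean normalized expression, and
#' Benjamini-Hochberg adjustment across all tested genes. Genes with an
#' adjusted p below `alpha` are flagged significant.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param cells_a,cells_b Cell identifiers (or indices) of the two groups.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param pseudo Pseudo expression added inside the fold-change ratio.
#' @return data.frame (`gene`, `log2fc`, `p`, `p_adj`, `significant`)
#'   ordered by p.
#' @export
de_wilcoxon <- function(norm, cells_a, cells_b, alpha = 0.05, pseudo = 1e-9) {
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) stop_ct("each group needs at least 2 cells")
  p <- vapply(seq_len(nrow(norm)), function(i)
    rank_sum_p(a[i, ], b[i, ]), numeric(1))
  log2fc <- log2((rowMeans(a) + pseudo) / (rowMeans(b) + pseudo))
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(norm), log2fc = log2fc, p = p, p_adj = p_adj,
                    significant = p_adj < alpha, row.names = NULL)
  out[order(out$p, out$gene), ]
}

# two-sided rank-sum p, normal approximation with tie and continuity
# corrections (identical to wilcox.test(exact = FALSE, correct = TRUE))
rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' One-vs-rest marker genes for every cluster
#'
#' Convenience wrapper running [de_wilcoxon()] for each cluster against all
#' remaining cells.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param clusters Per-cell labels (named, or aligned with columns).
#' @param alpha Significance level.
#' @return data.frame of per-cluster marker tables with a `cluster` column.
#' @export
find_markers <- function(norm, clusters, alpha = 0.05) {
  cl <- as.factor(clusters)
  out <- lapply(levels(cl), function(lv) {
    in_cl <- which(cl == lv)
    if (length(in_cl) < 2L || length(in_cl) > ncol(norm) - 2L) return(NULL)
    tab <- de_wilcoxon(norm, in_cl, which(cl != lv), alpha = alpha)
    cbind(cluster = lv, tab)
  })
  do.call(rbind, out)
}
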