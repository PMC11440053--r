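#' QC thresholds
#'
#' Inclusive bounds on detected genes per cell and a strict upper bound on
#' the mitochondrial read fraction: cells with at least `min_genes` but no
#' more than `max_genes` detected genes are kept, and cells with more than
#' `max_mito_fraction` mitochondrial reads are excluded.
#'
#' @param min_genes,max_genes Inclusive bounds on detected genes (defaults
#'   1000 and 12000).
#' @param max_mito_fraction Cells strictly above this mitochondrial
#'   fraction are removed (default 0.01).
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 1000L, max_genes = 12000L,
                          max_mito_fraction = 0.01) {
  if (!(min_genes > 0 && min_genes <= max_genes))
    stop_ct("need 0 < min_genes <= max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop_ct("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

# rows of the matrix used as "genes": everything except transgene cassettes
endogenous_rows <- function(counts, feature_class) {
  if (is.null(feature_class)) rep(TRUE, nrow(counts)) else feature_class != "Transgene"
}

mito_rows <- function(counts, feature_class) {
  if (!is.null(feature_class) && any(feature_class == "Mito")) feature_class == "Mito"
  else grepl("^MT-", rownames(counts), ignore.case = TRUE)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Keeps cells whose detected-gene count lies within the inclusive
#' `[min_genes, max_genes]` band and whose mitochondrial read fraction does
#' not exceed `max_mito_fraction`. Transgene features count toward neither
#' rule. If no mitochondrial features can be identified (by feature class
#' or `MT-` prefix) the mito rule is skipped with a warning and logged in
#' the report.
#'
#' @param counts Features-by-cells count matrix.
#' @param thresholds A [qc_thresholds()].
#' @param feature_class Optional per-feature class vector.
#' @return List with `counts` (filtered) and `report` (per-rule removal
#'   counts, survivor medians, and a placeholder doublet column).
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(), feature_class = NULL) {
  endo <- endogenous_rows(counts, feature_class)
  mito <- mito_rows(counts, feature_class) & endo
  n0 <- ncol(counts)
  if (n0 == 0L) {
    report <- list(n_input = 0L, n_removed_low_genes = 0L, n_removed_high_genes = 0L,
                   n_removed_mito = 0L, n_retained = 0L, mito_rule_applied = any(mito),
                   median_umi = NA_real_, median_genes = NA_real_, n_removed_doublet = NA)
    return(list(counts = counts, report = structure(report, class = "qc_report")))
  }
  detected <- Matrix::colSums(counts[endo, , drop = FALSE] > 0)
  total <- Matrix::colSums(counts[endo, , drop = FALSE])
  low <- detected < thresholds$min_genes
  high <- detected > thresholds$max_genes
  if (any(mito)) {
    mito_frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
    mito_fail <- mito_frac > thresholds$max_mito_fraction
  } else {
    warn_ct("no mitochondrial features found; mito rule skipped")
    mito_fail <- rep(FALSE, n0)
  }
  keep <- !(low | high | mito_fail)
  out <- counts[, keep, drop = FALSE]
  report <- list(
    n_input = n0,
    n_removed_low_genes = sum(low),
    n_removed_high_genes = sum(high),
    n_removed_mito = sum(mito_fail & !low & !high),
    n_retained = sum(keep),
    mito_rule_applied = any(mito),
    median_umi = if (any(keep)) stats::median(total[keep]) else NA_real_,
    median_genes = if (any(keep)) stats::median(detected[keep]) else NA_real_,
    n_removed_doublet = NA  # doublet detection out of scope; placeholder
  )
  list(counts = out, report = structure(report, class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "cells in,", x$n_retained, "retained\n")
  cat("  removed: ", x$n_removed_low_genes, " low-gene, ", x$n_removed_high_genes,
      " high-gene, ", x$n_removed_mito, " high-mito",
      if (!x$mito_rule_applied) " (mito rule skipped)", "\n", sep = "")
  cat("  survivors: median UMI", x$median_umi, ", median genes", x$median_genes, "\n")
  invisible(x)
}

#' Library-size normalization with log1p transform
#'
#' Scales each cell to a common total (`scale_factor`) and applies
#' `log1p`. Transgene features are excluded from the per-cell totals so
#' that transgene load does not distort normalization, but their values are
#' scaled by the same per-cell factor. Cells with zero endogenous counts
#' are removed with a warning.
#'
#' @param counts Features-by-cells count matrix.
#' @param scale_factor Common per-cell total (default 1e4).
#' @param feature_class Optional per-feature class vector.
#' @return Normalized sparse matrix.
#' @export
normalize_log <- function(counts, scale_factor = 1e4, feature_class = NULL) {
  endo <- endogenous_rows(counts, feature_class)
  total <- Matrix::colSums(counts[endo, , drop = FALSE])
  zero <- total == 0
  if (any(zero)) {
    warn_ct("removed ", sum(zero), " cell(s) with zero counts")
    counts <- counts[, !zero, drop = FALSE]
    total <- total[!zero]
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / total)
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}
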