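#' Permutation test for differential cluster abundance
#'
#' For two conditions A and B, the per-cluster statistic is the log2
#' fold-difference of cluster proportions, with a pseudo-count of 0.5 cells
#' added to every cluster-by-condition count before proportions are formed.
#' The null distribution comes from `n_perm` random reassignments of the
#' condition labels at fixed group sizes; the two-sided p-value uses the
#' add-one estimator `p = (1 + #{|stat*| >= |stat|}) / (n_perm + 1)`, so it
#' is never exactly zero. Percentile bootstrap confidence intervals come
#' from resampling cells within each condition, and Benjamini-Hochberg
#' adjustment is applied across clusters.
#'
#' @param cluster_labels Per-cell cluster labels.
#' @param condition_labels Per-cell condition labels (exactly two levels,
#'   each with at least 2 cells).
#' @param a,b Which condition level is A (reference) and B; default: the
#'   two levels in sorted order.
#' @param n_perm Number of permutations (default 1000).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf_level Bootstrap CI level (default 0.95).
#' @param seed Seed; permutation and bootstrap streams are derived
#'   sub-seeds, and the bootstrap resamples conditions in sorted level
#'   order so swapping A/B only negates the statistics.
#' @return Object of class `proportion_test`: data.frame with per-cluster
#'   counts, proportions, observed log2 fold-difference, permutation p,
#'   bootstrap CI and BH-adjusted FDR.
#' @export
permutation_proportion_test <- function(cluster_labels, condition_labels,
                                        a = NULL, b = NULL,
                                        n_perm = 1000L, n_boot = 1000L,
                                        conf_level = 0.95, seed = 1L) {
  cl <- as.character(cluster_labels)
  cond <- as.character(condition_labels)
  if (length(cl) != length(cond)) stop_ct("label vectors differ in length")
  if (anyNA(cl) || anyNA(cond)) stop_ct("every cell needs cluster and condition labels")
  lev <- sort(unique(cond))
  if (length(lev) != 2L)
    stop_ct("exactly two condition levels required (got ", length(lev),
            "); run pairwise comparisons for more")
  if (is.null(a)) a <- lev[1L]
  if (is.null(b)) b <- setdiff(lev, a)
  if (!all(c(a, b) %in% lev) || a == b) stop_ct("a/b must name the two condition levels")
  if (any(table(cond) < 2L)) stop_ct("each condition needs at least 2 cells")

  clusters <- sort(unique(cl))
  cl_f <- factor(cl, levels = clusters)
  stat_fun <- function(cl_vec, cond_vec) {
    na <- table(cl_vec[cond_vec == a]) + 0.5
    nb <- table(cl_vec[cond_vec == b]) + 0.5
    log2((nb / sum(nb)) / (na / sum(na)))
  }
  obs <- stat_fun(cl_f, cond)

  set.seed(substream_seed(seed, "permutation"))
  n <- length(cond)
  exceed <- numeric(length(clusters))
  for (i in seq_len(n_perm)) {
    s <- abs(stat_fun(cl_f, cond[sample.int(n)]))
    exceed <- exceed + (s >= abs(obs) - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)

  set.seed(substream_seed(seed, "bootstrap"))
  idx_by_lev <- lapply(lev, function(l) which(cond == l))
  boot <- matrix(0, nrow = n_boot, ncol = length(clusters))
  for (i in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_lev, function(ix) ix[sample.int(length(ix),
                                                                 replace = TRUE)]))
    boot[i, ] <- stat_fun(cl_f[take], cond[take])  # levels in fixed sorted order
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha))

  n_a <- as.vector(table(cl_f[cond == a]))
  n_b <- as.vector(table(cl_f[cond == b]))
  keep <- n_a + n_b > 0L
  if (any(!keep)) warn_ct("cluster(s) absent in both conditions dropped: ",
                          paste(clusters[!keep], collapse = ", "))
  out <- data.frame(
    cluster = clusters, n_a = n_a, n_b = n_b,
    prop_a = (n_a + 0.5) / sum(n_a + 0.5), prop_b = (n_b + 0.5) / sum(n_b + 0.5),
    log2fd = as.vector(obs), p = p,
    ci_lo = ci[1L, ], ci_hi = ci[2L, ], row.names = NULL
  )[keep, ]
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("proportion_test", "data.frame"),
            a = a, b = b, n_perm = n_perm, n_boot = n_boot, seed = seed)
}

#' @export
print.proportion_test <- function(x, digits = 4, ...) {
  cat("Permutation test of cluster proportions: B=", attr(x, "b"),
      " vs A=", attr(x, "a"), " (", attr(x, "n_perm"), " permutations)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# resample-index bootstrap helper kept internal; labels always follow the
# sorted level order so the permutation/bootstrap streams are independent of
# which level the caller designates as A

#' Cluster abundance per timepoint
#'
#' @param metadata data.frame with `cell`, `cluster` and `timepoint`
#'   columns (cluster may be an annotation).
#' @return Long data.frame (`timepoint`, `cluster`, `n`, `fraction`);
#'   fractions sum to 1 within each timepoint. Empty timepoints are
#'   omitted with a warning.
#' @export
abundance_timecourse <- function(metadata) {
  stopifnot(all(c("cluster", "timepoint") %in% names(metadata)))
  tp <- as.character(metadata$timepoint)
  lv <- order_timepoints(tp)
  if (is.factor(metadata$timepoint)) {
    empty <- setdiff(levels(metadata$timepoint), tp)
    if (length(empty)) warn_ct("empty timepoint(s) omitted: ",
                               paste(empty, collapse = ", "))
  }
  tab <- table(timepoint = factor(tp, levels = lv),
               cluster = as.character(metadata$cluster))
  frac <- prop.table(tab, margin = 1L)
  out <- as.data.frame(tab, responseName = "n")
  out$fraction <- as.data.frame(frac, responseName = "f")$f
  out
}
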