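#' Call transgene-positive cells
#'
#' A cell is positive for a factor if it has at least 1 UMI for that
#' transgene. Cells are grouped as `all_three` (all three conversion
#' factors positive), `any` (at least one but not all three) or `none`.
#' The boolean column `any_tf` is inclusive of `all_three` (as used for
#' density plots); the `group` column is the disjoint partition used for
#' the Fisher comparison. Extra cassettes (e.g. shRNA, rtTA) present in
#' the feature table are counted and reported but excluded from the
#' three-factor logic.
#'
#' @param counts Features-by-cells count matrix (raw UMIs).
#' @param transgene_features Names of all transgene features; default:
#'   rows with feature class `"Transgene"`.
#' @param factors The three conversion-factor features; default: the
#'   transgene features matching ASCL1/LMX1A/NURR1 (case-insensitive), or
#'   the first three transgene features.
#' @param feature_class Optional per-feature class vector.
#' @return data.frame of class `tf_calls`: per cell, UMI counts and
#'   positivity per factor, `any_tf`, `all_three_tf` and `group`.
#' @export
call_tf_positive <- function(counts, transgene_features = NULL, factors = NULL,
                             feature_class = NULL) {
  if (is.null(transgene_features)) {
    if (is.null(feature_class)) stop_ct("designate transgene features or supply feature_class")
    transgene_features <- rownames(counts)[feature_class == "Transgene"]
  }
  missing <- setdiff(transgene_features, rownames(counts))
  if (length(missing))
    stop_ct("designated transgene feature(s) missing: ", paste(missing, collapse = ", "))
  if (!length(transgene_features)) stop_ct("no transgene features designated")
  if (is.null(factors)) {
    hit <- transgene_features[grepl("ASCL1|LMX1A|NURR1|NR4A2", transgene_features,
                                    ignore.case = TRUE)]
    factors <- if (length(hit) == 3L) hit else utils::head(transgene_features, 3L)
  }
  if (length(factors) != 3L || !all(factors %in% transgene_features))
    stop_ct("exactly three factor features among the transgenes are required")
  umi <- t(as.matrix(counts[transgene_features, , drop = FALSE]))
  pos <- umi >= 1L
  n_pos <- rowSums(pos[, factors, drop = FALSE])
  out <- data.frame(cell = colnames(counts), umi, pos = pos, check.names = FALSE)
  names(out) <- c("cell", paste0("umi_", transgene_features),
                  paste0("pos_", transgene_features))
  out$any_tf <- n_pos >= 1L
  out$all_three_tf <- n_pos == 3L
  out$group <- factor(ifelse(n_pos == 3L, "all_three",
                             ifelse(n_pos >= 1L, "any", "none")),
                      levels = c("none", "any", "all_three"))
  structure(out, factors = factors, class = c("tf_calls", "data.frame"))
}

#' Neuron fraction by transgene group with Fisher's exact test
#'
#' Compares the fraction of neurons among cells positive for all three
#' conversion factors against cells with partial transgene expression (one
#' or two factors), using a two-sided Fisher exact test on the 2x2
#' contingency of group by neuron status.
#'
#' @param calls A `tf_calls` table from [call_tf_positive()].
#' @param is_neuron Logical vector (named by cell, or aligned with
#'   `calls$cell`): neuron annotation per called cell.
#' @return List with `table` (2x2 counts), `fractions` (neuron fraction
#'   per group) and `p` (two-sided Fisher p).
#' @export
neuron_fraction_by_group <- function(calls, is_neuron) {
  neu <- if (!is.null(names(is_neuron))) is_neuron[calls$cell] else is_neuron
  if (anyNA(neu)) stop_ct("every called cell needs a neuron annotation")
  all3 <- calls$group == "all_three"
  partial <- calls$group == "any"
  if (!any(all3) || !any(partial)) stop_ct("empty transgene group")
  tab <- rbind(all_three = c(neuron = sum(neu[all3]), other = sum(!neu[all3])),
               partial = c(neuron = sum(neu[partial]), other = sum(!neu[partial])))
  list(table = tab,
       fractions = c(all_three = mean(neu[all3]), partial = mean(neu[partial])),
       p = stats::fisher.test(tab)$p.value)
}

#' Transgene expression by group within the neuronal cluster
#'
#' Restricted to neuronal cells, compares normalized expression of each
#' transgene between the all-three and partial groups with a rank-sum
#' test.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param calls A `tf_calls` table.
#' @param neuron_cells Cell identifiers of the neuronal cluster.
#' @return data.frame per transgene: group medians and rank-sum p (NA with
#'   a warning when a group is empty in the neuronal cluster).
#' @export
transgene_level_by_group <- function(norm, calls, neuron_cells) {
  tg <- attr(calls, "factors") %||% grep("^umi_", names(calls), value = TRUE)
  tg <- sub("^umi_", "", tg)
  in_neu <- calls$cell %in% neuron_cells
  res <- lapply(tg, function(g) {
    a <- calls$cell[in_neu & calls$group == "all_three"]
    b <- calls$cell[in_neu & calls$group == "any"]
    if (length(a) < 2L || length(b) < 2L) {
      warn_ct("transgene group empty or too small in the neuronal cluster for ", g)
      return(data.frame(transgene = g, median_all_three = NA_real_,
                        median_partial = NA_real_, p = NA_real_))
    }
    xa <- as.numeric(norm[g, a]); xb <- as.numeric(norm[g, b])
    data.frame(transgene = g, median_all_three = stats::median(xa),
               median_partial = stats::median(xb), p = rank_sum_p(xa, xb))
  })
  do.call(rbind, res)
}

#' Module-score distributions across transgene groups
#'
#' Compares per-cell module scores (e.g. neuronal maturation) across the
#' disjoint groups none / any (one or two factors) / all_three, with the
#' two ordered rank-sum comparisons none-vs-any and any-vs-all_three.
#'
#' @param scores Named per-cell scores (e.g. from [module_score()]).
#' @param calls A `tf_calls` table.
#' @return List with `medians` (per group) and `comparisons` (data.frame
#'   with the two ordered tests; p is NA with a warning when a group has
#'   fewer than 2 cells).
#' @export
maturation_by_group <- function(scores, calls) {
  s <- if (!is.null(names(scores))) scores[calls$cell] else scores
  groups <- split(s, calls$group)
  med <- vapply(groups, function(v) if (length(v)) stats::median(v) else NA_real_,
                numeric(1))
  cmp <- function(g1, g2) {
    v1 <- groups[[g1]]; v2 <- groups[[g2]]
    if (length(v1) < 2L || length(v2) < 2L) {
      warn_ct("group ", g1, " or ", g2, " has fewer than 2 cells; p is NA")
      return(NA_real_)
    }
    rank_sum_p(v1, v2)
  }
  list(medians = med,
       comparisons = data.frame(
         comparison = c("none_vs_any", "any_vs_all_three"),
         p = c(cmp("none", "any"), cmp("any", "all_three"))))
}
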