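#' Build per-clone composition and conversion rows
#'
#' For each clone with at least one glial cell at the pre-conversion
#' timepoint and at least one cell in the post-induction window, records
#' the clone's composition over glial clusters at the pre timepoint (a
#' vector on the simplex) and the fraction of its post-window cells
#' annotated neuron. Clones lacking either window are excluded and
#' counted.
#'
#' @param clone_table Clone table with `clone_id`, `cell`, `timepoint`,
#'   `cluster` columns (cluster = annotation, `neuron_label` for neurons).
#' @param d0_label Pre-conversion timepoint label (default `"D0"`).
#' @param post_labels Post-window timepoint labels (default D2-D7).
#' @param neuron_label Annotation marking neurons (default `"neuron"`).
#' @return data.frame of class `clone_composition`: one row per qualifying
#'   clone with `comp_<cluster>` columns (summing to 1), `n_d0`, `n_post`,
#'   `conversion_fraction`; the number of excluded clones is attached as
#'   attribute `n_excluded`.
#' @export
build_clone_composition <- function(clone_table, d0_label = "D0",
                                    post_labels = c("D2", "D3", "D5", "D7"),
                                    neuron_label = "neuron") {
  stopifnot(all(c("clone_id", "timepoint", "cluster") %in% names(clone_table)))
  glial <- sort(setdiff(unique(clone_table$cluster[clone_table$timepoint == d0_label &
                                                     clone_table$cluster != neuron_label]),
                        NA))
  per <- split(clone_table, clone_table$clone_id)
  rows <- lapply(per, function(d) {
    d0 <- d[d$timepoint == d0_label & d$cluster != neuron_label, ]
    post <- d[d$timepoint %in% post_labels, ]
    if (!nrow(d0) || !nrow(post)) return(NULL)
    comp <- table(factor(d0$cluster, levels = glial)) / nrow(d0)
    out <- data.frame(clone_id = d$clone_id[1L], n_d0 = nrow(d0), n_post = nrow(post),
                      conversion_fraction = mean(post$cluster == neuron_label))
    for (g in glial) out[[paste0("comp_", g)]] <- as.numeric(comp[[g]])
    out
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop_ct("no clone spans both the pre timepoint and the post window")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  structure(out, class = c("clone_composition", "data.frame"),
            n_excluded = sum(!keep), clusters = glial,
            d0_label = d0_label, post_labels = post_labels)
}

#' Fit cluster-specific clonal conversion rates
#'
#' Weighted least-squares regression, without intercept, of each clone's
#' neuronal conversion fraction on its pre-conversion cluster composition
#' (a vector summing to 1), with weights equal to the number of
#' post-window cells. Because compositions span the simplex, each
#' coefficient is interpretable as the conversion rate of clones founded
#' in that cluster. A global F-type test of coefficient equality compares
#' the fit against the restricted common-rate model (which, on the
#' simplex, is the intercept-only model).
#'
#' @param rows A `clone_composition` table (or data.frame with
#'   `comp_*`, `conversion_fraction`, `n_post` columns).
#' @param method `"joint"` (default) for the multivariate no-intercept
#'   fit, or `"univariate"` for per-cluster weighted simple regressions
#'   (reported as the predicted conversion of a pure clone).
#' @param conf_level Level of the per-coefficient confidence intervals.
#' @return Object of class `conversion_fit` with coefficients, standard
#'   errors, confidence intervals, the equality test, and the underlying
#'   `lm` fit; supports `print`, `summary`, `coef`, `confint`, `predict`
#'   and `residuals`.
#' @export
fit_conversion_model <- function(rows, method = c("joint", "univariate"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  cc <- grep("^comp_", names(rows), value = TRUE)
  clusters <- sub("^comp_", "", cc)
  X <- as.matrix(rows[, cc, drop = FALSE])
  y <- rows$conversion_fraction
  w <- rows$n_post
  if (nrow(X) < length(clusters))
    stop_ct("underdetermined: ", nrow(X), " clones for ", length(clusters),
            " clusters")
  seen <- colSums(X) > 0
  if (any(!seen))
    warn_ct("cluster(s) never observed at the pre timepoint: ",
            paste(clusters[!seen], collapse = ", "), "; coefficient NA")
  coefs <- se <- stats::setNames(rep(NA_real_, length(clusters)), clusters)
  ci <- matrix(NA_real_, length(clusters), 2L,
               dimnames = list(clusters, c("lo", "hi")))
  if (method == "joint") {
    Xs <- X[, seen, drop = FALSE]
    colnames(Xs) <- clusters[seen]
    df <- data.frame(y = y, Xs, check.names = FALSE)
    fit <- stats::lm(y ~ . + 0, data = df, weights = w)
    sm <- summary(fit)$coefficients  # rows follow the column order of Xs
    coefs[clusters[seen]] <- sm[, 1L]
    se[clusters[seen]] <- sm[, 2L]
    cif <- stats::confint(fit, level = conf_level)
    ci[clusters[seen], ] <- cif
    rss_full <- sum(w * stats::residuals(fit)^2)
    fit0 <- stats::lm(y ~ 1, weights = w)
    rss_null <- sum(w * stats::residuals(fit0)^2)
    df1 <- sum(seen) - 1L
    df2 <- nrow(X) - sum(seen)
    Fstat <- if (df1 <= 0 || df2 <= 0) NA_real_
             else if (rss_full < 1e-12)  # perfect fit: 0/0 means no evidence
               (if (rss_null - rss_full < 1e-12) 0 else Inf)
             else ((rss_null - rss_full) / df1) / (rss_full / df2)
    equality <- list(F = Fstat, df1 = df1, df2 = df2,
                     p = if (is.na(Fstat)) NA_real_ else
                       stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  } else {
    fit <- NULL
    for (k in which(seen)) {
      fk <- stats::lm(y ~ X[, k], weights = w)
      cf <- stats::coef(fk)
      vc <- stats::vcov(fk)
      est <- cf[1L] + cf[2L]  # predicted conversion of a pure clone
      s <- sqrt(vc[1L, 1L] + vc[2L, 2L] + 2 * vc[1L, 2L])
      coefs[k] <- est; se[k] <- s
      q <- stats::qt(1 - (1 - conf_level) / 2, df = fk$df.residual)
      ci[k, ] <- c(est - q * s, est + q * s)
    }
    equality <- list(F = NA_real_, df1 = NA, df2 = NA, p = NA_real_)
  }
  structure(list(coefficients = coefs, se = se, ci = ci, equality = equality,
                 n_clones = nrow(X), method = method, fit = fit,
                 conf_level = conf_level),
            class = "conversion_fit")
}

#' @export
print.conversion_fit <- function(x, digits = 4, ...) {
  cat("Clonal conversion model (", x$method, ", ", x$n_clones, " clones)\n",
      sep = "")
  print(round(data.frame(rate = x$coefficients, se = x$se,
                         lo = x$ci[, 1L], hi = x$ci[, 2L]), digits))
  if (!is.na(x$equality$p))
    cat(sprintf("Equality of rates: F(%d, %d) = %.3f, p = %.4g\n",
                x$equality$df1, x$equality$df2, x$equality$F, x$equality$p))
  invisible(x)
}

#' @export
summary.conversion_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nUnderlying weighted least-squares fit:\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @export
coef.conversion_fit <- function(object, ...) object$coefficients

#' @export
confint.conversion_fit <- function(object, ...) object$ci

#' @export
residuals.conversion_fit <- function(object, ...) {
  if (is.null(object$fit)) stop_ct("no joint fit stored")
  stats::residuals(object$fit)
}

#' Predict clonal conversion for new compositions
#'
#' @param object A `conversion_fit`.
#' @param newdata Matrix or data.frame of compositions (columns named by
#'   cluster or `comp_<cluster>`), rows on the simplex.
#' @param ... Unused.
#' @return Predicted conversion fractions.
#' @export
predict.conversion_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  nd <- as.matrix(newdata)
  colnames(nd) <- sub("^comp_", "", colnames(nd))
  nd <- nd[, names(cf)[!is.na(cf)], drop = FALSE]
  as.vector(nd %*% cf[!is.na(cf)])
}

#' Per-cluster clonal conversion distributions with box statistics
#'
#' For each glial cluster, the distribution across clones of the
#' percentage of the clone's post-window cells that converted, attributed
#' to clusters either through every cluster among the clone's
#' pre-conversion cells (`mode = "per_cell"`) or only through clones whose
#' pre-conversion cells sit in a single cluster (`mode = "pure"`).
#' Box statistics use type-7 (linear interpolation) quartiles; values
#' outside `[Q1, Q3]` are reported as outliers.
#'
#' @param clone_table Clone table with `clone_id`, `timepoint`, `cluster`.
#' @param d0_label,post_labels,neuron_label As in
#'   [build_clone_composition()].
#' @param mode Attribution of mixed clones; see above.
#' @return List with `table` (one row per clone-cluster pair:
#'   `conversion_pct`) and `box` (per cluster: median, q1, q3, n,
#'   outliers as a comma-separated string). Clusters without clone
#'   coverage are omitted with a warning.
#' @export
per_cluster_conversion <- function(clone_table, d0_label = "D0",
                                   post_labels = c("D2", "D3", "D5", "D7"),
                                   neuron_label = "neuron",
                                   mode = c("per_cell", "pure")) {
  mode <- match.arg(mode)
  comp <- build_clone_composition(clone_table, d0_label, post_labels, neuron_label)
  clusters <- attr(comp, "clusters")
  rows <- list()
  for (i in seq_len(nrow(comp))) {
    in_clusters <- clusters[sapply(clusters, function(g)
      comp[[paste0("comp_", g)]][i] > 0)]
    if (mode == "pure" && length(in_clusters) != 1L) next
    for (g in in_clusters)
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = comp$clone_id[i], cluster = g,
        conversion_pct = 100 * comp$conversion_fraction[i])
  }
  if (!length(rows)) stop_ct("no clone-cluster pairs under mode ", mode)
  tab <- do.call(rbind, rows)
  box <- do.call(rbind, lapply(split(tab$conversion_pct, tab$cluster), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(median = q[[2L]], q1 = q[[1L]], q3 = q[[3L]], n = length(v),
               outliers = paste(v[v < q[[1L]] | v > q[[3L]]], collapse = ","))
  }))
  box <- cbind(cluster = rownames(box), box)
  rownames(box) <- NULL
  missing <- setdiff(clusters, box$cluster)
  if (length(missing))
    warn_ct("cluster(s) without clone coverage omitted: ",
            paste(missing, collapse = ", "))
  list(table = tab, box = box)
}
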