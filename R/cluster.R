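# PCA via the smaller Gram matrix: for n cells and g genes this costs
# eigen(min(n, g)^2) rather than a full SVD of the scaled matrix
pca_scores <- function(x, n_pcs) {
  n <- nrow(x)
  g <- ncol(x)
  n_pcs <- min(n_pcs, n - 1L, g)
  if (g <= n) {
    e <- eigen(crossprod(x) / (n - 1), symmetric = TRUE)
    v <- e$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- x %*% v
  } else {
    e <- eigen(tcrossprod(x) / (n - 1), symmetric = TRUE)
    scores <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n_pcs)], 0) * (n - 1)), n_pcs)
  }
  # deterministic sign convention: largest-magnitude coordinate positive
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Cluster cells by PCA, shared-nearest-neighbor graph and Louvain
#'
#' Scales the selected highly variable genes (z-score, clipped at 10), runs
#' PCA, builds a k-nearest-neighbor graph in PC space, weights edges by the
#' Jaccard overlap of neighborhoods (pruned below 1/15), and partitions the
#' graph with Louvain community detection at the given resolution. Cluster
#' labels are reported in descending cluster size ("1" is the largest) and
#' are stable for a fixed seed.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param hvg Character vector of genes to use (e.g. from [select_hvg()]).
#' @param n_pcs Number of principal components (default 25).
#' @param resolution Louvain resolution (default 0.3).
#' @param k_neighbors Neighbors per cell in the kNN graph (default 20).
#' @param seed Seed for the Louvain pass.
#' @return Object of class `cluster_result`: list with `cluster` (named
#'   factor), `pca` (cell scores), `annotation` (filled by
#'   [annotate_clusters()]) and `params`.
#' @export
cluster_cells <- function(norm, hvg, n_pcs = 25L, resolution = 0.3,
                          k_neighbors = 20L, seed = 42L) {
  hvg <- intersect(hvg, rownames(norm))
  if (!length(hvg)) stop_ct("none of the requested genes are in the matrix")
  n <- ncol(norm)
  if (n <= k_neighbors)
    stop_ct("need more cells (", n, ") than k_neighbors (", k_neighbors, ")")
  x <- as.matrix(Matrix::t(norm[hvg, , drop = FALSE]))
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > 10] <- 10
  x[x < -10] <- -10
  scores <- pca_scores(x, n_pcs)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- factor(relabel[as.character(memb)], levels = seq_along(sizes))
  names(cl) <- colnames(norm)
  structure(list(cluster = cl, pca = scores, annotation = NULL,
                 params = list(n_pcs = n_pcs, resolution = resolution,
                               k_neighbors = k_neighbors, seed = seed,
                               n_hvg = length(hvg))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$cluster), " cells, ",
      nlevels(x$cluster), " clusters (resolution ",
      x$params$resolution, ")\n", sep = "")
  print(table(cluster = x$cluster))
  if (!is.null(x$annotation)) {
    cat("annotation:\n")
    print(x$annotation)
  }
  invisible(x)
}

#' Annotate clusters by best-matching reference marker set
#'
#' Scores every reference marker set with the binned-control module score
#' and labels each cluster with the set achieving the highest mean score
#' over its cells. Ties are broken by the order the sets are listed and
#' logged via a message.
#'
#' @param norm Normalized features-by-cells matrix.
#' @param clusters A `cluster_result` or a factor/character vector of
#'   per-cell labels (named by cell).
#' @param marker_sets Named list mapping subpopulation name to a character
#'   vector of marker genes (a named numeric vector is accepted; its names
#'   are used).
#' @param params A [module_score_params()].
#' @return Named character vector: cluster label -> subpopulation name. If
#'   `clusters` is a `cluster_result` the updated object is returned
#'   instead, with `annotation` filled and a per-cell `cell_type` vector.
#' @export
annotate_clusters <- function(norm, clusters, marker_sets,
                              params = module_score_params()) {
  if (!length(marker_sets)) stop_ct("empty marker specification")
  res <- if (inherits(clusters, "cluster_result")) clusters else NULL
  cl <- if (!is.null(res)) res$cluster else as.factor(clusters)
  sets <- lapply(marker_sets, function(s) if (is.character(s)) s else names(s))
  missing <- lapply(sets, function(s) setdiff(s, rownames(norm)))
  bad <- lengths(missing) > 0L
  if (any(bad))
    stop_ct("marker genes absent from matrix: ",
            paste(unlist(missing[bad]), collapse = ", "))
  score_mat <- sapply(names(sets), function(nm)
    module_score(norm, sets[[nm]], params = params))
  mean_by_cluster <- apply(score_mat, 2L, function(s) tapply(s, cl, mean))
  if (nlevels(cl) == 1L) mean_by_cluster <- matrix(mean_by_cluster, nrow = 1L,
                                                   dimnames = list(levels(cl), names(sets)))
  ann <- apply(mean_by_cluster, 1L, function(r) {
    best <- which(r == max(r))
    if (length(best) > 1L)
      message("annotation tie for a cluster between ",
              paste(names(sets)[best], collapse = ", "), "; first listed kept")
    names(sets)[best[1L]]
  })
  ann <- stats::setNames(as.character(ann), levels(cl))
  if (!is.null(res)) {
    res$annotation <- ann
    res$cell_type <- stats::setNames(ann[as.character(res$cluster)], names(res$cluster))
    return(res)
  }
  ann
}
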