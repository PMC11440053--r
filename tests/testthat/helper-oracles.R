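# Independent brute-force oracles used across the suite. These stay
# deliberately naive and structurally different from the package code.

# Benjamini-Hochberg from the definition: for each p_i take the minimum of
# n * p_(m) / m over all sorted positions m whose p is >= p_i
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) adj[k] <- min(1, min(n * ps[k:n] / (k:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration over every
# table with the observed margins
brute_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# directional edit-distance collapse by union-find over all pairs with
# strictly different counts (original counts), iterated to closure
brute_collapse_partition <- function(bc, cnt, max_dist = 1) {
  n <- length(bc)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- utils::adist(bc)
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (d[i, j] <= max_dist && cnt[j] > cnt[i] && find(i) != find(j)) {
        parent[find(i)] <- find(j)
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  vapply(seq_len(n), find, integer(1))
}

# adjusted Rand index from a contingency table
ari <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- choose(sum(tab), 2)
  (a - b * cc / n) / ((b + cc) / 2 - b * cc / n)
}

# brute-force module score: explicit loops over set genes and their
# sampled controls, matching the documented sampling scheme
brute_module_score <- function(norm, gene_set, n_bins, n_ctrl, seed) {
  genes <- rownames(norm)
  avg <- Matrix::rowMeans(norm)
  ord <- order(avg, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) / (length(genes) / min(n_bins, length(genes))))
  names(bin) <- genes
  set.seed(seed)
  ctrl <- character(0)
  for (g in gene_set) {
    pool <- setdiff(genes[bin == bin[[g]]], gene_set)
    if (!length(pool)) pool <- genes[bin == bin[[g]]]
    ctrl <- c(ctrl, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
  }
  dn <- as.matrix(norm)
  set_mean <- colMeans(dn[gene_set, , drop = FALSE])
  ctrl_mean <- colMeans(dn[ctrl, , drop = FALSE])  # rows repeat with multiplicity
  set_mean - ctrl_mean
}

# small labelled sparse matrix from a dense definition
as_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
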