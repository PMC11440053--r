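# Clone composition, conversion-rate regression, per-cluster distributions

toy_clone_table <- function() {
  data.frame(
    clone_id = c(rep("bcA", 7), rep("bcB", 3), rep("bcC", 2)),
    cell = sprintf("c%02d", 1:12),
    timepoint = c("D0", rep(c("D2", "D3", "D5", "D7", "D2", "D3"), 1), # bcA: 1 D0 + 6 post
                  "D0", "D2", "D2",                                    # bcB
                  "D2", "D7"),                                         # bcC: no D0
    cluster = c("OPC1", "neuron", "neuron", "neuron", "OPC1", "OPC1", "OPC1",
                "OPC2", "neuron", "OPC2",
                "neuron", "neuron"))
}

test_that("clone composition rows respect windows and the simplex", {
  comp <- build_clone_composition(toy_clone_table())
  expect_equal(nrow(comp), 2)               # bcC has no D0 cell
  expect_equal(attr(comp, "n_excluded"), 1)
  a <- comp[comp$clone_id == "bcA", ]
  expect_equal(a$conversion_fraction, 0.5)  # 3 of 6 post cells are neurons
  expect_equal(a$comp_OPC1, 1)
  cc <- grep("^comp_", names(comp))
  expect_true(all(abs(rowSums(comp[, cc]) - 1) < 1e-9))
  expect_error(build_clone_composition(toy_clone_table()[11:12, ]), "no clone")
})

test_that("pure clones with uniform conversion give equal coefficients", {
  rows <- data.frame(clone_id = sprintf("k%02d", 1:15),
                     n_d0 = 1, n_post = 4, conversion_fraction = 0.5)
  for (g in c("OPC1", "OPC2", "OPC3")) rows[[paste0("comp_", g)]] <- 0
  for (i in seq_len(15)) rows[[paste0("comp_", c("OPC1", "OPC2", "OPC3")[i %% 3 + 1])]][i] <- 1
  fit <- suppressWarnings(fit_conversion_model(rows))  # lm flags the perfect fit
  expect_equal(unname(coef(fit)), rep(0.5, 3), tolerance = 1e-12)
  expect_true(is.na(fit$equality$p) || fit$equality$p > 0.99)
  expect_error(fit_conversion_model(rows[1:2, ]), "underdetermined")
})

test_that("planted cluster-specific rates are recovered within 0.1", {
  cfg <- sim_config(n_cells_per_timepoint = 1500, n_genes = 150, seed = 27,
                    n_clones = 100, conversion_base_rate = 0.2,
                    cluster_conversion_effect = c(OPC1 = 4, OPC2 = 1, OPC3 = 1,
                                                  OPC4 = 1, OPC5 = 1))
  tr <- simulate_counts(cfg)$truth
  ct <- data.frame(clone_id = tr$clone_id, cell = tr$cell,
                   timepoint = tr$timepoint, cluster = tr$population)
  ct <- ct[grepl("^clone_", ct$clone_id), ]
  comp <- build_clone_composition(ct)
  fit <- fit_conversion_model(comp)
  expected <- c(OPC1 = 0.8, OPC2 = 0.2, OPC3 = 0.2, OPC4 = 0.2, OPC5 = 0.2)
  est <- coef(fit)[names(expected)]
  expect_true(all(abs(est - expected) <= 0.1, na.rm = TRUE))
  # the elevated cluster is detected: equality rejected, OPC1 on top
  expect_lt(fit$equality$p, 0.05)
  expect_equal(names(which.max(est)), "OPC1")
})

test_that("a cluster never seen at D0 yields an NA coefficient with warning", {
  rows <- data.frame(clone_id = c("a", "b", "c", "d"), n_d0 = 1, n_post = 3,
                     conversion_fraction = c(0.2, 0.4, 0.3, 0.5),
                     comp_OPC1 = c(1, 0, 1, 0.5), comp_OPC2 = c(0, 1, 0, 0.5),
                     comp_OPC3 = 0)
  expect_warning(fit <- fit_conversion_model(rows), "OPC3")
  expect_true(is.na(coef(fit)["OPC3"]))
  expect_false(anyNA(coef(fit)[c("OPC1", "OPC2")]))
  # prediction works on the remaining clusters
  nd <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("OPC1", "OPC2")))
  expect_equal(length(predict(fit, nd)), 2)
})

test_that("per-cluster conversion box statistics match a quantile oracle", {
  ct <- data.frame(
    clone_id = rep(c("p1", "p2", "p3"), each = 4),
    cell = sprintf("c%02d", 1:12),
    timepoint = rep(c("D0", "D2", "D2", "D2"), 3),
    cluster = c("OPC1", "OPC1", "OPC1", "OPC1",      # 0% conversion
                "OPC2", "neuron", "OPC2", "neuron",  # 50%  (wait: 2 of 3 post)
                "OPC3", "neuron", "neuron", "neuron"))
  ct$cluster[6:8] <- c("neuron", "OPC2", "OPC2")     # p2: 1 of 3 post converted
  res <- per_cluster_conversion(ct)
  expect_equal(res$box$median[res$box$cluster == "OPC1"], 0)
  expect_equal(res$box$median[res$box$cluster == "OPC3"], 100)
  expect_equal(res$box$median[res$box$cluster == "OPC2"], 100 / 3, tolerance = 1e-9)
  # quartiles follow type-7 interpolation: verify against a manual oracle
  set.seed(44)
  v <- runif(11) * 100
  ct2 <- do.call(rbind, lapply(seq_along(v), function(i) {
    n_post <- 100
    n_neu <- round(v[i])
    data.frame(clone_id = sprintf("q%02d", i),
               cell = sprintf("q%02d_%03d", i, 0:n_post),
               timepoint = c("D0", rep("D2", n_post)),
               cluster = c("OPC1", rep("neuron", n_neu), rep("OPC1", n_post - n_neu)))
  }))
  res2 <- per_cluster_conversion(ct2)
  x <- sort(res2$table$conversion_pct)
  manual_q <- function(p) { h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)]) }
  expect_equal(res2$box$q1, manual_q(0.25), tolerance = 1e-9)
  expect_equal(res2$box$median, manual_q(0.5), tolerance = 1e-9)
  expect_equal(res2$box$q3, manual_q(0.75), tolerance = 1e-9)
  # pure mode drops mixed clones
  ct3 <- rbind(ct, data.frame(clone_id = "mix", cell = c("m1", "m2", "m3"),
                              timepoint = c("D0", "D0", "D2"),
                              cluster = c("OPC1", "OPC2", "neuron")))
  pure <- per_cluster_conversion(ct3, mode = "pure")
  expect_false("mix" %in% pure$table$clone_id)
})

test_that("null clones show no cluster effect in conversion distributions", {
  cfg <- sim_config(n_cells_per_timepoint = 800, n_genes = 150, seed = 51,
                    n_clones = 80, conversion_base_rate = 0.5)
  tr <- simulate_counts(cfg)$truth
  ct <- data.frame(clone_id = tr$clone_id, cell = tr$cell,
                   timepoint = tr$timepoint, cluster = tr$population)
  ct <- ct[grepl("^clone_", ct$clone_id), ]
  res <- suppressWarnings(per_cluster_conversion(ct, mode = "pure"))
  kw <- kruskal.test(split(res$table$conversion_pct, res$table$cluster))
  expect_gt(kw$p.value, 0.01)
})
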