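test_that("technical replicates collapse to their arithmetic mean", {
  d <- tiny_design(n_bio = 2, n_tech = 2)
  m <- tiny_matrix(rep(c(4, 6), 4), "f1", d$sample_id)
  cc <- collapse_technical_replicates(m, d)
  expect_true(all(cc$matrix$values == 5))
  expect_equal(ncol(cc$matrix$values), 4)

  # identical technical replicates: collapsed column equals either
  m2 <- tiny_matrix(rep(c(3, 3), 4), "f1", d$sample_id)
  expect_true(all(collapse_technical_replicates(m2, d)$matrix$values == 3))

  # full default design: 24 -> 12 columns
  e <- simulate_experiment(sim_config(n_mirna = 3, n_mrna = 3, n_edges = 0,
                                      n_de_mirna = 0, n_de_mrna = 0), 1)
  cc24 <- collapse_technical_replicates(e$mirna, e$design)
  expect_equal(ncol(cc24$matrix$values), 12)
  expect_equal(nrow(cc24$design), 12)
})

test_that("features identical across conditions get log2fc 0, fc 1, p 1", {
  d <- tiny_design(n_bio = 3, n_tech = 1)
  ctl <- matrix(rnorm(15), 5, 3)
  vals <- cbind(ctl, ctl)  # treated duplicates control
  colnames(vals) <- d$sample_id[order(d$condition)]
  rownames(vals) <- paste0("f", 1:5)
  m <- expression_matrix(vals[, d$sample_id], "mRNA")
  de <- differential_expression(m, d)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$fc == 1))
  expect_true(all(de$p == 1))
  expect_true(all(de$fdr >= de$p))
  expect_false(any(de$significant))
})

test_that("differential expression controls the null and detects planted shifts", {
  cfg_null <- sim_config(n_mirna = 2, n_mrna = 200, cell_lines = "HN1957",
                         n_de_mirna = 0, n_de_mrna = 0, n_edges = 0)
  cfg_alt <- sim_config(n_mirna = 2, n_mrna = 100, cell_lines = "HN1957",
                        n_de_mirna = 0, n_de_mrna = 10, n_edges = 0,
                        de_shift = 2.0, bio_sd = 0.25, tech_sd = 0.1)
  null_frac <- numeric(50); recall <- numeric(50); pooled_p <- list()
  for (s in 1:50) {
    e <- simulate_experiment(cfg_null, s)
    cc <- collapse_technical_replicates(e$mrna, e$design)
    de <- differential_expression(cc$matrix, cc$design)
    null_frac[s] <- mean(de$significant)
    pooled_p[[s]] <- de$p

    e2 <- simulate_experiment(cfg_alt, s)
    cc2 <- collapse_technical_replicates(e2$mrna, e2$design)
    de2 <- differential_expression(cc2$matrix, cc2$design)
    truth_mr <- intersect(e2$truth$de_features$feature_id, e2$truth$gene_ids)
    recall[s] <- mean(truth_mr %in% de2$feature_id[de2$significant])
  }
  expect_lte(mean(null_frac), 0.05)
  expect_gte(mean(recall), 0.95)
  # null p-values approximately uniform
  ks <- suppressWarnings(stats::ks.test(unlist(pooled_p), "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the printed examples and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.08 / 3, 0.8), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is permutation-invariant and order-preserving", {
  set.seed(3)
  p <- runif(30)
  adj <- bh_adjust(p)
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("top-k selection ranks by variance or p with lexicographic ties", {
  d <- tiny_design(n_bio = 2, n_tech = 1)
  vals <- rbind(c(0, 0, 0, 10), c(0, 0, 0, 5), c(0, 0, 0, 20),
                c(1, 1, 1, 1), c(2, 2, 2, 2))
  m <- tiny_matrix(as.vector(t(vals)), paste0("f", 1:5), d$sample_id, "mRNA")
  expect_equal(top_k_features(m, k = 3, by = "variance"), c("f3", "f1", "f2"))
  expect_equal(top_k_features(m, k = 5, by = "variance"),
               c("f3", "f1", "f2", "f4", "f5"))  # f4/f5 tie broken by id
  de <- data.frame(feature_id = paste0("f", 1:5), p = c(0.5, 0.01, 0.2, 0.01, 1))
  expect_equal(top_k_features(m, de, 2, by = "p_value"), c("f2", "f4"))
  expect_error(top_k_features(m, k = 0, by = "variance"), "positive")
  expect_error(top_k_features(m, k = 9, by = "variance"), "exceeds")
})

test_that("Fisher's exact p matches exact enumeration and is symmetric", {
  tabs <- list(matrix(c(5, 1, 1, 5), 2), matrix(c(6, 0, 1, 5), 2),
               matrix(c(6, 0, 2, 4), 2), matrix(c(3, 3, 3, 3), 2),
               matrix(c(8, 2, 1, 9), 2))
  for (tab in tabs) {
    p <- fisher_exact_p(tab)
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-9)
    expect_equal(fisher_exact_p(tab[2:1, ]), p)
    expect_equal(fisher_exact_p(tab[, 2:1]), p)
    expect_equal(fisher_exact_p(t(tab)), p)
    expect_true(p > 0 && p <= 1)
  }
  expect_equal(fisher_exact_p(matrix(c(3, 3, 3, 3), 2)), 1)
})

test_that("clustering recovers well-separated groups with the minimal Fisher p", {
  d <- tiny_design(n_bio = 3, n_tech = 2)
  set.seed(9)
  base <- matrix(rnorm(20 * 12, sd = 0.1), 20, 12,
                 dimnames = list(paste0("f", 1:20), d$sample_id))
  trt <- d$condition == "treated"
  base[1:10, trt] <- base[1:10, trt] + 4
  base[11:20, !trt] <- base[11:20, !trt] + 4
  m <- expression_matrix(base, "mRNA")
  res <- cluster_and_associate(m, d, label = "condition")
  expect_equal(res$fisher_p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_true(all(table(res$clusters, d$condition[match(names(res$clusters),
                                                        d$sample_id)]) %in% c(0, 6)))
})

test_that("clustering errors on a constant sample profile, naming it", {
  d <- tiny_design(n_bio = 2, n_tech = 1)
  vals <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("f", 1:3), d$sample_id))
  vals[, 2] <- 7
  m <- expression_matrix(vals, "mRNA")
  expect_error(cluster_and_associate(m, d), d$sample_id[2], fixed = TRUE)
})

test_that("feature overlap is exact set intersection", {
  expect_equal(feature_overlap(c("a", "b"), c("c", "d"))$count, 0)
  expect_equal(feature_overlap(c("a", "b"), c("a", "b", "c"))$count, 2)
  ov <- feature_overlap(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(ov$intersection, c("y", "z"))
  expect_equal(ov$count, 2)
})

test_that("moderated DE agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  e <- simulate_experiment(sim_config(n_mirna = 2, n_mrna = 300,
                                      cell_lines = "HN1957",
                                      n_de_mirna = 0, n_de_mrna = 20,
                                      n_edges = 0), 31)
  cc <- collapse_technical_replicates(e$mrna, e$design)
  de <- differential_expression(cc$matrix, cc$design)
  grp <- cc$design$condition[match(colnames(cc$matrix$values),
                                   cc$design$sample_id)]
  dm <- stats::model.matrix(~ factor(grp, levels = c("control", "treated")))
  fit <- limma::eBayes(limma::lmFit(cc$matrix$values, dm))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # p-values come from different variance priors but must rank alike and
  # call essentially the same discoveries at FDR 0.05
  expect_gt(cor(de$p, fit$p.value[, 2], method = "spearman"), 0.95)
  limma_sig <- rownames(fit$p.value)[p.adjust(fit$p.value[, 2], "BH") < 0.05]
  ours <- de$feature_id[de$significant]
  jaccard <- length(intersect(ours, limma_sig)) / length(union(ours, limma_sig))
  expect_gt(jaccard, 0.9)
})
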