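two_layer_fixture <- function(seed = 1, n_samples = 12) {
  set.seed(seed)
  s <- sprintf("S%02d", seq_len(n_samples))
  mi <- matrix(rnorm(3 * n_samples), 3, n_samples,
               dimnames = list(c("m1", "m2", "m3"), s))
  mr <- matrix(rnorm(3 * n_samples), 3, n_samples,
               dimnames = list(c("g1", "g2", "g3"), s))
  mr["g1", ] <- 5 - 2 * mi["m1", ]      # exact negative affine transform
  mr["g2", ] <- mi["m2", ]              # exact copy
  list(mi = expression_matrix(mi, "miRNA"), mr = expression_matrix(mr, "mRNA"))
}

test_that("correlation matrix hits the exact affine anchors", {
  f <- two_layer_fixture()
  cm <- correlation_matrix(f$mi, f$mr)
  expect_equal(cm["m1", "g1"], -1, tolerance = 1e-12)
  expect_equal(cm["m2", "g2"], 1, tolerance = 1e-12)
  expect_equal(dim(cm), c(3, 3))
})

test_that("correlation matrix flags sample mismatch and zero-variance features", {
  f <- two_layer_fixture()
  mr_perm <- expression_matrix(f$mr$values[, rev(colnames(f$mr$values))], "mRNA")
  expect_error(correlation_matrix(f$mi, mr_perm), "identically ordered")
  mi2 <- f$mi; mi2$values["m3", ] <- 4
  cm <- correlation_matrix(mi2, f$mr)
  expect_true(all(is.na(cm["m3", ])))
  expect_equal(attr(cm, "undefined_features"), "m3")
  expect_false(anyNA(cm["m1", ]))
  expect_error(correlation_matrix(f$mi, f$mr, character(0)), "nonempty")
})

test_that("binarization is inclusive at the threshold and maps NA to 0", {
  x <- matrix(c(-0.6, -0.5, -0.49, 0.7), 1, dimnames = list("m", paste0("g", 1:4)))
  expect_equal(unname(binarize(x)[1, ]), c(1L, 1L, 0L, 0L))
  pos <- matrix(runif(9, 0, 1), 3, dimnames = list(paste0("m", 1:3), paste0("g", 1:3)))
  expect_true(all(binarize(pos) == 0))
  expect_error(binarize(x, threshold = 0.2), "\\[-1, 0\\)")
  withna <- matrix(c(-0.9, NA, -0.2, NA), 2,
                   dimnames = list(paste0("m", 1:2), paste0("g", 1:2)))
  expect_equal(sum(binarize(withna)), 1L)
  # element-wise brute-force comparison on a crafted matrix
  set.seed(5)
  cm <- matrix(runif(9, -1, 1), 3, dimnames = list(paste0("m", 1:3), paste0("g", 1:3)))
  b <- binarize(cm, -0.3)
  for (i in 1:3) for (j in 1:3)
    expect_equal(b[i, j], as.integer(cm[i, j] <= -0.3))
})

test_that("permutation FDR is undefined at zero observed edges and seeded", {
  f <- two_layer_fixture(seed = 3)
  mi_pos <- expression_matrix(f$mi$values[c("m2", "m3"), ], "miRNA")
  mr_pos <- expression_matrix(f$mr$values["g2", , drop = FALSE], "mRNA")
  # m2-g2 correlates at +1; restrict to features with no anti-correlation
  pf <- permutation_fdr(mi_pos, mr_pos, threshold = -0.99, B = 10, seed = 1)
  expect_true(is.na(pf$network_fdr))
  expect_equal(pf$observed_edges, 0)
  expect_length(pf$null_edge_counts, 10)
  pf2 <- permutation_fdr(f$mi, f$mr, B = 25, seed = 7)
  pf3 <- permutation_fdr(f$mi, f$mr, B = 25, seed = 7)
  expect_identical(pf2$null_edge_counts, pf3$null_edge_counts)
  expect_error(permutation_fdr(f$mi, f$mr, B = 0), "B must be")
})

test_that("planted anti-correlation drives the network FDR below the null", {
  cfg <- sim_config(n_mirna = 20, n_mrna = 500, cell_lines = "HN1957",
                    n_de_mirna = 0, n_de_mrna = 0, n_edges = 20,
                    target_corr = -0.9)
  e <- simulate_experiment(cfg, 11)
  pf <- permutation_fdr(e$mirna, e$mrna, B = 200, seed = 1)
  expect_lt(pf$network_fdr, 0.5)
})

test_that("evidence filtering keeps only strong/NGS database pairs", {
  edges <- data.frame(mirna_id = c("m1", "m2", "m3"),
                      gene_id = c("g1", "g2", "g3"),
                      r = c(-0.9, -0.8, -0.7), stringsAsFactors = FALSE)
  db <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                   evidence = c("strong", "weak"), stringsAsFactors = FALSE)
  kept <- filter_validated(edges, db)
  expect_equal(kept$mirna_id, "m1")   # m2 weak, m3 absent
  expect_true(all(kept$validated))
})

test_that("filtering and thresholding commute", {
  f <- two_layer_fixture(seed = 8)
  cm <- correlation_matrix(f$mi, f$mr)
  db <- data.frame(mirna_id = c("m1", "m2", "m3"), gene_id = c("g1", "g3", "g2"),
                   evidence = c("strong", "NGS", "weak"), stringsAsFactors = FALSE)
  # threshold then filter
  e1 <- filter_validated(edges_from_matrix(cm, -0.5), db)
  # filter the full pair list then threshold
  all_pairs <- expand.grid(mirna_id = rownames(cm), gene_id = colnames(cm),
                           stringsAsFactors = FALSE)
  all_pairs$r <- cm[cbind(all_pairs$mirna_id, all_pairs$gene_id)]
  e2 <- filter_validated(all_pairs, db)
  e2 <- e2[!is.na(e2$r) & e2$r <= -0.5, ]
  expect_setequal(paste(e1$mirna_id, e1$gene_id), paste(e2$mirna_id, e2$gene_id))
})

test_that("direction annotation reflects DE fold-change signs", {
  de_mi <- data.frame(feature_id = c("m1", "m2"), log2fc = c(log2(1.31), -0.2))
  de_mr <- data.frame(feature_id = c("g1", "g2"), log2fc = c(log2(0.69), -0.6))
  edges <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  ann <- annotate_directions(edges, de_mi, de_mr)
  expect_equal(ann$mirna_direction, c("up", "down"))
  expect_equal(ann$gene_direction, c("down", "down"))
  bad <- data.frame(mirna_id = "mX", gene_id = "g1", stringsAsFactors = FALSE)
  expect_error(annotate_directions(bad, de_mi, de_mr), "mX")
})

test_that("combining networks intersects miRNAs and unions their edges", {
  mk <- function(mirnas, genes, cl) {
    ed <- data.frame(mirna_id = mirnas, gene_id = genes, r = -0.8,
                     mirna_direction = "up", gene_direction = "down",
                     validated = TRUE, cell_line = cl, stringsAsFactors = FALSE)
    structure(list(edges = ed, threshold = -0.5, network_fdr = 0.1,
                   n_permutations = 10, cell_line = cl), class = "corr_network")
  }
  a <- mk(c("m1", "m2"), c("g1", "g2"), "HN1957")
  b <- mk(c("m2", "m3"), c("g3", "g4"), "HN2092")
  comb <- combine_networks(a, b)
  expect_equal(comb$mirnas, "m2")
  expect_setequal(paste(comb$edges$mirna_id, comb$edges$gene_id),
                  c("m2 g2", "m2 g3"))
  expect_setequal(comb$edges$cell_line, c("HN1957", "HN2092"))
  # disjoint miRNA sets -> empty combined network
  d <- combine_networks(mk("m1", "g1", "HN1957"), mk("m9", "g9", "HN2092"))
  expect_equal(nrow(d$edges), 0)
  # identical networks -> same edges with dual provenance
  idn <- combine_networks(mk(c("m1", "m2"), c("g1", "g2"), "HN1957"),
                          mk(c("m1", "m2"), c("g1", "g2"), "HN2092"))
  expect_equal(nrow(idn$edges), 4)
  expect_error(combine_networks(a, mk("m1", "g1", "HN1957")), "distinct")
})

test_that("null decoy pairs pass the threshold at the iid chance rate", {
  # iid noise (no nesting), so the null tail P(r <= -0.5 | n = 12) applies
  p0 <- pt(-0.5 * sqrt(10) / sqrt(1 - 0.25), df = 10)
  cfg <- sim_config(n_mirna = 10, n_mrna = 100, cell_lines = "HN1957",
                    n_de_mirna = 0, n_de_mrna = 0, n_edges = 0,
                    bio_sd = 0, tech_sd = 0.3)
  hits <- 0; trials <- 0
  for (s in 1:30) {
    e <- simulate_experiment(cfg, s)
    db <- simulate_interaction_db(e$truth, n_decoys = 100,
                                  evidence_mix = c(strong = 1, NGS = 0, weak = 0),
                                  seed = s)
    cm <- correlation_matrix(e$mirna, e$mrna)
    kept <- filter_validated(edges_from_matrix(cm, -0.5), db)
    hits <- hits + nrow(kept)
    trials <- trials + nrow(db)
  }
  rate <- hits / trials
  tol <- 4 * sqrt(p0 * (1 - p0) / trials)
  expect_lt(abs(rate - p0), tol)
})

test_that("GraphML and SIF exports carry the network structure", {
  cfg <- sim_config(n_mirna = 10, n_mrna = 50, cell_lines = "HN1957",
                    n_de_mirna = 2, n_de_mrna = 5, n_edges = 4)
  e <- simulate_experiment(cfg, 6)
  db <- simulate_interaction_db(e$truth, n_decoys = 0, seed = 1)
  cc_mi <- collapse_technical_replicates(e$mirna, e$design)
  cc_mr <- collapse_technical_replicates(e$mrna, e$design)
  de_mi <- differential_expression(cc_mi$matrix, cc_mi$design)
  de_mr <- differential_expression(cc_mr$matrix, cc_mr$design)
  net <- build_network(e$mirna, e$mrna, de_mi, de_mr, db, "HN1957",
                       B = 20, seed = 2)
  gml <- tempfile(fileext = ".graphml"); sif <- tempfile(fileext = ".sif")
  write_graphml(net, gml)
  write_sif(net, sif)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(unique(igraph::V(g)$type), c("miRNA", "gene"))
  sif_lines <- readLines(sif)
  expect_length(sif_lines, nrow(net$edges))
  expect_true(all(grepl("\ttargets\t", sif_lines)))
  # every reported edge satisfies the threshold
  expect_true(all(net$edges$r <= -0.5))
})
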