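# Benchmark harness scoring the pipeline against the planted ground truth.
# Used by the analysis scripts and the acceptance checks.

#' Planted-edge recall of the full pipeline
#'
#' For each seed: simulate one culture, average technical replicates, score
#' differential expression in both layers, build the validated
#' anti-correlation network over the significant feature sets (database =
#' planted edges only), and compute the fraction of planted edges
#' recovered.
#'
#' @param seeds integer vector of simulation seeds
#' @param sim a [sim_config()]; defaults to the single-culture study layout
#' @param alpha DE FDR cutoff
#' @param threshold anti-correlation cutoff
#' @return numeric vector of per-seed recall values
#' @export
planted_edge_recall <- function(seeds, sim = sim_config(cell_lines = "HN1957"),
                                alpha = 0.05, threshold = -0.5) {
  vapply(seeds, function(s) {
    e <- simulate_experiment(sim, s)
    db <- simulate_interaction_db(e$truth, n_decoys = 0, seed = s)
    cc_mi <- collapse_technical_replicates(e$mirna, e$design)
    cc_mr <- collapse_technical_replicates(e$mrna, e$design)
    de_mi <- differential_expression(cc_mi$matrix, cc_mi$design, alpha = alpha)
    de_mr <- differential_expression(cc_mr$matrix, cc_mr$design, alpha = alpha)
    net <- tryCatch(
      build_network(e$mirna, e$mrna, de_mi, de_mr, db, sim$cell_lines[1],
                    threshold = threshold, B = 1, seed = s),
      error = function(err) NULL)
    if (is.null(net)) return(0)
    got <- paste(net$edges$mirna_id, net$edges$gene_id)
    want <- paste(e$truth$planted_edges$mirna_id, e$truth$planted_edges$gene_id)
    mean(want %in% got)
  }, 0)
}

#' Null-pipeline network calibration
#'
#' Simulates structure-free data and compares the observed thresholded edge
#' count (over all features) with its permutation-null expectation. With no
#' planted signal the ratio of totals should sit near 1.
#'
#' @param seeds integer vector of simulation seeds
#' @param sim a null [sim_config()] (no planted features)
#' @param threshold anti-correlation cutoff
#' @param B permutations per seed
#' @return list: `ratio` (total observed / total null expectation),
#'   `observed`, `null_expected` (per-seed vectors)
#' @export
null_network_calibration <- function(seeds,
                                     sim = sim_config(n_mirna = 20, n_mrna = 100,
                                                      cell_lines = "HN1957",
                                                      n_de_mirna = 0, n_de_mrna = 0,
                                                      n_edges = 0),
                                     threshold = -0.5, B = 20) {
  if (sim$n_edges != 0 || sim$n_de_mirna != 0 || sim$n_de_mrna != 0)
    stop("null calibration requires a configuration without planted structure")
  obs <- numeric(length(seeds)); nul <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    e <- simulate_experiment(sim, seeds[i])
    blocks <- paste(e$design$condition, e$design$bio_rep)[
      match(colnames(e$mirna$values), e$design$sample_id)]
    pf <- permutation_fdr(e$mirna, e$mrna, threshold = threshold, B = B,
                          seed = seeds[i], blocks = blocks)
    obs[i] <- pf$observed_edges
    nul[i] <- mean(pf$null_edge_counts)
  }
  list(ratio = sum(obs) / sum(nul), observed = obs, null_expected = nul)
}

#' Type-I proportion of the DE stage under the null
#'
#' Fraction of features called significant (BH FDR < alpha) in
#' structure-free simulations, averaged over seeds.
#'
#' @param seeds integer vector of simulation seeds
#' @param sim a null [sim_config()]
#' @param alpha DE FDR cutoff
#' @return list: `mean_fraction`, `fractions` (per seed), `pooled_p`
#'   (all raw p-values)
#' @export
null_de_type1 <- function(seeds,
                          sim = sim_config(n_mirna = 2, n_mrna = 200,
                                           cell_lines = "HN1957",
                                           n_de_mirna = 0, n_de_mrna = 0,
                                           n_edges = 0),
                          alpha = 0.05) {
  fr <- numeric(length(seeds)); pp <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    e <- simulate_experiment(sim, seeds[i])
    cc <- collapse_technical_replicates(e$mrna, e$design)
    de <- differential_expression(cc$matrix, cc$design, alpha = alpha)
    fr[i] <- mean(de$significant)
    pp[[i]] <- de$p
  }
  list(mean_fraction = mean(fr), fractions = fr, pooled_p = unlist(pp))
}
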