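#' Simulation configuration
#'
#' Defines the study conditions for the synthetic radiochemotherapy
#' experiment: two cell cultures, each with control and treated arms in
#' three biological and two technical replicates, log2-scale intensities
#' with additive Gaussian noise, planted treatment shifts and planted
#' repressive miRNA->mRNA dependencies.
#'
#' The planted repression acts on the log2 scale as
#' `mRNA = a - b * miRNA + noise` with `b > 0`, and the noise SD is
#' calibrated analytically so the population Pearson correlation between
#' the pair equals `target_corr`.
#'
#' @param n_mirna,n_mrna numbers of miRNA and mRNA features
#' @param cell_lines character vector of cell culture labels
#' @param n_bio,n_tech biological and technical replicates per arm
#' @param n_de_mirna,n_de_mrna numbers of planted differentially expressed
#'   features (beyond those involved in planted edges)
#' @param n_edges number of planted repressive miRNA->mRNA edges
#' @param de_shift absolute log2 treatment shift for planted DE features
#' @param edge_shift absolute log2 treatment shift given to each planted
#'   edge's miRNA (propagates with inverted sign to its target)
#' @param target_corr target population Pearson correlation of planted
#'   pairs, in [-1, -0.5]
#' @param bio_sd,tech_sd SDs of biological and technical noise (log2 units);
#'   biological noise is shared by the technical replicates of a
#'   biological replicate
#' @param baseline_mean,baseline_sd mean/SD of per-feature baseline log2
#'   intensity
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_mirna = 50, n_mrna = 500,
                       cell_lines = c("HN1957", "HN2092"),
                       n_bio = 3, n_tech = 2,
                       n_de_mirna = 10, n_de_mrna = 40,
                       n_edges = 20,
                       de_shift = 2.0, edge_shift = 2.0,
                       target_corr = -0.8,
                       bio_sd = 0.25, tech_sd = 0.1,
                       baseline_mean = 8, baseline_sd = 1.5) {
  if (n_mirna < 1 || n_mrna < 1 || n_bio < 1 || n_tech < 1 ||
      length(cell_lines) < 1)
    stop("dimensions must be positive")
  if (n_edges > 0 && (target_corr < -1 || target_corr > -0.5))
    stop("target_corr must lie in [-1, -0.5]")
  if (bio_sd < 0 || tech_sd < 0) stop("noise SDs must be >= 0")
  if (n_edges > min(n_mirna, n_mrna) || n_de_mirna + n_edges > n_mirna ||
      n_de_mrna + n_edges > n_mrna)
    stop("too many planted features for the requested dimensions")
  structure(list(
    n_mirna = n_mirna, n_mrna = n_mrna, cell_lines = cell_lines,
    n_bio = n_bio, n_tech = n_tech,
    n_de_mirna = n_de_mirna, n_de_mrna = n_de_mrna, n_edges = n_edges,
    de_shift = de_shift, edge_shift = edge_shift,
    target_corr = target_corr, bio_sd = bio_sd, tech_sd = tech_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd
  ), class = "sim_config")
}

default_design <- function(config) {
  g <- expand.grid(tech_rep = seq_len(config$n_tech),
                   bio_rep = seq_len(config$n_bio),
                   condition = c("control", "treated"),
                   cell_line = config$cell_lines,
                   stringsAsFactors = FALSE)
  g <- g[, c("cell_line", "condition", "bio_rep", "tech_rep")]
  g$sample_id <- sprintf("%s_%s%d_%s", g$cell_line,
                         ifelse(g$condition == "control", "C", "T"),
                         g$bio_rep, LETTERS[g$tech_rep])
  sample_design(g[, c("sample_id", "cell_line", "condition", "bio_rep", "tech_rep")])
}

#' Simulate the two-culture treatment-response experiment
#'
#' Generates log2 miRNA and mRNA intensity matrices over the nested
#' replicate design, with planted treatment shifts and planted repressive
#' miRNA->mRNA edges, plus the ground truth needed to score recovery.
#' Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [sim_config()]
#' @param seed integer RNG seed
#' @return list with elements `mirna`, `mrna` (expr_matrix), `design`
#'   (sample design), and `truth` (planted edges, truly shifted features,
#'   feature universes)
#' @export
simulate_experiment <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  design <- default_design(config)
  mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirna))
  gene_ids  <- sprintf("GENE%04d", seq_len(config$n_mrna))

  # assign planted roles without overlap
  edge_mi <- if (config$n_edges) sample(mirna_ids, config$n_edges) else character(0)
  edge_mr <- if (config$n_edges) sample(gene_ids, config$n_edges) else character(0)
  de_mi <- if (config$n_de_mirna)
    sample(setdiff(mirna_ids, edge_mi), config$n_de_mirna) else character(0)
  de_mr <- if (config$n_de_mrna)
    sample(setdiff(gene_ids, edge_mr), config$n_de_mrna) else character(0)

  shift_sign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  shifts <- c(
    stats::setNames(shift_sign(length(edge_mi)) * config$edge_shift, edge_mi),
    stats::setNames(shift_sign(length(de_mi)) * config$de_shift, de_mi),
    stats::setNames(shift_sign(length(de_mr)) * config$de_shift, de_mr)
  )

  base_mi <- stats::setNames(
    stats::rnorm(config$n_mirna, config$baseline_mean, config$baseline_sd), mirna_ids)
  base_mr <- stats::setNames(
    stats::rnorm(config$n_mrna, config$baseline_mean, config$baseline_sd), gene_ids)

  gen_matrix <- function(ids, base) {
    vals <- matrix(0, length(ids), nrow(design),
                   dimnames = list(ids, design$sample_id))
    for (cl in config$cell_lines) {
      for (cond in c("control", "treated")) {
        for (b in seq_len(config$n_bio)) {
          cols <- design$sample_id[design$cell_line == cl &
                                   design$condition == cond &
                                   design$bio_rep == b]
          bio <- stats::rnorm(length(ids), 0, config$bio_sd)
          for (s in cols) {
            tech <- stats::rnorm(length(ids), 0, config$tech_sd)
            vals[, s] <- base + bio + tech
          }
        }
      }
    }
    treated <- design$sample_id[design$condition == "treated"]
    sh <- shifts[ids]; sh[is.na(sh)] <- 0
    vals[, treated] <- vals[, treated] + sh
    vals
  }

  v_mi <- gen_matrix(mirna_ids, base_mi)
  v_mr <- gen_matrix(gene_ids, base_mr)

  # overwrite planted targets: gene = a - b*miRNA + eps, noise calibrated to
  # the target correlation given the miRNA's marginal variance (balanced
  # condition indicator contributes delta^2/4)
  b <- 1
  rho <- config$target_corr
  induced <- numeric(0)
  if (config$n_edges) {
    for (e in seq_len(config$n_edges)) {
      mi <- edge_mi[e]; mr <- edge_mr[e]
      delta <- shifts[[mi]]
      var_m <- delta^2 / 4 + config$bio_sd^2 + config$tech_sd^2
      sd_eps <- b * sqrt(var_m) * sqrt(1 / rho^2 - 1)
      for (cl in config$cell_lines) {
        cols <- design$sample_id[design$cell_line == cl]
        m_vals <- v_mi[mi, cols]
        center <- base_mi[[mi]] + delta / 2
        v_mr[mr, cols] <- base_mr[[mr]] - b * (m_vals - center) +
          stats::rnorm(length(cols), 0, sd_eps)
      }
    }
    induced <- stats::setNames(-b * shifts[edge_mi], edge_mr)
  }

  truth <- list(
    planted_edges = data.frame(mirna_id = edge_mi, gene_id = edge_mr,
                               target_correlation = rep(rho, config$n_edges),
                               stringsAsFactors = FALSE),
    de_features = data.frame(
      feature_id = c(names(shifts), names(induced)),
      log2_shift = unname(c(shifts, induced)),
      stringsAsFactors = FALSE),
    mirna_ids = mirna_ids, gene_ids = gene_ids
  )

  list(mirna = expression_matrix(v_mi, "miRNA"),
       mrna = expression_matrix(v_mr, "mRNA"),
       design = design, truth = truth)
}

#' Simulate a validated-interaction database
#'
#' Emulates a curated miRNA-target database: all planted edges are present
#' with admissible evidence ("strong" or "NGS"), plus `n_decoys` random
#' non-planted pairs whose evidence labels follow `evidence_mix`.
#'
#' @param truth the `truth` element of [simulate_experiment()]
#' @param n_decoys number of decoy (non-planted) records
#' @param evidence_mix named proportions over c(strong, NGS, weak) for the
#'   decoys; must sum to 1
#' @param seed integer RNG seed
#' @return data.frame with columns mirna_id, gene_id, evidence
#' @export
simulate_interaction_db <- function(truth, n_decoys = 100,
                                    evidence_mix = c(strong = 0.4, NGS = 0.3, weak = 0.3),
                                    seed = 1) {
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  if (!setequal(names(evidence_mix), c("strong", "NGS", "weak")) ||
      abs(sum(evidence_mix) - 1) > 1e-8)
    stop("evidence_mix must be named proportions over {strong, NGS, weak} summing to 1")
  set.seed(seed)
  planted <- truth$planted_edges
  db <- data.frame(mirna_id = planted$mirna_id, gene_id = planted$gene_id,
                   evidence = if (nrow(planted))
                     sample(c("strong", "NGS"), nrow(planted), replace = TRUE)
                   else character(0),
                   stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    taken <- paste(db$mirna_id, db$gene_id)
    n_pairs <- length(truth$mirna_ids) * length(truth$gene_ids)
    if (n_decoys > n_pairs - nrow(db)) stop("not enough non-planted pairs for decoys")
    decoys <- character(0)
    while (length(decoys) < n_decoys) {
      cand <- paste(sample(truth$mirna_ids, n_decoys, replace = TRUE),
                    sample(truth$gene_ids, n_decoys, replace = TRUE))
      decoys <- unique(c(decoys, setdiff(cand, taken)))
    }
    decoys <- decoys[seq_len(n_decoys)]
    parts <- strsplit(decoys, " ", fixed = TRUE)
    db <- rbind(db, data.frame(
      mirna_id = vapply(parts, `[`, "", 1L),
      gene_id = vapply(parts, `[`, "", 2L),
      evidence = sample(names(evidence_mix), n_decoys, replace = TRUE,
                        prob = evidence_mix),
      stringsAsFactors = FALSE))
  }
  rownames(db) <- NULL
  db
}

#' Simulate a pathway gene-set collection
#'
#' Random gene sets drawn from the gene universe, tagged with one of the
#' five standard source letters. Optionally plants one pathway concentrated
#' on a supplied gene set so downstream over-representation has a known
#' positive.
#'
#' @param gene_ids the gene universe
#' @param n_pathways number of random pathways
#' @param size_range min/max pathway size
#' @param planted_genes optional character vector; if given, an extra
#'   pathway "PLANTED_RESPONSE" containing these genes (padded with random
#'   genes up to `planted_size`) is added
#' @param planted_size size of the planted pathway
#' @param seed integer RNG seed
#' @return a [pathway_collection()]
#' @export
simulate_pathway_collection <- function(gene_ids, n_pathways = 50,
                                        size_range = c(10, 60),
                                        planted_genes = NULL,
                                        planted_size = 40, seed = 1) {
  set.seed(seed)
  sources <- c("B", "K", "N", "P", "R")
  sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
  pw <- lapply(seq_len(n_pathways), function(i) {
    list(id = sprintf("PW%03d", i), name = sprintf("Random pathway %03d", i),
         source = sample(sources, 1), genes = sample(gene_ids, sizes[i]))
  })
  if (!is.null(planted_genes)) {
    pad <- sample(setdiff(gene_ids, planted_genes),
                  max(0, planted_size - length(planted_genes)))
    pw <- c(pw, list(list(id = "PLANTED_RESPONSE", name = "Planted response pathway",
                          source = "R", genes = c(planted_genes, pad))))
  }
  pathway_collection(pw, universe = gene_ids)
}

#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold values for control and treated biological
#' replicates such that the expected ddCt of each target equals
#' `-log2(fold_change)`; with `ct_noise_sd = 0` the generation round-trips
#' exactly through [ddct_fold_change()].
#'
#' @param fold_changes named positive numeric vector of true treated/control
#'   fold changes; must include the reference targets with fold change 1
#' @param reference_targets names of the normalizer targets
#' @param n_bio_reps biological replicates per condition
#' @param n_pcr_reps technical PCR replicates per sample
#' @param ct_noise_sd SD of Gaussian measurement noise on Ct (cycles)
#' @param seed integer RNG seed
#' @return list with `ct` (data.frame target_id, sample_id, replicate, ct),
#'   `reference_targets`, and `design` (sample_id, condition)
#' @export
simulate_qpcr <- function(fold_changes, reference_targets,
                          n_bio_reps = 3, n_pcr_reps = 2,
                          ct_noise_sd = 0.2, seed = 1) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (!all(reference_targets %in% names(fold_changes)))
    stop("reference targets must appear in fold_changes")
  if (any(abs(fold_changes[reference_targets] - 1) > 1e-12))
    stop("reference targets must have fold change 1")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  set.seed(seed)
  targets <- names(fold_changes)
  base_ct <- stats::setNames(20 + 2 * seq_along(targets), targets)
  design <- data.frame(
    sample_id = c(sprintf("C%d", seq_len(n_bio_reps)),
                  sprintf("T%d", seq_len(n_bio_reps))),
    condition = rep(c("control", "treated"), each = n_bio_reps),
    stringsAsFactors = FALSE)
  rows <- expand.grid(replicate = seq_len(n_pcr_reps),
                      sample_id = design$sample_id,
                      target_id = targets, stringsAsFactors = FALSE)
  rows <- rows[, c("target_id", "sample_id", "replicate")]
  cond <- design$condition[match(rows$sample_id, design$sample_id)]
  ct <- base_ct[rows$target_id] -
    ifelse(cond == "treated", log2(fold_changes[rows$target_id]), 0)
  if (ct_noise_sd > 0) ct <- ct + stats::rnorm(nrow(rows), 0, ct_noise_sd)
  rows$ct <- unname(ct)
  list(ct = rows, reference_targets = reference_targets, design = design)
}
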