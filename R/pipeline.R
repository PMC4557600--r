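#' Pipeline configuration
#'
#' Collects the analysis constants: the DE significance cutoff (FDR 0.05),
#' the anti-correlation threshold (-0.5, inclusive), the number of
#' permutations behind the network FDR, the number of top features used
#' for heatmap clustering (50), and the clustering convention
#' (1 - Pearson distance, average linkage).
#'
#' @param seed integer master seed
#' @param alpha_de FDR cutoff for differential expression
#' @param corr_threshold anti-correlation threshold in [-1, 0)
#' @param n_permutations permutations for the network FDR
#' @param top_k number of top features for clustering
#' @param clustering list(distance, linkage)
#' @param collapse_tech_for_de average technical replicates before DE
#'   (biological replicates are then the test units); clustering always
#'   uses the full technical-replicate sample set
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, alpha_de = 0.05, corr_threshold = -0.5,
                            n_permutations = 1000, top_k = 50,
                            clustering = list(distance = "correlation",
                                              linkage = "average"),
                            collapse_tech_for_de = TRUE) {
  if (alpha_de <= 0 || alpha_de >= 1) stop("alpha_de must lie in (0, 1)")
  if (corr_threshold < -1 || corr_threshold >= 0)
    stop("corr_threshold must lie in [-1, 0)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(list(seed = seed, alpha_de = alpha_de,
                 corr_threshold = corr_threshold,
                 n_permutations = n_permutations, top_k = top_k,
                 clustering = clustering,
                 collapse_tech_for_de = collapse_tech_for_de),
            class = "pipeline_config")
}

#' Run the full integrative analysis end-to-end
#'
#' Simulates (or loads) the experiment, then per cell line: averages
#' technical replicates, scores treated-vs-control differential
#' expression, clusters samples on the top features and tests the
#' cluster-condition association, builds the validated anti-correlation
#' network with its permutation FDR, combines the two cell lines'
#' networks, and runs pathway over-representation on each network's target
#' genes. All artifacts are written under `out_dir` as TSV / GraphML /
#' SIF / JSON together with a machine-readable run manifest (config, seed,
#' package version, md5 of every artifact). Identical config + seed give
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()]
#' @param sim a [sim_config()] describing the synthetic experiment
#' @param out_dir output directory (created if needed)
#' @param n_decoys decoy records in the simulated interaction database
#' @return invisibly, a list with all in-memory stage results and
#'   `manifest_path`
#' @export
run_all <- function(config = pipeline_config(), sim = sim_config(),
                    out_dir, n_decoys = 100) {
  stopifnot(inherits(config, "pipeline_config"), inherits(sim, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  exp_ <- stage("simulate", simulate_experiment(sim, config$seed))
  db <- stage("interaction-db",
              simulate_interaction_db(exp_$truth, n_decoys = n_decoys,
                                      seed = config$seed + 1L))
  write_expression(exp_$mirna, pth("mirna_expression.tsv"))
  write_expression(exp_$mrna, pth("mrna_expression.tsv"))
  write_sample_sheet(exp_$design, pth("sample_sheet.tsv"))
  write_interaction_db(db, pth("interaction_db.tsv"))
  write_truth(exp_$truth, pth("truth.json"))

  lines <- sim$cell_lines
  de <- list(); clust <- list(); nets <- list()
  for (cl in lines) {
    mi <- subset_cell_line(exp_$mirna, exp_$design, cl)
    mr <- subset_cell_line(exp_$mrna, exp_$design, cl)
    de_in_mi <- if (config$collapse_tech_for_de)
      collapse_technical_replicates(mi$matrix, mi$design) else mi
    de_in_mr <- if (config$collapse_tech_for_de)
      collapse_technical_replicates(mr$matrix, mr$design) else mr
    de_mi <- stage(paste0("de-mirna-", cl),
                   differential_expression(de_in_mi$matrix, de_in_mi$design,
                                           alpha = config$alpha_de))
    de_mr <- stage(paste0("de-mrna-", cl),
                   differential_expression(de_in_mr$matrix, de_in_mr$design,
                                           alpha = config$alpha_de))
    write_de_table(de_mi, pth(sprintf("de_mirna_%s.tsv", cl)))
    write_de_table(de_mr, pth(sprintf("de_mrna_%s.tsv", cl)))
    de[[cl]] <- list(mirna = de_mi, mrna = de_mr)

    # clustering on the full technical-replicate sample set
    k_mi <- min(config$top_k, nrow(mi$matrix$values))
    k_mr <- min(config$top_k, nrow(mr$matrix$values))
    top_mi <- top_k_features(de_in_mi$matrix, de_mi, k_mi, by = "p_value")
    top_mr <- top_k_features(mr$matrix, k = k_mr, by = "variance")
    cl_mi <- stage(paste0("cluster-mirna-", cl), cluster_and_associate(
      expression_matrix(mi$matrix$values[top_mi, , drop = FALSE], "miRNA"),
      mi$design, label = "condition",
      linkage = config$clustering$linkage))
    cl_mr <- stage(paste0("cluster-mrna-", cl), cluster_and_associate(
      expression_matrix(mr$matrix$values[top_mr, , drop = FALSE], "mRNA"),
      mr$design, label = "condition",
      linkage = config$clustering$linkage))
    clust[[cl]] <- list(mirna = cl_mi, mrna = cl_mr)

    blocks <- paste(mi$design$condition, mi$design$bio_rep)[
      match(colnames(mi$matrix$values), mi$design$sample_id)]
    net <- stage(paste0("network-", cl), build_network(
      mi$matrix, mr$matrix, de_mi, de_mr, db, cl,
      threshold = config$corr_threshold, B = config$n_permutations,
      seed = config$seed + 2L, blocks = blocks))
    write_graphml(net, pth(sprintf("network_%s.graphml", cl)))
    write_sif(net, pth(sprintf("network_%s.sif", cl)))
    nets[[cl]] <- net
  }

  combined <- NULL
  if (length(lines) >= 2) {
    combined <- stage("combine", combine_networks(nets[[lines[1]]], nets[[lines[2]]]))
    write_graphml(combined, pth("network_combined.graphml"))
    write_sif(combined, pth("network_combined.sif"))
  }

  coll <- stage("pathways", simulate_pathway_collection(
    exp_$truth$gene_ids, planted_genes = exp_$truth$planted_edges$gene_id,
    seed = config$seed + 3L))
  write_gmt(coll, pth("pathways.gmt"))
  enr <- list()
  for (cl in lines) {
    genes <- unique(nets[[cl]]$edges$gene_id)
    if (length(intersect(genes, coll$universe))) {
      tab <- stage(paste0("enrich-", cl), enrich(genes, coll, alpha = config$alpha_de))
      write_enrichment_table(tab, pth(sprintf("enrichment_%s.tsv", cl)))
      enr[[cl]] <- tab
    }
  }

  # cluster report
  cr <- do.call(rbind, lapply(lines, function(cl) data.frame(
    cell_line = cl, layer = c("miRNA", "mRNA"),
    fisher_p = c(clust[[cl]]$mirna$fisher_p, clust[[cl]]$mrna$fisher_p),
    stringsAsFactors = FALSE)))
  write_tsv(cr, pth("cluster_association.tsv"))

  manifest <- make_manifest(config, sim, out_dir)
  invisible(list(experiment = exp_, db = db, de = de, clusters = clust,
                 networks = nets, combined = combined, enrichment = enr,
                 manifest_path = manifest))
}

make_manifest <- function(config, sim, out_dir) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  md5 <- as.character(tools::md5sum(file.path(out_dir, files)))
  cfg <- list(pipeline = unclass(config), sim = unclass(sim))
  cfg_file <- tempfile()
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg,
    config_md5 = as.character(tools::md5sum(cfg_file)),
    seed = config$seed,
    package = "miRmRNet",
    version = as.character(utils::packageVersion("miRmRNet")),
    artifacts = stats::setNames(as.list(md5), files)
  )
  unlink(cfg_file)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
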