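#' miRNA-mRNA correlation matrix
#'
#' Pearson correlations between selected miRNA rows and selected mRNA rows
#' across the shared (identically ordered) sample set of one cell line,
#' both conditions pooled. Zero-variance features yield undefined (NA)
#' entries, signalled via the "undefined_features" attribute.
#'
#' @param mi,mr `expr_matrix` objects over the same samples
#' @param features_mi,features_mr feature ids to correlate (e.g. the
#'   DE-significant sets)
#' @return numeric matrix (miRNAs x mRNAs) of correlations
#' @export
correlation_matrix <- function(mi, mr,
                               features_mi = feature_ids(mi),
                               features_mr = feature_ids(mr)) {
  if (!identical(colnames(mi$values), colnames(mr$values)))
    stop("miRNA and mRNA matrices must share an identically ordered sample set")
  if (length(features_mi) == 0 || length(features_mr) == 0)
    stop("feature sets must be nonempty")
  x <- t(mi$values[features_mi, , drop = FALSE])
  y <- t(mr$values[features_mr, , drop = FALSE])
  bad_x <- features_mi[apply(x, 2, stats::sd) == 0]
  bad_y <- features_mr[apply(y, 2, stats::sd) == 0]
  cmat <- suppressWarnings(stats::cor(x, y))
  if (length(bad_x)) cmat[bad_x, ] <- NA_real_
  if (length(bad_y)) cmat[, bad_y] <- NA_real_
  if (length(bad_x) || length(bad_y))
    attr(cmat, "undefined_features") <- c(bad_x, bad_y)
  cmat
}

#' Binarize a correlation matrix at the anti-correlation threshold
#'
#' An entry becomes 1 iff it is defined and <= `threshold` (inclusive, per
#' the -1 <= c <= -0.5 rule); undefined entries become 0.
#'
#' @param cmat correlation matrix
#' @param threshold cutoff in [-1, 0)
#' @return integer 0/1 matrix of the same shape
#' @export
binarize <- function(cmat, threshold = -0.5) {
  if (threshold < -1 || threshold >= 0) stop("threshold must lie in [-1, 0)")
  out <- (!is.na(cmat) & cmat <= threshold) * 1L
  dimnames(out) <- dimnames(cmat)
  out
}

# edge list (mirna_id, gene_id, r) from a correlation matrix + its binarization
edges_from_matrix <- function(cmat, threshold = -0.5) {
  b <- binarize(cmat, threshold)
  idx <- which(b == 1L, arr.ind = TRUE)
  data.frame(mirna_id = rownames(cmat)[idx[, 1]],
             gene_id = colnames(cmat)[idx[, 2]],
             r = cmat[idx], stringsAsFactors = FALSE)
}

#' Permutation-based network-level false discovery rate
#'
#' For each of B permutations the mRNA matrix's samples are randomly
#' permuted relative to the miRNA matrix (preserving each layer's internal
#' covariance while destroying cross-layer alignment) and the thresholded
#' edge count is recomputed. When `blocks` is supplied (normally the
#' biological-replicate grouping), whole blocks are permuted as units:
#' technical replicates of a biological replicate share noise and are not
#' individually exchangeable, so block permutation is what keeps the null
#' comparable to the observed data under the nested design. The network
#' FDR is the mean null edge count divided by the observed edge count;
#' undefined (NA) when no edge is observed.
#'
#' @param mi,mr `expr_matrix` objects over the same samples
#' @param features_mi,features_mr feature sets entering the network
#' @param threshold anti-correlation cutoff
#' @param B number of permutations
#' @param seed integer RNG seed
#' @param blocks optional factor-like vector (one entry per sample, in
#'   column order) defining exchangeable sample blocks; all blocks must
#'   have equal size
#' @return list: `network_fdr`, `null_edge_counts` (length B),
#'   `observed_edges`
#' @export
permutation_fdr <- function(mi, mr,
                            features_mi = feature_ids(mi),
                            features_mr = feature_ids(mr),
                            threshold = -0.5, B = 1000, seed = 1,
                            blocks = NULL) {
  if (B < 1) stop("B must be >= 1")
  cmat <- correlation_matrix(mi, mr, features_mi, features_mr)
  observed <- sum(binarize(cmat, threshold))
  set.seed(seed)
  x <- t(mi$values[features_mi, , drop = FALSE])
  y <- t(mr$values[features_mr, , drop = FALSE])
  n <- nrow(x)
  if (is.null(blocks)) {
    draw_perm <- function() sample.int(n)
  } else {
    if (length(blocks) != n) stop("'blocks' must have one entry per sample")
    idx <- split(seq_len(n), blocks)
    if (length(unique(lengths(idx))) != 1L)
      stop("permutation blocks must have equal size")
    draw_perm <- function() unlist(idx[sample.int(length(idx))], use.names = FALSE)
  }
  null_counts <- vapply(seq_len(B), function(b) {
    perm <- draw_perm()
    cb <- suppressWarnings(stats::cor(x, y[perm, , drop = FALSE]))
    sum(binarize(cb, threshold))
  }, 0L)
  fdr <- if (observed == 0) NA_real_ else mean(null_counts) / observed
  list(network_fdr = fdr, null_edge_counts = null_counts,
       observed_edges = observed)
}

#' Keep only database-validated edges
#'
#' Retains edges present in the interaction database with admissible
#' evidence ("strong" or "NGS"); weak-evidence and absent pairs are
#' dropped. Retained edges are flagged validated = TRUE.
#'
#' @param edges data.frame with mirna_id, gene_id columns
#' @param db interaction database (mirna_id, gene_id, evidence)
#' @return filtered edges with a `validated` column
#' @export
filter_validated <- function(edges, db) {
  ok <- db[db$evidence %in% c("strong", "NGS"), , drop = FALSE]
  keep <- paste(edges$mirna_id, edges$gene_id) %in% paste(ok$mirna_id, ok$gene_id)
  out <- edges[keep, , drop = FALSE]
  out$validated <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Annotate edge endpoints with regulation direction
#'
#' Attaches up/down direction labels from the sign of each endpoint's DE
#' log2 fold change.
#'
#' @param edges edge data.frame (mirna_id, gene_id, ...)
#' @param de_mi,de_mr DE result tables for miRNAs and mRNAs
#' @return edges with `mirna_direction` and `gene_direction` columns
#' @export
annotate_directions <- function(edges, de_mi, de_mr) {
  i1 <- match(edges$mirna_id, de_mi$feature_id)
  i2 <- match(edges$gene_id, de_mr$feature_id)
  if (anyNA(i1) || anyNA(i2))
    stop("edge endpoint(s) missing from the DE tables: ",
         paste(c(edges$mirna_id[is.na(i1)], edges$gene_id[is.na(i2)]), collapse = ", "))
  edges$mirna_direction <- ifelse(de_mi$log2fc[i1] >= 0, "up", "down")
  edges$gene_direction <- ifelse(de_mr$log2fc[i2] >= 0, "up", "down")
  edges
}

#' Build the anti-correlation network for one cell line
#'
#' Full network stage: correlation matrix over the significant feature
#' sets, thresholding, validated-interaction filtering, direction
#' annotation, and permutation FDR.
#'
#' @param mi,mr `expr_matrix` objects for one cell line (same samples)
#' @param de_mi,de_mr DE result tables (used for significance and
#'   directions)
#' @param db interaction database
#' @param cell_line cell line label carried by the network
#' @param threshold anti-correlation cutoff
#' @param B permutations for the network FDR
#' @param seed integer RNG seed
#' @param blocks optional exchangeable sample blocks for the permutation
#'   null (see [permutation_fdr()]); normally the biological-replicate
#'   grouping
#' @return object of class `corr_network`: `edges`, `threshold`,
#'   `network_fdr`, `n_permutations`, `cell_line`, `observed_unfiltered`
#' @export
build_network <- function(mi, mr, de_mi, de_mr, db, cell_line,
                          threshold = -0.5, B = 1000, seed = 1,
                          blocks = NULL) {
  sig_mi <- de_mi$feature_id[de_mi$significant]
  sig_mr <- de_mr$feature_id[de_mr$significant]
  if (length(sig_mi) == 0 || length(sig_mr) == 0)
    stop("no significant features to correlate for ", cell_line)
  cmat <- correlation_matrix(mi, mr, sig_mi, sig_mr)
  edges <- edges_from_matrix(cmat, threshold)
  pf <- permutation_fdr(mi, mr, sig_mi, sig_mr, threshold, B, seed,
                        blocks = blocks)
  edges <- filter_validated(edges, db)
  edges <- annotate_directions(edges, de_mi, de_mr)
  if (nrow(edges)) edges$cell_line <- cell_line
  structure(list(edges = edges, threshold = threshold,
                 network_fdr = pf$network_fdr, n_permutations = B,
                 cell_line = cell_line,
                 observed_unfiltered = pf$observed_edges),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network [%s]: %d validated edges (threshold %.2f, network FDR %s, B = %d)\n",
              x$cell_line, nrow(x$edges), x$threshold,
              ifelse(is.na(x$network_fdr), "n/a", sprintf("%.3f", x$network_fdr)),
              x$n_permutations))
  invisible(x)
}

#' Combine two cell lines' networks
#'
#' Restricts to miRNAs present in both networks and takes the union of
#' their edges over those miRNAs; each edge keeps its cell line of origin.
#'
#' @param a,b `corr_network` objects from distinct cell lines
#' @return object of class `corr_network_combined` with `edges`,
#'   `mirnas` (the shared miRNA set) and `cell_lines`
#' @export
combine_networks <- function(a, b) {
  stopifnot(inherits(a, "corr_network"), inherits(b, "corr_network"))
  if (identical(a$cell_line, b$cell_line))
    stop("networks must come from distinct cell lines")
  shared <- intersect(unique(a$edges$mirna_id), unique(b$edges$mirna_id))
  ed <- rbind(a$edges[a$edges$mirna_id %in% shared, , drop = FALSE],
              b$edges[b$edges$mirna_id %in% shared, , drop = FALSE])
  rownames(ed) <- NULL
  structure(list(edges = ed, mirnas = sort(shared),
                 cell_lines = c(a$cell_line, b$cell_line)),
            class = "corr_network_combined")
}

network_igraph <- function(net) {
  ed <- net$edges
  nodes <- data.frame(
    name = c(unique(ed$mirna_id), unique(ed$gene_id)),
    type = c(rep("miRNA", length(unique(ed$mirna_id))),
             rep("gene", length(unique(ed$gene_id)))),
    stringsAsFactors = FALSE)
  dir_of <- function(ids, id_col, dir_col) {
    vapply(ids, function(id) {
      d <- unique(ed[[dir_col]][ed[[id_col]] == id]); paste(d, collapse = "/")
    }, "")
  }
  nodes$direction <- c(dir_of(nodes$name[nodes$type == "miRNA"], "mirna_id", "mirna_direction"),
                       dir_of(nodes$name[nodes$type == "gene"], "gene_id", "gene_direction"))
  g <- igraph::graph_from_data_frame(
    ed[, c("mirna_id", "gene_id")], directed = TRUE, vertices = nodes)
  igraph::E(g)$r <- ed$r
  igraph::E(g)$validated <- ed$validated
  igraph::E(g)$cell_line <- if ("cell_line" %in% names(ed)) ed$cell_line else NA_character_
  g
}

#' Export a network as GraphML
#'
#' Node attributes: type (miRNA/gene), direction. Edge attributes: r,
#' validated, cell_line. Edges run miRNA -> gene.
#'
#' @param net a `corr_network` or `corr_network_combined`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_graphml <- function(net, path) {
  if (nrow(net$edges) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    g <- network_igraph(net)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network as SIF
#'
#' One line per edge: `miRNA  targets  gene`.
#'
#' @param net a `corr_network` or `corr_network_combined`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sif <- function(net, path) {
  ed <- net$edges
  lines <- if (nrow(ed)) paste(ed$mirna_id, "targets", ed$gene_id, sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}
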