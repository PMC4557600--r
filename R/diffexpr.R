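#' Average technical replicates
#'
#' Collapses each biological replicate's technical replicates to their
#' arithmetic mean on the log2 scale, yielding one column per biological
#' replicate. Averaging before testing avoids treating technical replicates
#' as independent units.
#'
#' @param m an `expr_matrix`
#' @param design a sample design covering `m`'s columns
#' @return list with collapsed `matrix` and updated `design`
#'   (one row per biological replicate, tech_rep = 1)
#' @export
collapse_technical_replicates <- function(m, design) {
  check_matrix_design(m, design)
  key <- paste(design$cell_line, design$condition, design$bio_rep, sep = "|")
  groups <- split(design$sample_id, key)
  ord <- unique(key)
  new_ids <- vapply(strsplit(ord, "|", fixed = TRUE), function(p)
    sprintf("%s_%s%s", p[1], ifelse(p[2] == "control", "C", "T"), p[3]), "")
  vals <- matrix(unlist(lapply(ord, function(k)
    rowMeans(m$values[, groups[[k]], drop = FALSE]))),
    nrow = nrow(m$values),
    dimnames = list(rownames(m$values), new_ids))
  parts <- strsplit(ord, "|", fixed = TRUE)
  d2 <- data.frame(
    sample_id = new_ids,
    cell_line = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    bio_rep = as.integer(vapply(parts, `[`, "", 3L)),
    tech_rep = 1L, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, m$kind), design = sample_design(d2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]), kept as a
#' named operation so the step is explicit and testable against the
#' hand-computed step-up arithmetic.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same order as input
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Moderated treated-vs-control differential expression
#'
#' Two-sample test on log2 intensities with empirical-Bayes variance
#' moderation: each feature's pooled variance is shrunk toward the median
#' feature variance with a fixed prior weight (`prior_df` pseudo-degrees of
#' freedom), and the moderated t-statistic is referred to a t distribution
#' with residual + prior degrees of freedom. Degenerate features whose
#' moderated variance is zero get p = 1 (and log2fc as computed), so null
#' pipelines stay runnable.
#'
#' @param m an `expr_matrix` (one cell line, typically after
#'   [collapse_technical_replicates()])
#' @param design matching sample design; must contain a single cell line
#'   and at least 2 replicates per condition
#' @param alpha FDR significance cutoff
#' @param prior_df prior degrees of freedom of the variance shrinkage
#' @return data.frame: feature_id, log2fc, fc, t, p, fdr, significant
#' @export
differential_expression <- function(m, design, alpha = 0.05, prior_df = 4) {
  check_matrix_design(m, design)
  if (length(unique(design$cell_line)) != 1L)
    stop("design spans multiple cell lines; subset with subset_cell_line() first")
  trt <- design$sample_id[design$condition == "treated"]
  ctl <- design$sample_id[design$condition == "control"]
  n1 <- length(trt); n2 <- length(ctl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")
  x1 <- m$values[, trt, drop = FALSE]
  x2 <- m$values[, ctl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log2fc <- m1 - m2
  df_res <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / df_res
  if (all(s2 == 0)) stop("zero total variance matrix")
  s2_prior <- stats::median(s2)
  s2_mod <- (prior_df * s2_prior + df_res * s2) / (prior_df + df_res)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0,
              2 * stats::pt(abs(tstat), df = prior_df + df_res, lower.tail = FALSE),
              1)
  p <- pmin(p, 1)
  fdr <- bh_adjust(p)
  data.frame(feature_id = feature_ids(m), log2fc = log2fc, fc = 2^log2fc,
             t = tstat, p = p, fdr = fdr, significant = fdr < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select top-k features
#'
#' Ranks features by cross-sample variance or by ascending raw DE p-value;
#' ties broken deterministically by feature id.
#'
#' @param m an `expr_matrix`
#' @param de DE result table (required for `by = "p_value"`)
#' @param k number of features to keep
#' @param by ranking criterion
#' @return character vector of k feature ids
#' @export
top_k_features <- function(m, de = NULL, k, by = c("p_value", "variance")) {
  by <- match.arg(by)
  ids <- feature_ids(m)
  if (k <= 0) stop("k must be positive")
  if (k > length(ids)) stop("k exceeds the number of features")
  if (by == "variance") {
    v <- apply(m$values, 1, stats::var)
    ids[order(-v, ids)][seq_len(k)]
  } else {
    if (is.null(de)) stop("DE table required for p-value ranking")
    idx <- match(ids, de$feature_id)
    if (anyNA(idx)) stop("features missing from DE table")
    ids[order(de$p[idx], ids)][seq_len(k)]
  }
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' @param tab 2x2 matrix of counts
#' @return the two-sided exact p-value
#' @export
fisher_exact_p <- function(tab) {
  if (!is.matrix(tab) || any(dim(tab) != 2) || any(tab < 0))
    stop("tab must be a nonnegative 2x2 matrix")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Cluster samples and test cluster-label association
#'
#' Agglomerative clustering of sample expression profiles with correlation
#' distance (1 - Pearson) and average linkage; the tree is cut into
#' `k_clusters` groups and association between cluster membership and a
#' design label (condition or cell line) is tested with a two-sided
#' Fisher's exact test.
#'
#' @param m an `expr_matrix` (typically restricted to top-k features)
#' @param design matching sample design
#' @param label design column to associate: "condition" or "cell_line"
#' @param k_clusters number of clusters to cut
#' @param linkage hclust agglomeration method
#' @return list: `clusters` (named integer vector), `table` (contingency),
#'   `fisher_p`, `tree` (hclust object)
#' @export
cluster_and_associate <- function(m, design, label = c("condition", "cell_line"),
                                  k_clusters = 2, linkage = "average") {
  label <- match.arg(label)
  check_matrix_design(m, design)
  if (ncol(m$values) < k_clusters) stop("fewer samples than clusters")
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample profile(s): ",
         paste(colnames(m$values)[sds == 0], collapse = ", "),
         " (correlation distance undefined)")
  d <- stats::as.dist(1 - stats::cor(m$values))
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k_clusters)
  lab <- design[[label]][match(names(cl), design$sample_id)]
  tab <- table(cluster = cl, label = lab)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(clusters = cl, table = tab, fisher_p = p, tree = tree)
}

#' Feature-set overlap
#'
#' @param a,b character vectors
#' @return list with `intersection` (sorted) and `count`
#' @export
feature_overlap <- function(a, b) {
  ix <- sort(intersect(a, b))
  list(intersection = ix, count = length(ix))
}
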