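#' Pathway collection
#'
#' A list of gene sets, each tagged with a source database letter
#' ((B) BioCarta, (K) KEGG, (N) NCI Nature, (P) PANTHER, (R) Reactome),
#' plus the background universe. By default the universe is the union of
#' all pathway genes; the background is the single most consequential
#' unstated parameter of over-representation analysis, so it is exposed
#' explicitly.
#'
#' @param pathways list of lists with elements id, name, source, genes
#' @param universe optional character vector; default: union of all genes
#' @return object of class `pathway_collection`
#' @export
pathway_collection <- function(pathways, universe = NULL) {
  for (p in pathways) {
    if (!all(c("id", "name", "source", "genes") %in% names(p)))
      stop("each pathway needs id, name, source, genes")
    if (length(p$genes) == 0) stop("pathway '", p$id, "' has an empty gene set")
    if (!p$source %in% c("B", "K", "N", "P", "R"))
      stop("unknown source tag '", p$source, "' in pathway '", p$id, "'")
  }
  all_genes <- unique(unlist(lapply(pathways, `[[`, "genes")))
  if (is.null(universe)) universe <- all_genes
  if (!all(all_genes %in% universe))
    stop("pathway gene(s) outside the universe")
  structure(list(pathways = pathways, universe = unique(universe)),
            class = "pathway_collection")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least k marked genes when n genes are drawn without replacement from a
#' universe of N containing K marked ones. Computed via [stats::phyper()],
#' which works in log space internally and is numerically stable.
#'
#' @param N universe size
#' @param K pathway size (marked genes)
#' @param n draw (gene-list) size
#' @param k observed overlap
#' @return the one-sided over-representation p-value
#' @export
hypergeom_upper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation of a gene list against the
#' collection's universe, adjusts jointly across all pathways with
#' Benjamini-Hochberg, filters to `fdr < alpha`, and sorts by p-value
#' (ties broken by pathway name).
#'
#' @param gene_list character vector of genes of interest
#' @param coll a [pathway_collection()]
#' @param alpha FDR cutoff for the reported table
#' @return data.frame: pathway, source, n_pathway, n_hits, p, fdr,
#'   hit_genes (comma-separated); attribute "all" carries the unfiltered
#'   table
#' @export
enrich <- function(gene_list, coll, alpha = 0.05) {
  stopifnot(inherits(coll, "pathway_collection"))
  lst <- intersect(unique(gene_list), coll$universe)
  if (length(lst) == 0) stop("gene list has empty intersection with the universe")
  N <- length(coll$universe); n <- length(lst)
  rows <- lapply(coll$pathways, function(pw) {
    hits <- sort(intersect(lst, pw$genes))
    data.frame(pathway = pw$name, source = pw$source,
               n_pathway = length(pw$genes), n_hits = length(hits),
               p = hypergeom_upper(N, length(pw$genes), n, length(hits)),
               hit_genes = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$p)
  tab <- tab[order(tab$p, tab$pathway), c("pathway", "source", "n_pathway",
                                          "n_hits", "p", "fdr", "hit_genes")]
  rownames(tab) <- NULL
  out <- tab[tab$fdr < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- tab
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set id, description, member genes. The description field
#' carries the source tag by convention (single letter, e.g. "K").
#'
#' @param path GMT file
#' @param universe optional background; default union of all sets
#' @return a [pathway_collection()]
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pw <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    list(id = f[1], name = f[1], source = f[2], genes = unique(f[-(1:2)]))
  })
  pathway_collection(pw, universe)
}

#' Write a pathway collection as GMT
#'
#' @param coll a [pathway_collection()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(coll$pathways, function(p)
    paste(c(p$id, p$source, p$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
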