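# TSV readers/writers for every pipeline artifact. All writers use '.' as
# the decimal mark, tab separation, no quoting, and a fixed column order so
# that write -> read -> write is byte-identical (golden-file friendly).

fmt_num <- function(x) {
  # canonical numeric formatting: up to 15 significant digits, no
  # scientific notation drift between platforms
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    s
  }, "")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA)
}

#' Write an expression matrix as TSV
#'
#' Rows are features; the first column is `feature_id`, remaining columns
#' are sample ids.
#'
#' @param m an `expr_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression <- function(m, path) {
  df <- data.frame(feature_id = feature_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix from TSV
#'
#' Malformed input (duplicate feature ids, non-numeric cells) is reported
#' with the offending id/line. Data lines are numbered from 2 (line 1 is
#' the header).
#'
#' @param path TSV file written by [write_expression()]
#' @param kind "miRNA" or "mRNA"
#' @param design optional sample design to validate the column set against
#' @return an `expr_matrix`
#' @export
read_expression <- function(path, kind, design = NULL) {
  df <- read_tsv(path)
  if (names(df)[1] != "feature_id") stop("first column must be 'feature_id'")
  dup <- duplicated(df$feature_id)
  if (any(dup))
    stop("duplicate feature id '", df$feature_id[dup][1], "' at line ",
         which(dup)[1] + 1L)
  for (j in seq_along(df)[-1]) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop("non-numeric cell in column '", names(df)[j], "' at line ", bad + 1L)
    }
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  m <- expression_matrix(vals, kind)
  if (!is.null(design)) check_matrix_design(m, design)
  m
}

#' Write / read a sample sheet
#'
#' @param design a sample design
#' @param path TSV file
#' @return `path` / the validated design
#' @export
write_sample_sheet <- function(design, path) {
  write_tsv(design[, c("sample_id", "cell_line", "condition", "bio_rep", "tech_rep")],
            path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) sample_design(read_tsv(path))

#' Write / read an interaction database
#'
#' @param db data.frame (mirna_id, gene_id, evidence)
#' @param path TSV file
#' @return `path` / the database
#' @export
write_interaction_db <- function(db, path) {
  write_tsv(db[, c("mirna_id", "gene_id", "evidence")], path)
}

#' @rdname write_interaction_db
#' @export
read_interaction_db <- function(path) {
  db <- read_tsv(path)
  if (anyDuplicated(db[, c("mirna_id", "gene_id")]))
    stop("duplicate (mirna_id, gene_id) record in interaction database")
  db
}

#' Write / read a differential expression table
#'
#' Columns: feature_id, log2fc, fc, p, fdr, significant.
#'
#' @param de DE result table
#' @param path TSV file
#' @return `path` / the table
#' @export
write_de_table <- function(de, path) {
  write_tsv(de[, c("feature_id", "log2fc", "fc", "p", "fdr", "significant")], path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) read_tsv(path)

#' Write / read a Ct table
#'
#' @param ct data.frame (target_id, sample_id, replicate, ct)
#' @param path TSV file
#' @return `path` / the table
#' @export
write_ct_table <- function(ct, path) {
  write_tsv(ct[, c("target_id", "sample_id", "replicate", "ct")], path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) read_tsv(path)

#' Write / read an enrichment table
#'
#' Mirrors the five-column pathway report: pathway, source, pathway size,
#' hits, p, FDR, hit genes.
#'
#' @param tab enrichment table from [enrich()]
#' @param path TSV file
#' @return `path` / the table
#' @export
write_enrichment_table <- function(tab, path) {
  write_tsv(as.data.frame(tab)[, c("pathway", "source", "n_pathway", "n_hits",
                                   "p", "fdr", "hit_genes")], path)
}

#' @rdname write_enrichment_table
#' @export
read_enrichment_table <- function(path) read_tsv(path)

#' Write / read the simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_experiment()]
#' @param path JSON file
#' @return `path` / the truth list
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_edges <- as.data.frame(x$planted_edges, stringsAsFactors = FALSE)
  x$de_features <- as.data.frame(x$de_features, stringsAsFactors = FALSE)
  x
}
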