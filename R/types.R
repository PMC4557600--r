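#' Expression matrix with feature kind
#'
#' Light container for a log2-scale feature-by-sample matrix. Rows are
#' features (miRNAs or genes), columns are samples keyed to a sample design.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample ids
#' @param kind "miRNA" or "mRNA"
#' @return an object of class `expr_matrix`
#' @export
expression_matrix <- function(values, kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("all expression values must be finite")
  structure(list(values = values, kind = kind), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids  <- function(m) colnames(m$values)

#' Sample design table
#'
#' Validates a sample sheet describing the nested replicate layout:
#' cell line x condition (control/treated) x biological x technical replicate.
#'
#' @param df data.frame with columns sample_id, cell_line, condition,
#'   bio_rep, tech_rep
#' @return the validated data.frame
#' @export
sample_design <- function(df) {
  need <- c("sample_id", "cell_line", "condition", "bio_rep", "tech_rep")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample design missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  if (!all(df$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  if (any(df$bio_rep < 1) || any(df$tech_rep < 1))
    stop("bio_rep and tech_rep must be >= 1")
  key <- paste(df$cell_line, df$condition, df$bio_rep, df$tech_rep)
  if (anyDuplicated(key))
    stop("duplicate (cell_line, condition, bio_rep, tech_rep) combination")
  df$sample_id <- as.character(df$sample_id)
  df$cell_line <- as.character(df$cell_line)
  df
}

# check that a matrix's columns exactly cover a design's samples
check_matrix_design <- function(m, design) {
  if (!setequal(sample_ids(m), design$sample_id))
    stop("matrix columns do not match the sample design: missing [",
         paste(setdiff(design$sample_id, sample_ids(m)), collapse = ", "),
         "], extra [",
         paste(setdiff(sample_ids(m), design$sample_id), collapse = ", "), "]")
  invisible(TRUE)
}

#' Subset an expression matrix and design to one cell line
#'
#' @param m an `expr_matrix`
#' @param design a sample design
#' @param cell_line cell line label to keep
#' @return list with elements `matrix` and `design`
#' @export
subset_cell_line <- function(m, design, cell_line) {
  keep <- design[design$cell_line == cell_line, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no samples for cell line '", cell_line, "'")
  list(matrix = expression_matrix(m$values[, keep$sample_id, drop = FALSE], m$kind),
       design = keep)
}
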