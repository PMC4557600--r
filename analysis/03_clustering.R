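#!/usr/bin/env Rscript
# Stage 3: unsupervised clustering of samples and cluster-condition
# association.
#
# Per culture: top 50 miRNAs by DE p-value and top 50 mRNAs by
# cross-sample variance (the two heatmap conventions), clustered over all
# 12 technical-replicate samples with 1 - Pearson distance and average
# linkage; the two main clusters are tested against the condition labels
# with a two-sided Fisher's exact test.

suppressPackageStartupMessages(library(miRmRNet))

dat <- "results/data"
design <- read_sample_sheet(file.path(dat, "sample_sheet.tsv"))
mirna <- read_expression(file.path(dat, "mirna_expression.tsv"), "miRNA", design)
mrna <- read_expression(file.path(dat, "mrna_expression.tsv"), "mRNA", design)

rows <- list()
for (cl in unique(design$cell_line)) {
  mi <- subset_cell_line(mirna, design, cl)
  mr <- subset_cell_line(mrna, design, cl)
  de_mi <- read_de_table(sprintf("results/de_mirna_%s.tsv", cl))
  top_mi <- top_k_features(mi$matrix, de_mi, min(50, nrow(mi$matrix$values)),
                           by = "p_value")
  top_mr <- top_k_features(mr$matrix, k = min(50, nrow(mr$matrix$values)),
                           by = "variance")
  res_mi <- cluster_and_associate(
    expression_matrix(mi$matrix$values[top_mi, ], "miRNA"), mi$design)
  res_mr <- cluster_and_associate(
    expression_matrix(mr$matrix$values[top_mr, ], "mRNA"), mr$design)
  cat(sprintf("%s: Fisher's exact cluster-condition p = %.4g (miRNA), %.4g (mRNA)\n",
              cl, res_mi$fisher_p, res_mr$fisher_p))
  rows[[cl]] <- data.frame(cell_line = cl, layer = c("miRNA", "mRNA"),
                           fisher_p = c(res_mi$fisher_p, res_mr$fisher_p))
}
tab <- do.call(rbind, rows); rownames(tab) <- NULL
utils::write.table(tab, "results/cluster_association.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("cluster-association table written to results/cluster_association.tsv\n")
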