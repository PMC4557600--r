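#!/usr/bin/env Rscript
# Stage 2: treated-vs-control differential expression per culture.
#
# Technical replicates are averaged first (biological replicates are the
# test units), then each feature is scored with the moderated t-statistic
# and BH-adjusted at FDR < 0.05. Reports the per-culture deregulated
# counts and their overlap, mirroring the study's headline summaries.

suppressPackageStartupMessages(library(miRmRNet))

dat <- "results/data"
design <- read_sample_sheet(file.path(dat, "sample_sheet.tsv"))
mirna <- read_expression(file.path(dat, "mirna_expression.tsv"), "miRNA", design)
mrna <- read_expression(file.path(dat, "mrna_expression.tsv"), "mRNA", design)

sig <- list()
for (cl in unique(design$cell_line)) {
  for (layer in c("mirna", "mrna")) {
    m <- if (layer == "mirna") mirna else mrna
    sub <- subset_cell_line(m, design, cl)
    cc <- collapse_technical_replicates(sub$matrix, sub$design)
    de <- differential_expression(cc$matrix, cc$design, alpha = 0.05)
    write_de_table(de, sprintf("results/de_%s_%s.tsv", layer, cl))
    sig[[paste(layer, cl)]] <- de$feature_id[de$significant]
    cat(sprintf("%s %-6s: %d / %d features deregulated at FDR < 0.05\n",
                cl, layer, sum(de$significant), nrow(de)))
  }
}
for (layer in c("mirna", "mrna")) {
  keys <- grep(layer, names(sig), value = TRUE)
  ov <- feature_overlap(sig[[keys[1]]], sig[[keys[2]]])
  cat(sprintf("%s overlap between cultures: %d features\n", layer, ov$count))
}
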