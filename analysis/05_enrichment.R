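#!/usr/bin/env Rscript
# Stage 5: pathway over-representation of the network target genes.
#
# Each culture's network target genes are tested against the multi-source
# pathway collection (hypergeometric upper tail, joint BH-FDR < 0.05,
# universe = union of all pathway genes). The planted response pathway
# should surface as the top hit.

suppressPackageStartupMessages(library(miRmRNet))

coll <- read_gmt("results/data/pathways.gmt")
for (cl in c("HN1957", "HN2092")) {
  sif <- readLines(sprintf("results/network_%s.sif", cl))
  genes <- unique(vapply(strsplit(sif, "\t"), `[`, "", 3L))
  tab <- enrich(genes, coll, alpha = 0.05)
  write_enrichment_table(tab, sprintf("results/enrichment_%s.tsv", cl))
  cat(sprintf("%s: %d target genes; %d pathway(s) at FDR < 0.05; top: %s (p = %.3g, %d/%d genes)\n",
              cl, length(genes), nrow(tab),
              if (nrow(tab)) tab$pathway[1] else "none",
              if (nrow(tab)) tab$p[1] else NA,
              if (nrow(tab)) tab$n_hits[1] else 0,
              if (nrow(tab)) tab$n_pathway[1] else 0))
}
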