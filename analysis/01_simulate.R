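#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-culture radiochemotherapy experiment.
#
# Emulates the study layout — two primary cultures (HN1957, HN2092), each
# with control (DMSO/sham) and treated (5-FU + 2x2 Gy) arms in three
# biological x two technical replicates — with 20 planted repressive
# miRNA->mRNA edges (population r = -0.8) and planted treatment shifts.
# Writes every downstream input plus the ground truth under results/data/.

suppressPackageStartupMessages(library(miRmRNet))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

sim <- sim_config()   # study defaults: 50 miRNAs x 500 mRNAs x 24 samples
e <- simulate_experiment(sim, seed)
db <- simulate_interaction_db(e$truth, n_decoys = 100, seed = seed + 1)
coll <- simulate_pathway_collection(e$truth$gene_ids,
                                    planted_genes = e$truth$planted_edges$gene_id,
                                    seed = seed + 2)

write_expression(e$mirna, file.path(out, "mirna_expression.tsv"))
write_expression(e$mrna, file.path(out, "mrna_expression.tsv"))
write_sample_sheet(e$design, file.path(out, "sample_sheet.tsv"))
write_interaction_db(db, file.path(out, "interaction_db.tsv"))
write_gmt(coll, file.path(out, "pathways.gmt"))
write_truth(e$truth, file.path(out, "truth.json"))

cat(sprintf("simulated %d miRNAs x %d mRNAs over %d samples (%s)\n",
            nrow(e$mirna$values), nrow(e$mrna$values), nrow(e$design),
            paste(sim$cell_lines, collapse = ", ")))
cat(sprintf("planted: %d repressive edges at r = %.1f, %d shifted features; DB: %d records (%d decoys)\n",
            nrow(e$truth$planted_edges), sim$target_corr,
            nrow(e$truth$de_features), nrow(db), nrow(db) - nrow(e$truth$planted_edges)))
cat("inputs written to", out, "\n")
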