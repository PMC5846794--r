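#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Writes, under results/inputs/: the 70 x 1128 abundance matrix (28 control /
# 42 affected, 28 treated), phenotype and annotation tables, a directed
# signaling network with 20 TFs, an undirected physical-interaction network
# carrying the planted seed gene, a gene-set collection with one planted
# pathway, a tissue expression table, and truth.json recording everything
# that was planted.

suppressPackageStartupMessages(library(serosig))

out_dir <- "results/inputs"
truth <- simulate_study(out_dir, cohort_config(seed = 1L))

message("inputs written to ", out_dir)
message(sprintf("planted: %d markers (%d strong), %d age markers, %d treatment markers",
                length(truth$marker_ids), length(truth$strong_marker_ids),
                length(truth$age_marker_ids), length(truth$treatment_marker_ids)))
message(sprintf("network: %d nodes / %d edges; regulator %s; seed gene %s at distance %g from the planted pathway",
                truth$n_nodes, truth$n_edges, truth$planted_regulator_tf,
                truth$planted_seed_gene, truth$planted_seed_distance))
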