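#!/usr/bin/env Rscript
# Step 5: network layer.
#
# Calls differentially abundant proteins (Welch t + BH over all assays),
# extracts a DE-preferring sub-network rooted at every transcription factor,
# attributes BH-significant pathways to their best regulator, computes
# pairwise overlap coefficients between the significant pathways, and tests
# the proximity of the planted seed gene to the top pathway against random
# network genes. Writes regulators.tsv, overlap_map.tsv and proximity.json
# under results/.

suppressPackageStartupMessages(library(serosig))

inp <- "results/inputs"
dataset <- read_expression(file.path(inp, "expression.tsv"),
                           file.path(inp, "phenotype.tsv"),
                           file.path(inp, "annotation.tsv"))
panel <- read.delim("results/panel_long.tsv")$assay_id
collection <- read_gmt(file.path(inp, "genesets.gmt"))
signaling <- read_network(file.path(inp, "signaling_edges.tsv"), directed = TRUE,
                          tf_list_path = file.path(inp, "tfs.txt"))
ppi <- read_network(file.path(inp, "ppi_edges.tsv"), directed = FALSE)
truth <- jsonlite::read_json(file.path(inp, "truth.json"), simplifyVector = TRUE)

de_genes <- differential_proteins(dataset)
message(length(de_genes), " differentially abundant genes (BH q < 0.05)")

tfs <- network_nodes(signaling)[igraph::V(signaling$graph)$is_tf]
panel_genes <- mapped_genes(dataset, panel)
regulators <- rank_regulators(signaling, tfs, panel_genes, de_genes, collection)
message("significant pathways: ", nrow(regulators),
        if (nrow(regulators)) paste0(" (top: ", regulators$pathway[1],
                                     " via ", regulators$regulator[1], ")"))
write.table(regulators, "results/regulators.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (nrow(regulators) >= 2) {
  pairs <- combn(sort(unique(regulators$pathway)), 2)
  overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    oc <- pathway_overlap_coefficient(collection$sets[[pairs[1, j]]],
                                      collection$sets[[pairs[2, j]]])
    data.frame(set_a = pairs[1, j], set_b = pairs[2, j],
               coefficient = oc$coefficient, shared = oc$shared)
  }))
  write.table(overlap, "results/overlap_map.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

if (nrow(regulators) >= 1) {
  top_pathway <- regulators$pathway[1]
  n_random <- min(1000L, length(network_nodes(ppi)) - 1L)
  prox <- proximity_empirical_p(ppi, truth$planted_seed_gene,
                                collection$sets[[top_pathway]],
                                n_random = n_random, rng_seed = 13L)
  message(sprintf("proximity of %s to %s: distance %g, empirical p = %.4g (n_random = %d)",
                  truth$planted_seed_gene, top_pathway, prox$d_obs, prox$p,
                  prox$n_random))
  jsonlite::write_json(list(seed_gene = prox$seed_gene, pathway = top_pathway,
                            d_obs = prox$d_obs, p = prox$p,
                            n_random = prox$n_random),
                       "results/proximity.json", auto_unbox = TRUE, digits = NA)
}
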