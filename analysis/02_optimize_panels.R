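#!/usr/bin/env Rscript
# Step 2: rank-signature classification and biomarker panel optimization.
#
# Runs the genetic optimizer twice on the simulated cohort: short mode
# (smallest panel at maximal accuracy) and long mode (largest panel with
# cross-validated accuracy >= 98%), then checks the long panel against 1000
# class-label permutations. Writes panel_short.tsv, panel_long.tsv,
# cv_results.json and permutation.json under results/.

suppressPackageStartupMessages(library(serosig))

inp <- "results/inputs"
dataset <- read_expression(file.path(inp, "expression.tsv"),
                           file.path(inp, "phenotype.tsv"),
                           file.path(inp, "annotation.tsv"))
message("cohort: ", length(dataset$subject_ids), " subjects x ",
        length(dataset$protein_ids), " proteins")

short <- optimize_parameters(dataset, ga_config(mode = "short", seed = 11L))
message(sprintf("short panel: %d proteins, signature length %d, accuracy %.4f",
                length(short$panel$protein_ids),
                short$params$n1 + short$params$n2, short$cv$mean_accuracy))

long <- optimize_parameters(dataset, ga_config(mode = "long", seed = 11L))
message(sprintf("long panel: %d proteins (n1=%d, n2=%d, alpha=%.3g), accuracy %.4f",
                length(long$panel$protein_ids), long$params$n1, long$params$n2,
                long$params$filter_alpha, long$cv$mean_accuracy))

perm <- permutation_test(dataset, long$params, k = 5, B = 1000, seed = 12L)
message(sprintf("permutation test: observed %.4f vs %d permutations, p = %.4g",
                perm$observed_accuracy, perm$B, perm$p_value))

write_panel <- function(res, file) {
  genes <- vapply(dataset$gene_map[res$panel$protein_ids], paste, "",
                  collapse = ";")
  write.table(data.frame(assay_id = res$panel$protein_ids,
                         gene_symbols = unname(genes)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
}
dir.create("results", showWarnings = FALSE)
write_panel(short, "results/panel_short.tsv")
write_panel(long, "results/panel_long.tsv")
jsonlite::write_json(list(short = list(params = unclass(short$params),
                                       accuracy = short$cv$mean_accuracy,
                                       panel_size = length(short$panel$protein_ids)),
                          long = list(params = unclass(long$params),
                                      accuracy = long$cv$mean_accuracy,
                                      panel_size = length(long$panel$protein_ids))),
                     "results/cv_results.json", auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(B = perm$B, observed = perm$observed_accuracy,
                          p = perm$p_value),
                     "results/permutation.json", auto_unbox = TRUE, digits = NA)
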