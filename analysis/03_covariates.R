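#!/usr/bin/env Rscript
# Step 3: covariate screens on the long biomarker panel.
#
# Checks that the cohort is age-matched (two-sample KS), then tests every
# long-panel protein for an age trend (per-group OLS on log2 levels) and for
# a steroid-treatment effect (Wilcoxon among affected subjects), with BH
# correction within the panel. Writes age_association.tsv,
# treatment_association.tsv and ks_age.json under results/.

suppressPackageStartupMessages(library(serosig))

inp <- "results/inputs"
dataset <- read_expression(file.path(inp, "expression.tsv"),
                           file.path(inp, "phenotype.tsv"),
                           file.path(inp, "annotation.tsv"))
panel <- read.delim("results/panel_long.tsv")$assay_id

aff <- dataset$class_label == "affected"
ks <- ks_age_compare(dataset$age[aff], dataset$age[!aff])
message(sprintf("age distributions: KS D = %.3f, p = %.2f (age-matched design)",
                ks$D, ks$p))

age_tab <- age_association(dataset, group = "both", proteins = panel)
n_aff <- sum(age_tab$q < 0.05 & age_tab$group == "affected")
n_ctl <- sum(age_tab$q < 0.05 & age_tab$group == "control")
message(sprintf("age trend (q < 0.05): %d panel proteins in affected, %d in controls",
                n_aff, n_ctl))

trt_tab <- treatment_association(dataset, proteins = panel)
message(sprintf("treatment effect (q < 0.05): %d panel proteins",
                sum(trt_tab$q < 0.05)))

write.table(age_tab, "results/age_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(trt_tab, "results/treatment_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(ks, "results/ks_age.json", auto_unbox = TRUE, digits = NA)
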