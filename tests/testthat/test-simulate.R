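test_that("cohort generator matches the study dimensions and is deterministic", {
  out <- generate_cohort(cohort_config(seed = 1))
  ds <- out$dataset
  expect_equal(length(ds$subject_ids), 70)
  expect_equal(length(ds$protein_ids), 1128)
  expect_equal(sum(ds$class_label == "affected"), 42)
  expect_equal(sum(ds$class_label == "control"), 28)
  expect_equal(sum(ds$treated), 28)
  expect_length(out$truth$marker_ids, 52)
  expect_length(out$truth$strong_marker_ids, 6)
  expect_length(out$truth$age_marker_ids, 31)
  expect_length(out$truth$treatment_marker_ids, 32)

  again <- generate_cohort(cohort_config(seed = 1))
  expect_identical(again$dataset$values, ds$values)
  other <- generate_cohort(cohort_config(seed = 2))
  expect_false(identical(other$dataset$values, ds$values))
})

test_that("impossible cohort configurations fail before sampling", {
  expect_error(cohort_config(n_markers = 2000), "exceeds n_proteins")
  expect_error(cohort_config(n_strong_markers = 60), "exceeds n_markers")
  expect_error(cohort_config(n_age_markers = 53), "exceeds n_markers")
  expect_error(cohort_config(treated_fraction_of_affected = 1.2), "\\[0, 1\\]")
})

test_that("planted class effects are recovered by group means of log2 values", {
  out <- generate_cohort(cohort_config(seed = 1))
  ds <- out$dataset
  tr <- out$truth
  # treatment markers carry an extra shift in the treated affected subgroup,
  # so the clean class-mean comparison applies to the remaining markers
  check <- setdiff(tr$marker_ids, tr$treatment_marker_ids)
  L <- log2(ds$values[, check, drop = FALSE])
  aff <- ds$class_label == "affected"
  diff_means <- colMeans(L[aff, ]) - colMeans(L[!aff, ])
  se <- sqrt(apply(L[aff, ], 2, var) / sum(aff) +
               apply(L[!aff, ], 2, var) / sum(!aff))
  expect_true(all(abs(diff_means - tr$effects[check]) <= 3 * se))
})

test_that("age distributions are exchangeable and non-markers carry no class effect", {
  n_seeds <- 100
  ks_reject <- logical(n_seeds)
  null_reject_num <- 0
  null_total <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_control = 14, n_affected = 20, n_proteins = 60,
                         n_markers = 5, n_strong_markers = 2,
                         n_age_markers = 3, n_treatment_markers = 3, seed = s)
    out <- generate_cohort(cfg)
    ds <- out$dataset
    aff <- ds$class_label == "affected"
    ks_reject[s] <- ks_age_compare(ds$age[aff], ds$age[!aff])$p < 0.05
    p <- attr(wilcoxon_prefilter(ds, 1), "p")
    nulls <- setdiff(ds$protein_ids, out$truth$marker_ids)
    null_reject_num <- null_reject_num + sum(p[nulls] < 0.05)
    null_total <- null_total + length(nulls)
  }
  # alpha = 0.05 tests: binomial 3 SD band around the nominal level, with
  # room below for the conservativeness of exact/discrete tests
  expect_lt(mean(ks_reject), 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))
  rate <- null_reject_num / null_total
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / null_total))
  expect_gt(rate, 0.03)
})

test_that("network generator wires the planted TF and records true distances", {
  markers <- sprintf("G%02d", 1:20)
  strong <- markers[1:6]
  nets <- generate_network(n_nodes = 500, truth_markers = markers,
                           strong_markers = strong, seed = 9)
  g <- nets$signaling$graph
  d <- igraph::distances(g, v = nets$truth$planted_regulator_tf, to = strong,
                         mode = "out")
  expect_true(all(d == 2))           # length-2 paths through the DE relays
  de_nodes <- igraph::V(g)$name[igraph::V(g)$is_de]
  expect_true(all(nets$truth$de_intermediates %in% de_nodes))

  # recorded seed distance equals a brute-force shortest-path computation
  gp <- nets$ppi$graph
  all_d <- igraph::distances(gp, v = nets$truth$planted_seed_gene,
                             to = intersect(nets$truth$planted_pathway_genes,
                                            igraph::V(gp)$name))
  expect_equal(min(all_d), nets$truth$planted_seed_distance)

  again <- generate_network(n_nodes = 500, truth_markers = markers,
                            strong_markers = strong, seed = 9)
  expect_identical(igraph::as_edgelist(again$signaling$graph),
                   igraph::as_edgelist(g))
  expect_error(generate_network(n_nodes = 10, n_tfs = 10), "smaller than")
})

test_that("gene-set generator plants an enriched set and is deterministic", {
  universe <- sprintf("G%03d", 1:300)
  planted <- sprintf("G%03d", 1:12)
  gs <- generate_genesets(n_sets = 30, set_size_range = c(10, 30),
                          universe = universe, planted_set = planted, seed = 4)
  expect_length(gs$sets, 31)
  expect_true(all(planted %in% gs$sets$PLANTED))
  ora <- ora_hypergeometric(planted, gs, universe)
  p_planted <- ora$p[ora$set == "PLANTED"]
  expect_lt(p_planted, median(ora$p[ora$set != "PLANTED"]))

  only <- generate_genesets(n_sets = 0, set_size_range = c(10, 30),
                            universe = universe, planted_set = planted, seed = 4)
  expect_equal(names(only$sets), "PLANTED")
  expect_identical(generate_genesets(25, c(5, 20), universe, planted, seed = 8),
                   generate_genesets(25, c(5, 20), universe, planted, seed = 8))
  expect_error(generate_genesets(5, c(10, 400), universe, planted, seed = 1),
               "universe")
  expect_error(generate_genesets(5, c(5, 20), universe, "NOTTHERE", seed = 1),
               "subset")
})

test_that("tissue generator plants recoverable categories", {
  quota <- c(tissue_enriched = 5, group_enriched = 6, tissue_enhanced = 4,
             expressed_in_all = 10, not_detected = 5)
  out <- generate_tissue_table(n_genes = 40, tissues = sprintf("t%02d", 1:10),
                               category_quota = quota, seed = 11,
                               target_tissue = "t03")
  cats <- classify_tissue_specificity(out$table)
  expect_equal(cats$category, out$truth$category)
  enr <- cats[cats$category == "tissue_enriched", ]
  expect_equal(unique(enr$tissue), "t03")
  expect_identical(out$table$values,
                   generate_tissue_table(40, sprintf("t%02d", 1:10), quota,
                                         seed = 11, target_tissue = "t03")$table$values)
  expect_error(generate_tissue_table(10, c("a", "b"),
                                     c(group_enriched = 2), seed = 1),
               "at least 3 tissues")
  expect_error(generate_tissue_table(3, sprintf("t%d", 1:8),
                                     c(tissue_enriched = 2, not_detected = 2),
                                     seed = 1),
               "exceed")
})
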