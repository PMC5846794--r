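test_that("group-average classification picks the nearer class, tie -> control", {
  expect_equal(classify_subject(c(0.1, 0.1, 0.9), c("control", "control", "affected")),
               "control")
  expect_warning(out <- classify_subject(c(0.3, 0.3), c("control", "affected")),
                 "tie")
  expect_equal(out, "control")
  # hand-computed group means: control (0.2 + 0.4)/2 = 0.3, affected (0.1 + 0.3)/2 = 0.2
  expect_equal(classify_subject(c(0.2, 0.4, 0.1, 0.3),
                                c("control", "control", "affected", "affected")),
               "affected")
  expect_error(classify_subject(c(0.1, 0.2), c("control", "control")),
               "both classes")
})

test_that("cross-validation separates a planted cohort perfectly and is deterministic", {
  ds <- generate_cohort(cohort_config(seed = 3))$dataset
  params <- signature_params(1, 1, filter_alpha = 1e-6)
  cv <- cross_validate(ds, params, k = 5, seed = 2)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_true(all(sort(unique(unname(cv$fold_assignment))) == 1:5))
  cv2 <- cross_validate(ds, params, k = 5, seed = 2)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$predicted, cv2$predicted)
  expect_identical(cv$panel_ids, cv2$panel_ids)

  small <- noise_cohort(4, 12, 10, seed = 1)
  expect_error(cross_validate(small, params, k = 5, seed = 1), "at least k")
})

test_that("pure-noise cohorts classify at chance level", {
  accs <- vapply(1:200, function(s) {
    ds <- noise_cohort(10, 14, 30, seed = 1000 + s)
    cross_validate(ds, signature_params(1, 1, filter_alpha = 1),
                   k = 4, seed = s)$mean_accuracy
  }, 1.0)
  # label-exchangeable data: prediction is symmetric, so accuracy centres on
  # 1/2; band = 3 SD of the mean of 200 per-cohort accuracies
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.02)
})

test_that("stronger planted effects never reduce cross-validated accuracy", {
  acc <- vapply(c(0.2, 1.0, 4.0), function(scale) {
    cfg <- cohort_config(n_control = 14, n_affected = 20, n_proteins = 80,
                         n_markers = 8, n_strong_markers = 0,
                         n_age_markers = 0, n_treatment_markers = 0,
                         effect_sizes = c(0.5, 0.8) * scale, seed = 7)
    ds <- generate_cohort(cfg)$dataset
    cross_validate(ds, signature_params(2, 2, filter_alpha = 0.25),
                   k = 5, seed = 7)$mean_accuracy
  }, 1.0)
  expect_true(all(diff(acc) >= 0))
})

test_that("panel aggregation is the union of signatures with a contribution map", {
  s1 <- structure(list(subject_id = "x", top = c("A"), bottom = c("B")),
                  class = "subject_signature")
  s2 <- structure(list(subject_id = "y", top = c("B"), bottom = c("C")),
                  class = "subject_signature")
  pan <- aggregate_panel(list(s1, s2), mode = "short")
  expect_setequal(pan$protein_ids, c("A", "B", "C"))
  expect_setequal(pan$contributing$B, c("x", "y"))
  same <- aggregate_panel(list(s1, s1), mode = "short")
  expect_setequal(same$protein_ids, c("A", "B"))

  set.seed(9)
  sigs <- lapply(1:50, function(i) {
    ids <- sample(sprintf("P%02d", 1:30), 4)
    structure(list(subject_id = paste0("s", i), top = ids[1:2],
                   bottom = ids[3:4]), class = "subject_signature")
  })
  pan2 <- aggregate_panel(sigs, mode = "long")
  union_oracle <- unique(unlist(lapply(sigs, function(s) c(s$top, s$bottom))))
  expect_setequal(pan2$protein_ids, union_oracle)
})

test_that("permutation p-value follows the add-one formula and flags real signal", {
  ds <- generate_cohort(cohort_config(n_control = 14, n_affected = 20,
                                      n_proteins = 100, n_markers = 10,
                                      n_strong_markers = 4, n_age_markers = 5,
                                      n_treatment_markers = 5, seed = 5))$dataset
  pr <- permutation_test(ds, signature_params(1, 1, filter_alpha = 1e-4),
                         k = 5, B = 19, seed = 5)
  expect_equal(pr$p_value,
               (sum(pr$null_accuracies >= pr$observed_accuracy) + 1) / (19 + 1))
  expect_equal(pr$observed_accuracy, 1.0)
  expect_equal(pr$p_value, 1 / 20)   # no permutation matches the real labels
  expect_error(permutation_test(ds, signature_params(1, 1), B = 0), "B must be")
})

test_that("permutation p is valid (super-uniform) under true-null labels", {
  n_seeds <- 150
  B <- 19
  pvals <- vapply(seq_len(n_seeds), function(s) {
    ds <- noise_cohort(8, 10, 25, seed = 3000 + s)
    permutation_test(ds, signature_params(1, 1, filter_alpha = 0.5),
                     k = 3, B = B, seed = s)$p_value
  }, 1.0)
  tol <- 3 * sqrt(0.25 / n_seeds)
  for (a in c(0.1, 0.25, 0.5, 0.75)) {
    expect_lte(mean(pvals <= a), a + tol)
  }
  expect_gt(mean(pvals), 0.35)   # and not degenerately stuck at 1
})
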