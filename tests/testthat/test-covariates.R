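test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # all-equal p unchanged
  set.seed(12)
  for (i in 1:10) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))    # monotone in p order
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("age regression recovers exact linear trends and flat proteins", {
  ages <- c(4, 6, 8, 10, 12)
  vals <- cbind(LIN = 2^(9 - 0.3 * ages),   # exactly linear in log2
                FLAT = rep(2^8, 5))
  rownames(vals) <- paste0("s", 1:5)
  ds <- tiny_dataset(vals, rep("affected", 5), age = ages)
  tab <- age_association(ds, group = "affected")
  expect_equal(tab$estimate[tab$protein == "LIN"], -0.3, tolerance = 1e-12)
  expect_equal(tab$p[tab$protein == "LIN"], 0)        # zero residuals
  expect_equal(tab$estimate[tab$protein == "FLAT"], 0)
  expect_equal(tab$p[tab$protein == "FLAT"], 1)
  expect_error(age_association(tiny_dataset(vals[1:2, ], rep("affected", 2),
                                            age = c(5, 6)), "affected"),
               "at least 3")
  expect_error(age_association(tiny_dataset(vals, rep("affected", 5),
                                            age = rep(7, 5)), "affected"),
               "constant")
})

test_that("age regression matches lm on random data", {
  set.seed(3)
  ages <- runif(12, 4, 15)
  vals <- matrix(2^rnorm(12 * 4, 10), 12, 4,
                 dimnames = list(paste0("s", 1:12), paste0("P", 1:4)))
  ds <- tiny_dataset(vals, rep("control", 12), age = ages)
  tab <- age_association(ds, group = "control")
  for (j in 1:4) {
    fit <- summary(lm(log2(vals[, j]) ~ ages))
    expect_equal(tab$estimate[j], unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(tab$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-10)
  }
})

test_that("planted age markers are recovered in affected subjects only", {
  out <- generate_cohort(cohort_config(seed = 2))
  ds <- out$dataset
  tr <- out$truth
  tab <- age_association(ds, group = "both", proteins = tr$marker_ids)
  aff <- tab[tab$group == "affected", ]
  ctl <- tab[tab$group == "control", ]
  sens <- mean(aff$q[aff$protein %in% tr$age_marker_ids] < 0.05)
  expect_gte(sens, 0.8)
  expect_lte(mean(ctl$q[ctl$protein %in% tr$age_marker_ids] < 0.05), 0.1)
  # the two exceptional markers drift upward, the rest downward
  slopes <- setNames(aff$estimate, aff$protein)[tr$age_marker_ids]
  expect_equal(sum(tr$age_slopes > 0), 2)
  expect_true(all(sign(slopes[tr$age_slopes > 0]) == 1))
})

test_that("treatment association is exact on small arms and null on identical arms", {
  vals <- matrix(c(1, 2, 3, 10, 11, 12, 5, 6, 7, 5.5, 6.5, 7.5), 6, 2,
                 dimnames = list(paste0("s", 1:6), c("P1", "P2")))
  ds <- tiny_dataset(vals, rep("affected", 6),
                     treated = rep(c(FALSE, TRUE), each = 3))
  tab <- treatment_association(ds)
  # enumeration over all C(6,3) = 20 assignments: fully separated arms give
  # two-sided p = 2/20
  expect_equal(tab$p[tab$protein == "P1"], 0.1)
  expect_gt(tab$estimate[tab$protein == "P1"], 0)

  set.seed(21)
  null_ds <- noise_cohort(0, 24, 40, seed = 33)
  null_ds$treated[13:24] <- TRUE
  ntab <- treatment_association(null_ds)
  expect_lte(mean(ntab$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40) + 0.05)
  expect_true(all(ntab$q >= ntab$p - 1e-15))
  expect_error(treatment_association(tiny_dataset(vals, rep("affected", 6),
                                                  treated = rep(TRUE, 6))),
               "both treated and untreated")
})

test_that("KS comparison matches hand-computed ECDF toys and the matched design", {
  same <- ks_age_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  apart <- ks_age_compare(c(1, 2), c(3, 4))
  expect_equal(apart$D, 1)
  expect_error(ks_age_compare(numeric(0), c(1)), "non-empty")

  ok <- vapply(1:100, function(s) {
    cfg <- cohort_config(n_control = 14, n_affected = 20, n_proteins = 4,
                         n_markers = 0, n_strong_markers = 0,
                         n_age_markers = 0, n_treatment_markers = 0, seed = s)
    ds <- generate_cohort(cfg)$dataset
    aff <- ds$class_label == "affected"
    ks_age_compare(ds$age[aff], ds$age[!aff])$p > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
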