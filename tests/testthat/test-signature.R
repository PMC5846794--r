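test_that("enrichment score reproduces the running-sum example and extremes", {
  # P = 5, hits at ranks 1 and 3, w = 0: running sum
  # (0.5, 0.1667, 0.6667, 0.3333, 0) -> score 2/3
  expect_equal(enrichment_score(c("A", "C"), c("A", "B", "C", "D", "E"), w = 0),
               2 / 3, tolerance = 1e-12)
  ranking <- sprintf("P%02d", 1:10)
  for (w in c(0, 0.5, 1, 2)) {
    expect_equal(enrichment_score(ranking[1:3], ranking, w), 1)
    expect_equal(enrichment_score(ranking[8:10], ranking, w), -1)
  }
  expect_error(enrichment_score(character(), ranking), "empty")
  expect_error(enrichment_score(ranking, ranking), "strict subset")
  expect_error(enrichment_score("ZZ", ranking), "absent")
})

test_that("enrichment score agrees with the brute-force oracle on random cases", {
  set.seed(31)
  ranking <- sprintf("P%02d", 1:25)
  for (i in 1:50) {
    s <- sample(ranking, sample(1:10, 1))
    w <- sample(c(0, 0.5, 1, 2), 1)
    expect_equal(enrichment_score(s, ranking, w), es_oracle(s, ranking, w),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon pre-filter uses the exact two-sided rank-sum p", {
  vals <- matrix(c(1, 2, 3, 10, 11, 12, 5, 6, 7, 5.5, 6.5, 7.5), 6, 2,
                 dimnames = list(paste0("s", 1:6), c("P1", "P2")))
  ds <- tiny_dataset(vals, rep(c("control", "affected"), each = 3))
  # fully separated 3 vs 3: exact two-sided p = 2 * 1/20 = 0.1
  expect_equal(unname(attr(wilcoxon_prefilter(ds, 1), "p")["P1"]), 0.1)
  expect_equal(wilcoxon_prefilter(ds, 0.1)[1], "P1")
  expect_error(wilcoxon_prefilter(ds, 0.09), "increase alpha")
  expect_error(wilcoxon_prefilter(ds, 0), "\\(0, 1\\]")
  expect_error(wilcoxon_prefilter(ds, 1.5), "\\(0, 1\\]")

  same <- tiny_dataset(matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 6, 2,
                              dimnames = list(paste0("s", 1:6), c("A", "B"))),
                       rep(c("control", "affected"), each = 3))
  expect_length(wilcoxon_prefilter(same, 1), 2)  # alpha = 1 retains everything
})

test_that("rank-sum p matches wilcox.test across sizes and with ties", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    x <- matrix(rnorm(n1 + n0), ncol = 1)
    if (rep %% 3 == 0) x[1:2] <- x[3:4]   # inject ties sometimes
    grp <- rep(c(TRUE, FALSE), c(n1, n0))
    mine <- serosig:::ranksum_pvalues(x, grp)
    ref <- suppressWarnings(wilcox.test(x[grp], x[!grp]))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("fold-change preprocessing divides by training means, reusable on held-out data", {
  vals <- matrix(c(1, 3, 2, 2), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  ds <- tiny_dataset(vals, c("control", "affected"))
  out <- foldchange_preprocess(ds)
  expect_equal(unname(out$values[, "A"]), c(0.5, 1.5))   # column {1,3}, mean 2
  expect_equal(unname(out$values[, "B"]), c(1, 1))       # constant column
  held <- tiny_dataset(matrix(c(4, 6), 1, 2, dimnames = list("s3", c("A", "B"))),
                       "affected")
  applied <- foldchange_preprocess(held, means = attr(out, "protein_means"))
  expect_equal(unname(applied$values[1, ]), c(4 / 2, 6 / 2))
})

test_that("signatures take rank extremes with deterministic tie-breaks", {
  p <- signature_params(1, 1, filter_alpha = 1)
  sig <- make_signature(c(A = 5, B = 3, C = 1), p, "s1")
  expect_equal(sig$top, "A")
  expect_equal(sig$bottom, "C")
  tie <- make_signature(c(B = 5, A = 5, C = 1), signature_params(1, 0))
  expect_equal(tie$top, "A")                 # tie broken by ascending id
  expect_error(make_signature(c(A = 1, B = 2), signature_params(2, 1)),
               "exceeds")

  set.seed(5)
  for (i in 1:20) {
    prof <- setNames(runif(20), sprintf("P%02d", sample(20)))
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    if (n1 + n2 == 0) n2 <- 1
    sig <- make_signature(prof, signature_params(n1, n2))
    ids <- names(prof)[order(-prof, names(prof))]   # brute-force sort oracle
    expect_equal(sig$top, head(ids, n1))
    expect_equal(sig$bottom, if (n2 > 0) ids[(20 - n2 + 1):20] else character())
  }
})

test_that("signature distance is zero to self, one for reversed rankings, symmetric", {
  p <- signature_params(1, 1)
  ranking <- sprintf("P%d", 1:6)
  prof_a <- setNames(6:1, ranking)
  prof_b <- setNames(1:6, ranking)
  sa <- make_signature(prof_a, p, "a")
  sb <- make_signature(prof_b, p, "b")
  ra <- ranking
  rb <- rev(ranking)
  expect_equal(signature_distance(sa, ra, sa, ra), 0)
  expect_equal(signature_distance(sa, ra, sb, rb), 1)  # four ES terms all -1
  expect_error(signature_distance(sa, ra, sb, sprintf("Q%d", 1:6)),
               "different protein universes")

  set.seed(17)
  for (i in 1:15) {
    prof1 <- setNames(runif(12), sprintf("P%02d", 1:12))
    prof2 <- setNames(runif(12), sprintf("P%02d", 1:12))
    n1 <- sample(0:3, 1); n2 <- sample(1:3, 1)
    w <- sample(c(0, 1, 2), 1)
    pp <- signature_params(n1, n2)
    s1 <- make_signature(prof1, pp); r1 <- names(sort(-prof1))
    s2 <- make_signature(prof2, pp); r2 <- names(sort(-prof2))
    d12 <- signature_distance(s1, r1, s2, r2, w)
    expect_equal(d12, signature_distance(s2, r2, s1, r1, w))
    expect_equal(d12, distance_oracle(s1, r1, s2, r2, w), tolerance = 1e-12)
    expect_equal(signature_distance(s1, r1, s1, r1, w), 0)
  }
})

test_that("distance matrix is symmetric, zero-diagonal, bounded, oracle-consistent", {
  set.seed(23)
  n <- 30
  profs <- lapply(seq_len(n), function(i)
    setNames(runif(15), sprintf("P%02d", 1:15)))
  pp <- signature_params(2, 2)
  sigs <- lapply(seq_len(n), function(i)
    make_signature(profs[[i]], pp, sprintf("S%02d", i)))
  ranks <- lapply(profs, function(x) names(sort(-x)))
  D <- distance_matrix(sigs, ranks)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, n))
  expect_true(all(D >= 0 & D <= 1))
  for (idx in list(c(1, 2), c(5, 20), c(13, 29))) {
    expect_equal(D[idx[1], idx[2]],
                 distance_oracle(sigs[[idx[1]]], ranks[[idx[1]]],
                                 sigs[[idx[2]]], ranks[[idx[2]]], 1),
                 tolerance = 1e-12)
  }
  same <- distance_matrix(sigs[c(1, 1)], ranks[c(1, 1)])
  expect_equal(unname(same), matrix(0, 2, 2))
  expect_error(distance_matrix(sigs[1], ranks[1]), "at least 2")
})
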