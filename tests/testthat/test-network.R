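toy_network <- function(edges, directed = TRUE, tfs = character()) {
  interaction_network(matrix(edges, ncol = 2, byrow = TRUE),
                      directed = directed, tf_nodes = tfs)
}

test_that("differential calling matches Welch t-tests and recovers planted markers", {
  set.seed(4)
  vals <- matrix(2^rnorm(10 * 5, 10, 0.5), 10, 5,
                 dimnames = list(paste0("s", 1:10), paste0("P", 1:5)))
  ds <- tiny_dataset(vals, rep(c("control", "affected"), each = 5))
  tab <- attr(differential_proteins(ds), "table")
  L <- log2(vals)
  for (j in 1:5) {
    ref <- t.test(L[6:10, j], L[1:5, j])   # Welch by default
    expect_equal(tab$p[j], ref$p.value, tolerance = 1e-10)
    expect_equal(tab$estimate[j], unname(diff(rev(ref$estimate))), tolerance = 1e-10)
  }

  out <- generate_cohort(cohort_config(seed = 6))
  de <- differential_proteins(out$dataset)
  detab <- attr(de, "table")
  sens <- mean(detab$q[detab$protein %in% out$truth$marker_ids] < 0.05)
  fpr <- mean(detab$q[!(detab$protein %in% out$truth$marker_ids)] < 0.05)
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.05)
  expect_true(all(unname(out$truth$marker_genes[
    detab$protein[detab$q < 0.05 & detab$protein %in% out$truth$marker_ids]]) %in% de))

  const <- tiny_dataset(matrix(c(rep(2, 10), 2^rnorm(10, 10)), 10, 2,
                               dimnames = list(paste0("s", 1:10), c("C1", "P"))),
                        rep(c("control", "affected"), each = 5))
  expect_message(dc <- differential_proteins(const), "constant")
  expect_equal(attr(dc, "table")$p[1], 1)
})

test_that("TF paths prefer differentially expressed intermediates", {
  net <- toy_network(c("TF", "X", "TF", "Y", "X", "M", "Y", "M"), tfs = "TF")
  sub <- tf_subnetwork(net, "TF", targets = "M", de_set = "X")
  expect_equal(sub$paths$M, c("TF", "X", "M"))
  sub2 <- tf_subnetwork(net, "TF", targets = "M", de_set = "Y")
  expect_equal(sub2$paths$M, c("TF", "Y", "M"))
  # no DE information: lexicographic tie-break
  sub3 <- tf_subnetwork(net, "TF", targets = "M", de_set = character())
  expect_equal(sub3$paths$M, c("TF", "X", "M"))
  # direct successor: path of length 1, no intermediates
  sub4 <- tf_subnetwork(net, "TF", targets = "X", de_set = character())
  expect_equal(sub4$paths$X, c("TF", "X"))
  expect_error(tf_subnetwork(net, "NOPE", "M"), "absent")
  miss <- tf_subnetwork(net, "TF", targets = c("M", "GHOST"), de_set = "X")
  expect_equal(miss$unreachable, "GHOST")
})

test_that("chosen paths equal brute-force enumeration on random DAG-rich graphs", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 30
    g0 <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE)
    el <- igraph::as_edgelist(g0, names = FALSE)
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    labels <- sprintf("N%02d", seq_len(n))
    net <- interaction_network(cbind(labels[el[, 1]], labels[el[, 2]]),
                               directed = TRUE, tf_nodes = labels[1])
    de <- sample(labels, 8)
    targets <- sample(labels[-1], 5)
    sub <- tf_subnetwork(net, labels[1], targets, de)
    dists <- igraph::distances(net$graph, v = labels[1], mode = "out")[1, ]
    for (tgt in names(sub$paths)) {
      path <- sub$paths[[tgt]]
      expect_equal(length(path) - 1, unname(dists[tgt]))  # BFS-length paths
      cand <- igraph::all_shortest_paths(net$graph, from = labels[1], to = tgt,
                                         mode = "out")$vpaths
      score <- function(p) {
        nm <- igraph::V(net$graph)$name[as.integer(p)]
        sum(nm[-c(1, length(nm))] %in% de)
      }
      best <- max(vapply(cand, score, 1.0))
      expect_equal(score(igraph::V(net$graph)[path]), best)
      # lexicographic tie-break among maximal-DE paths
      seqs <- vapply(cand[vapply(cand, score, 1.0) == best], function(p)
        paste(igraph::V(net$graph)$name[as.integer(p)], collapse = "|"), "")
      expect_equal(paste(path, collapse = "|"), min(seqs))
    }
  }
})

test_that("regulator ranking attributes the planted pathway to the planted TF", {
  markers <- sprintf("G%02d", 1:20)
  strong <- markers[1:6]
  nets <- generate_network(n_nodes = 400, truth_markers = markers,
                           strong_markers = strong, seed = 21)
  gs <- generate_genesets(n_sets = 25, set_size_range = c(8, 25),
                          universe = network_nodes(nets$signaling),
                          planted_set = nets$truth$planted_pathway_genes,
                          seed = 22, planted_name = "PLANTED")
  de <- c(markers, nets$truth$de_intermediates)
  rr <- rank_regulators(nets$signaling, nets$truth$tf_list, markers, de, gs)
  expect_true("PLANTED" %in% rr$pathway)
  expect_equal(rr$regulator[rr$pathway == "PLANTED"],
               nets$truth$planted_regulator_tf)

  # invariant to input orderings
  rr2 <- rank_regulators(nets$signaling, rev(nets$truth$tf_list), markers, de,
                         geneset_collection(rev(gs$sets), source = gs$source))
  expect_equal(rr, rr2)
  expect_true(all(rr$p >= 0 & rr$p <= 1))
  expect_true(all(rr$overlap <= rr$subnetwork_size))

  far <- geneset_collection(list(ELSEWHERE = c("ZZZ1", "ZZZ2", "ZZZ3")))
  none <- rank_regulators(nets$signaling, nets$truth$tf_list, markers, de,
                          far, background = c(network_nodes(nets$signaling),
                                              c("ZZZ1", "ZZZ2", "ZZZ3")))
  expect_equal(nrow(none), 0)
})

test_that("overlap coefficient handles toys and the derived case", {
  expect_equal(pathway_overlap_coefficient(c("A", "B"), c("C", "D"))$coefficient, 0)
  expect_equal(pathway_overlap_coefficient(c("A", "B"), c("A", "B", "C"))$coefficient, 1)
  oc <- pathway_overlap_coefficient(c("A", "B", "C", "D"),
                                    c("A", "B", "X", "Y", "Z", "W"))
  expect_equal(oc$coefficient, 0.5)   # |A n B| = 2, min(4, 6) = 4
  expect_equal(oc$shared, 2)
  expect_error(pathway_overlap_coefficient(character(), "A"), "non-empty")
})

test_that("proximity statistic and empirical null follow hand-computed toys", {
  path_net <- toy_network(c("A", "B", "B", "C", "C", "D"), directed = FALSE)
  res <- proximity_empirical_p(path_net, "A", "D", n_random = 3, rng_seed = 1)
  expect_equal(res$d_obs, 3)
  expect_equal(res$p, 1)              # null distances 2, 1, 0 all <= 3
  expect_setequal(res$null_distances, c(2, 1, 0))

  star <- toy_network(c("S", "A", "S", "B", "S", "C", "C", "D"),
                      directed = FALSE)
  inside <- proximity_empirical_p(star, "S", c("S", "A"), n_random = 4,
                                  rng_seed = 1)
  expect_equal(inside$d_obs, 0)
  expect_equal(inside$p, mean(c("A", "B", "C", "D") %in% c("S", "A")))
  expect_error(proximity_empirical_p(path_net, "ZZ", "D"), "not in network")
  expect_error(proximity_empirical_p(path_net, "A", "QQ"), "no pathway gene")
  expect_error(proximity_empirical_p(path_net, "A", "D", n_random = 10),
               "exceeds")
})

test_that("the planted seed gene is closer to its pathway than random gene sets", {
  markers <- sprintf("G%02d", 1:20)
  nets <- generate_network(n_nodes = 400, truth_markers = markers,
                           strong_markers = markers[1:6], seed = 30)
  truth <- nets$truth
  res <- proximity_empirical_p(nets$ppi, truth$planted_seed_gene,
                               truth$planted_pathway_genes,
                               n_random = 300, rng_seed = 2)
  expect_equal(res$d_obs, truth$planted_seed_distance)
  set.seed(55)
  nodes <- setdiff(network_nodes(nets$ppi), truth$planted_seed_gene)
  p_rand <- vapply(1:15, function(i) {
    proximity_empirical_p(nets$ppi, truth$planted_seed_gene,
                          sample(nodes, length(truth$planted_pathway_genes)),
                          n_random = 300, rng_seed = i)$p
  }, 1.0)
  expect_lt(res$p, median(p_rand))
})

test_that("proximity p is valid (super-uniform) for random seed genes", {
  set.seed(61)
  g0 <- igraph::sample_pa(300, power = 1, m = 2, directed = FALSE)
  labels <- sprintf("N%03d", 1:300)
  el <- igraph::as_edgelist(g0, names = FALSE)
  net <- interaction_network(cbind(labels[el[, 1]], labels[el[, 2]]),
                             directed = FALSE)
  pathway <- sample(labels, 15)
  n_rep <- 200
  seeds <- sample(labels, n_rep, replace = TRUE)
  pvals <- vapply(seq_len(n_rep), function(i) {
    proximity_empirical_p(net, seeds[i], pathway, n_random = 100,
                          rng_seed = i)$p
  }, 1.0)
  tol <- 3 * sqrt(0.25 / n_rep)
  for (a in c(0.1, 0.25, 0.5, 0.75)) expect_lte(mean(pvals <= a), a + tol)
  expect_gt(mean(pvals), 0.3)
})
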