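#' Differentially abundant proteins between classes
#'
#' Per protein: two-sided Welch t-test on log2 abundances (affected vs
#' control), BH-corrected across all assay proteins. The DE set is the union
#' of gene symbols mapped by analytes with `q < alpha`; constant proteins
#' get `p = 1` and are counted in a message.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Character vector of DE gene symbols, with the per-protein test
#'   table (columns `protein`, `estimate` = log2 mean difference, `p`, `q`)
#'   attached as attribute `"table"`.
#' @export
differential_proteins <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"))
  grp <- dataset$class_label == "affected"
  if (!any(grp) || !any(!grp)) stop("both classes must be present")
  L <- log2(dataset$values)
  n1 <- sum(grp); n0 <- sum(!grp)
  m1 <- colMeans(L[grp, , drop = FALSE])
  m0 <- colMeans(L[!grp, , drop = FALSE])
  v1 <- apply(L[grp, , drop = FALSE], 2, var)
  v0 <- apply(L[!grp, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    message(sum(degenerate), " constant protein(s) assigned p = 1")
    p[degenerate] <- 1
  }
  q <- bh_adjust(p)
  de_assays <- dataset$protein_ids[q < alpha]
  genes <- mapped_genes(dataset, de_assays)
  structure(genes,
            table = data.frame(protein = dataset$protein_ids,
                               estimate = m1 - m0, p = p, q = q,
                               row.names = NULL, stringsAsFactors = FALSE))
}

# nodes lying on at least one shortest path tf -> target, given distances
# from the TF (mode out) and to the target (mode in)
shortest_path_dag_nodes <- function(d_from, d_to, d_target) {
  which(is.finite(d_from) & is.finite(d_to) & d_from + d_to == d_target)
}

#' Transcription-factor-rooted sub-network
#'
#' For each target reachable from the TF in the directed network, selects
#' among all minimum-length directed paths the one passing through the most
#' differentially expressed intermediate nodes (exact maximisation by
#' dynamic programming over the shortest-path DAG), breaking ties by
#' lexicographically smallest node sequence. The sub-network is the union
#' of the chosen paths.
#'
#' @param network a directed [interaction_network()].
#' @param tf transcription-factor gene symbol (must be a node).
#' @param targets gene symbols of interest (e.g. the biomarker panel);
#'   symbols absent from the network are recorded, not an error.
#' @param de_set character vector of differentially expressed gene symbols
#'   used for the path preference.
#' @return A list of class `tf_subnetwork`: `tf`, `nodes`, `edges`
#'   (two-column matrix), `paths` (named list of chosen node sequences),
#'   `unreachable`, `n_de` (DE nodes in the sub-network).
#' @export
tf_subnetwork <- function(network, tf, targets, de_set = character()) {
  stopifnot(inherits(network, "interaction_network"))
  if (!network$directed) stop("tf_subnetwork requires a directed network")
  g <- network$graph
  nodes <- igraph::V(g)$name
  tf <- toupper(tf)
  if (!(tf %in% nodes)) stop("TF '", tf, "' is absent from the network")
  targets <- unique(toupper(targets))
  de_set <- toupper(de_set)
  in_net <- targets[targets %in% nodes]
  absent <- setdiff(targets, in_net)
  in_net <- setdiff(in_net, tf)

  d_from <- igraph::distances(g, v = tf, mode = "out")[1, ]
  d_to_all <- igraph::distances(g, to = in_net, mode = "out")
  is_de <- setNames(nodes %in% de_set, nodes)
  adj_out <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")

  paths <- list()
  unreachable <- absent
  for (tgt in in_net) {
    d_tgt <- d_from[[tgt]]
    if (!is.finite(d_tgt)) { unreachable <- c(unreachable, tgt); next }
    d_to <- d_to_all[, tgt]
    on_path <- nodes[shortest_path_dag_nodes(d_from, d_to, d_tgt)]
    # backward DP over the shortest-path DAG: g_score(v) = max DE count
    # collectable strictly after v (interior nodes only, target excluded)
    g_score <- setNames(rep(-Inf, length(on_path)), on_path)
    g_score[tgt] <- 0
    depth <- d_from[on_path]
    for (dd in sort(unique(depth[depth < d_tgt]), decreasing = TRUE)) {
      for (v in on_path[depth == dd]) {
        succ <- intersect(nodes[as.integer(adj_out[[v]])], on_path)
        succ <- succ[d_from[succ] == d_from[[v]] + 1]
        if (!length(succ)) next
        gains <- ifelse(succ == tgt, 0, as.numeric(is_de[succ])) + g_score[succ]
        g_score[v] <- max(gains)
      }
    }
    # greedy reconstruction: highest remaining DE potential, then
    # lexicographically smallest next node
    cur <- tf
    path <- tf
    while (cur != tgt) {
      succ <- intersect(nodes[as.integer(adj_out[[cur]])], on_path)
      succ <- succ[d_from[succ] == d_from[[cur]] + 1]
      gain <- ifelse(succ == tgt, 0, as.numeric(is_de[succ])) + g_score[succ]
      succ <- succ[is.finite(gain)]
      gain <- gain[is.finite(gain)]
      best <- sort(succ[gain == max(gain)])[1]
      path <- c(path, best)
      cur <- best
    }
    paths[[tgt]] <- path
  }
  sub_nodes <- unique(c(tf, unlist(paths, use.names = FALSE)))
  edges <- do.call(rbind, lapply(paths, function(p)
    if (length(p) > 1) cbind(p[-length(p)], p[-1])))
  if (!is.null(edges)) edges <- unique(edges)
  structure(list(tf = tf, nodes = sub_nodes, edges = edges, paths = paths,
                 unreachable = unique(unreachable),
                 n_de = sum(sub_nodes %in% de_set)),
            class = "tf_subnetwork")
}

#' @export
print.tf_subnetwork <- function(x, ...) {
  cat(sprintf("tf_subnetwork rooted at %s: %d nodes (%d DE), %d targets reached, %d unreachable\n",
              x$tf, length(x$nodes), x$n_de, length(x$paths),
              length(x$unreachable)))
  invisible(x)
}

#' Rank regulators by network-based pathway over-representation
#'
#' Builds a TF-rooted sub-network per transcription factor, tests every
#' sub-network gene set against every pathway with a one-sided Fisher exact
#' test over the network gene universe, applies BH across all (TF, pathway)
#' tests, and attributes each BH-significant pathway to the TF with the
#' smallest raw p-value. The output is invariant to the order of `tf_list`
#' and of the collection.
#'
#' @param network directed [interaction_network()].
#' @param tf_list transcription-factor symbols (non-empty; symbols absent
#'   from the network are skipped).
#' @param targets biomarker gene symbols used to root the sub-networks.
#' @param de_set differentially expressed symbols for the path preference.
#' @param collection a [geneset_collection()] of pathways.
#' @param background gene universe for the Fisher tests (default: all
#'   network nodes).
#' @param q_threshold BH significance cutoff (default 0.05).
#' @return A data.frame sorted by `p`: `regulator`, `subnetwork_size`,
#'   `pathway`, `overlap`, `p`, `q`.
#' @export
rank_regulators <- function(network, tf_list, targets, de_set, collection,
                            background = NULL, q_threshold = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  tf_list <- sort(unique(toupper(tf_list)))
  if (!length(tf_list)) stop("tf_list is empty")
  nodes <- network_nodes(network)
  if (is.null(background)) background <- nodes
  background <- unique(toupper(background))
  tf_list <- tf_list[tf_list %in% nodes]
  subnets <- lapply(tf_list, function(tf)
    tf_subnetwork(network, tf, targets, de_set))
  names(subnets) <- tf_list
  reached <- vapply(subnets, function(s) length(s$paths) > 0, TRUE)
  if (!any(reached)) stop("no transcription factor reaches any target")
  subnets <- subnets[reached]

  N <- length(background)
  rows <- list()
  for (tf in names(subnets)) {
    G <- intersect(subnets[[tf]]$nodes, background)
    for (nm in sort(names(collection$sets))) {
      S <- intersect(collection$sets[[nm]], background)
      if (!length(S)) next
      k <- length(intersect(G, S))
      tab <- matrix(c(k, length(S) - k, length(G) - k,
                      N - length(S) - length(G) + k), 2, 2)
      rows[[length(rows) + 1L]] <-
        data.frame(regulator = tf, subnetwork_size = length(subnets[[tf]]$nodes),
                   pathway = nm, overlap = k,
                   p = fisher.test(tab, alternative = "greater")$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests))
    return(data.frame(regulator = character(), subnetwork_size = integer(),
                      pathway = character(), overlap = integer(),
                      p = numeric(), q = numeric()))
  tests$q <- bh_adjust(tests$p)
  sig_paths <- unique(tests$pathway[tests$q < q_threshold])
  out <- do.call(rbind, lapply(sort(sig_paths), function(nm) {
    cand <- tests[tests$pathway == nm, , drop = FALSE]
    cand <- cand[order(cand$p, cand$regulator), , drop = FALSE]
    cand[1, , drop = FALSE]
  }))
  if (is.null(out))
    return(data.frame(regulator = character(), subnetwork_size = integer(),
                      pathway = character(), overlap = integer(),
                      p = numeric(), q = numeric()))
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap coefficient between two gene sets
#'
#' @param set_a,set_b non-empty character vectors.
#' @return A list with `coefficient` = `|A n B| / min(|A|, |B|)` and
#'   `shared` = the overlap count.
#' @export
pathway_overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(toupper(set_a)); set_b <- unique(toupper(set_b))
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  shared <- length(intersect(set_a, set_b))
  list(coefficient = shared / min(length(set_a), length(set_b)),
       shared = shared)
}

#' Seed-gene to pathway proximity with an empirical null
#'
#' The observed statistic is the minimal unweighted shortest-path distance
#' from the seed gene to any in-network pathway member. The null draws
#' `n_random` genes uniformly without replacement from the network nodes
#' (seed excluded) and recomputes the same statistic; the empirical p-value
#' is the proportion of null genes at distance less than or equal to the
#' observed one. Unreachable nodes count as infinitely distant.
#'
#' @param ppi an undirected [interaction_network()].
#' @param seed_gene gene symbol (must be a node).
#' @param pathway_genes pathway member symbols; at least one must be in the
#'   network.
#' @param n_random null sample size (default 1000; must not exceed the
#'   number of candidate nodes).
#' @param rng_seed integer seed for the null draw.
#' @param exclude_pathway drop pathway members from the null candidates
#'   (default `FALSE`, i.e. random genes are drawn from the whole network).
#' @param plus_one add-one correction to the empirical proportion (default
#'   `FALSE`).
#' @return A list of class `proximity_result`: `seed_gene`, `d_obs`,
#'   `null_distances`, `p`, `n_random`, `rng_seed`.
#' @export
proximity_empirical_p <- function(ppi, seed_gene, pathway_genes,
                                  n_random = 1000, rng_seed = 1L,
                                  exclude_pathway = FALSE, plus_one = FALSE) {
  stopifnot(inherits(ppi, "interaction_network"))
  if (ppi$directed) stop("proximity analysis expects an undirected network")
  g <- ppi$graph
  nodes <- igraph::V(g)$name
  seed_gene <- toupper(seed_gene)
  if (!(seed_gene %in% nodes)) stop("seed gene '", seed_gene, "' not in network")
  pathway_genes <- unique(toupper(pathway_genes))
  in_net <- intersect(pathway_genes, nodes)
  if (!length(in_net)) stop("no pathway gene is present in the network")
  D <- igraph::distances(g, v = in_net, to = igraph::V(g))
  min_d <- apply(D, 2, min)
  names(min_d) <- nodes
  d_obs <- min_d[[seed_gene]]
  candidates <- setdiff(nodes, seed_gene)
  if (exclude_pathway) candidates <- setdiff(candidates, in_net)
  if (n_random > length(candidates))
    stop(sprintf("n_random = %d exceeds the %d candidate nodes",
                 n_random, length(candidates)))
  set.seed(as.integer(rng_seed))
  null_genes <- sample(candidates, n_random)
  null_d <- min_d[null_genes]
  add <- as.integer(isTRUE(plus_one))
  p <- (sum(null_d <= d_obs) + add) / (n_random + add)
  structure(list(seed_gene = seed_gene, d_obs = unname(d_obs),
                 null_distances = unname(null_d), p = p,
                 n_random = n_random, rng_seed = as.integer(rng_seed)),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity_result: %s at distance %s from pathway; empirical p = %.4g (n_random = %d)\n",
              x$seed_gene, format(x$d_obs), x$p, x$n_random))
  invisible(x)
}
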