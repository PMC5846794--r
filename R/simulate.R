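#' Configuration for the synthetic case/control cohort generator
#'
#' Defaults emulate the structure of an aptamer-based serum proteomics study
#' of Duchenne muscular dystrophy: 42 affected and 28 control subjects,
#' 1128 analytes, 52 planted differential proteins of which 6 separate the
#' classes completely, 31 proteins declining with age in affected subjects
#' only (two exceptional ones increasing), and 32 proteins shifted in the
#' steroid-treated subgroup (28 of 42 affected).
#'
#' @param n_control,n_affected,n_proteins cohort dimensions.
#' @param n_markers number of planted class-differential proteins.
#' @param effect_sizes range of |log2 shift| for ordinary markers.
#' @param n_strong_markers markers with non-overlapping class distributions
#'   (|log2 shift| at least 6 within-group SDs; half up-, half down-regulated).
#' @param baseline_mean_log2,baseline_sd_log2 per-protein baseline ranges on
#'   the log2 scale.
#' @param age_range_years uniform age range, drawn identically for both
#'   classes (age-matched design).
#' @param n_age_markers markers whose level drifts with age in affected
#'   subjects only; the first two drift upward, the rest downward.
#' @param age_slope_log2_per_year range of (negative) slopes, log2 units per
#'   year, applied around the midpoint of `age_range_years`.
#' @param treated_fraction_of_affected fraction of affected subjects treated.
#' @param n_treatment_markers markers shifted in treated affected subjects.
#' @param treatment_shift_log2 range of |log2 shift| for treatment markers
#'   (sign random).
#' @param seed integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 28, n_affected = 42, n_proteins = 1128,
                          n_markers = 52, effect_sizes = c(1.0, 2.5),
                          n_strong_markers = 6,
                          baseline_mean_log2 = c(8, 12),
                          baseline_sd_log2 = c(0.3, 0.8),
                          age_range_years = c(4, 15),
                          n_age_markers = 31,
                          age_slope_log2_per_year = c(-0.30, -0.08),
                          treated_fraction_of_affected = 28 / 42,
                          n_treatment_markers = 32,
                          treatment_shift_log2 = c(0.3, 0.8),
                          seed = 1L) {
  cfg <- list(n_control = n_control, n_affected = n_affected,
              n_proteins = n_proteins, n_markers = n_markers,
              effect_sizes = effect_sizes, n_strong_markers = n_strong_markers,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              age_range_years = age_range_years, n_age_markers = n_age_markers,
              age_slope_log2_per_year = age_slope_log2_per_year,
              treated_fraction_of_affected = treated_fraction_of_affected,
              n_treatment_markers = n_treatment_markers,
              treatment_shift_log2 = treatment_shift_log2, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_control < 1 || n_affected < 1 || n_proteins < 1)
      stop("cohort dimensions must be positive")
    if (n_markers > n_proteins)
      stop("n_markers exceeds n_proteins")
    if (n_strong_markers > n_markers)
      stop("n_strong_markers exceeds n_markers")
    if (n_age_markers > n_markers)
      stop("n_age_markers exceeds n_markers")
    if (n_treatment_markers > n_markers)
      stop("n_treatment_markers exceeds n_markers")
    if (treated_fraction_of_affected < 0 || treated_fraction_of_affected > 1)
      stop("treated_fraction_of_affected must be in [0, 1]")
    if (diff(effect_sizes) < 0 || effect_sizes[1] <= 0)
      stop("effect_sizes must be an increasing positive range")
  })
  invisible(cfg)
}

#' Generate a synthetic case/control proteomic cohort with ground truth
#'
#' Abundances are log-normal: on the log2 scale each protein has a Gaussian
#' baseline, markers get a signed class shift in affected subjects, age
#' markers an additional age-centered drift (affected only), treatment
#' markers a shift in treated affected subjects, plus residual Gaussian
#' noise. Ages are drawn identically for both classes. Strong markers
#' receive |shift| >= 6 within-group SDs so the classes do not overlap on
#' them.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (planted marker ids, signed effects, age/treatment marker ids
#'   with slopes/shifts, and the marker gene symbols).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_sub <- config$n_control + config$n_affected
  prot <- sprintf("SL%04d", seq_len(config$n_proteins))
  genes <- sprintf("G%04d", seq_len(config$n_proteins))
  gene_map <- as.list(genes)
  names(gene_map) <- prot
  # a couple of realistic annotation quirks: one multi-gene analyte and one
  # unannotated analyte, planted outside the marker set
  base_mu <- runif(config$n_proteins, config$baseline_mean_log2[1],
                   config$baseline_mean_log2[2])
  base_sd <- runif(config$n_proteins, config$baseline_sd_log2[1],
                   config$baseline_sd_log2[2])

  markers <- sort(sample.int(config$n_proteins, config$n_markers))
  strong <- sort(sample(markers, config$n_strong_markers))
  ordinary <- setdiff(markers, strong)

  effect <- numeric(config$n_proteins)
  # strong shifts clear 6 SDs at the top of the baseline-SD range, half in
  # each direction so both tails of the subject ranking are informative
  n_up <- ceiling(config$n_strong_markers / 2)
  strong_sign <- rep(c(1, -1), c(n_up, config$n_strong_markers - n_up))
  effect[strong] <- strong_sign *
    runif(config$n_strong_markers, 6 * config$baseline_sd_log2[2] + 0.1,
          6 * config$baseline_sd_log2[2] + 1.1)
  effect[ordinary] <- sample(c(-1, 1), length(ordinary), replace = TRUE) *
    runif(length(ordinary), config$effect_sizes[1], config$effect_sizes[2])

  age_markers <- sort(sample(markers, config$n_age_markers))
  age_slope <- numeric(config$n_proteins)
  age_slope[age_markers] <- runif(config$n_age_markers,
                                  config$age_slope_log2_per_year[1],
                                  config$age_slope_log2_per_year[2])
  if (config$n_age_markers >= 2)  # two exceptions drift upward with age
    age_slope[age_markers[1:2]] <- -age_slope[age_markers[1:2]]

  trt_markers <- sort(sample(markers, config$n_treatment_markers))
  trt_shift <- numeric(config$n_proteins)
  trt_shift[trt_markers] <- sample(c(-1, 1), config$n_treatment_markers, replace = TRUE) *
    runif(config$n_treatment_markers, config$treatment_shift_log2[1],
          config$treatment_shift_log2[2])

  subj <- c(sprintf("CTRL%02d", seq_len(config$n_control)),
            sprintf("CASE%02d", seq_len(config$n_affected)))
  cls <- rep(c("control", "affected"), c(config$n_control, config$n_affected))
  age <- runif(n_sub, config$age_range_years[1], config$age_range_years[2])
  n_treated <- round(config$treated_fraction_of_affected * config$n_affected)
  treated <- rep(FALSE, n_sub)
  treated[config$n_control + sample.int(config$n_affected, n_treated)] <- TRUE

  is_case <- as.numeric(cls == "affected")
  age_mid <- mean(config$age_range_years)
  L <- matrix(rnorm(n_sub * config$n_proteins), n_sub, config$n_proteins)
  L <- sweep(L, 2, base_sd, `*`)
  L <- sweep(L, 2, base_mu, `+`)
  L <- L + outer(is_case, effect)
  L <- L + outer(is_case * (age - age_mid), age_slope)
  L <- L + outer(as.numeric(treated), trt_shift)
  vals <- 2^L
  rownames(vals) <- subj
  colnames(vals) <- prot

  non_markers <- setdiff(seq_len(config$n_proteins), markers)
  if (length(non_markers) >= 2) {
    gene_map[[prot[non_markers[1]]]] <- c(genes[non_markers[1]], "GMULTI1", "GMULTI2")
    gene_map[[prot[non_markers[2]]]] <- character(0)
  }

  dataset <- expression_dataset(vals, cls, age, treated, gene_map)
  truth <- list(
    marker_ids = prot[markers],
    strong_marker_ids = prot[strong],
    effects = setNames(effect[markers], prot[markers]),
    age_marker_ids = prot[age_markers],
    age_slopes = setNames(age_slope[age_markers], prot[age_markers]),
    treatment_marker_ids = prot[trt_markers],
    treatment_shifts = setNames(trt_shift[trt_markers], prot[trt_markers]),
    marker_genes = setNames(genes[markers], prot[markers]),
    strong_marker_genes = setNames(genes[strong], prot[strong]),
    seed = config$seed)
  list(dataset = dataset, truth = truth)
}

#' Generate synthetic signaling and physical-interaction networks
#'
#' Builds a connected scale-free-like graph by preferential attachment. The
#' directed (signaling) copy orients each edge from the earlier-attached to
#' the later-attached node. One designated transcription factor is wired to
#' every strong marker gene through a dedicated length-2 path whose
#' intermediate node is flagged differentially expressed. The undirected
#' (physical interaction) copy additionally plants a seed gene attached at a
#' recorded shortest distance from the planted pathway members.
#'
#' @param n_nodes number of base nodes (gene symbols).
#' @param n_tfs number of transcription factors (drawn from early, hub-like
#'   nodes).
#' @param mean_degree target mean degree of the base graph.
#' @param truth_markers character vector of marker gene symbols that must be
#'   present as nodes; the strong markers to wire are passed separately.
#' @param strong_markers character vector (subset of `truth_markers`) wired
#'   to the planted TF at distance 2.
#' @param n_de_intermediates number of dedicated DE intermediate nodes used
#'   for the TF wiring (recycled if fewer than strong markers).
#' @param seed integer RNG seed.
#' @param seed_gene symbol of the proximity seed gene planted in the
#'   undirected copy (default `"DMD"`, dystrophin).
#' @param planted_distance shortest-path distance (edge count) from the seed
#'   gene to the nearest planted pathway member.
#' @return A list with `signaling` (directed [interaction_network()]),
#'   `ppi` (undirected copy with the planted seed gene) and `truth`
#'   (TF list, planted regulator, DE intermediates, planted pathway genes,
#'   seed gene and its recorded distance, node/edge counts).
#' @export
generate_network <- function(n_nodes = 500, n_tfs = 20, mean_degree = 4,
                             truth_markers = character(),
                             strong_markers = character(),
                             n_de_intermediates = 6, seed = 1L,
                             seed_gene = "DMD", planted_distance = 1L) {
  if (n_tfs >= n_nodes) stop("n_tfs must be smaller than n_nodes")
  m <- max(1L, round(mean_degree / 2))
  if (m >= n_nodes) stop("mean_degree infeasible for n_nodes")
  truth_markers <- toupper(truth_markers)
  strong_markers <- toupper(strong_markers)
  if (!all(strong_markers %in% truth_markers) && length(truth_markers))
    stop("strong_markers must be a subset of truth_markers")
  n_named <- n_tfs + length(truth_markers)
  if (n_named > n_nodes) stop("n_nodes too small for TFs plus markers")
  set.seed(as.integer(seed))

  g <- igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
  # name assignment: TFs on early (hub-like) nodes, markers on later nodes
  # that are not direct neighbours of the planted TF (so the planted TF
  # reaches strong markers at distance exactly 2 through its DE relays)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  planted_tf <- tfs[1]
  nodes <- character(n_nodes)
  nodes[seq_len(n_tfs)] <- tfs
  nb1 <- as.integer(igraph::neighbors(g, 1))
  candidates <- setdiff(seq((n_tfs + 1), n_nodes), nb1)
  if (length(candidates) < length(truth_markers))
    stop("n_nodes too small to place markers away from the planted TF")
  marker_pos <- sample(candidates, length(truth_markers))
  nodes[marker_pos] <- truth_markers
  rest <- which(nodes == "")
  nodes[rest] <- sprintf("N%04d", seq_along(rest))
  igraph::V(g)$name <- nodes

  el <- igraph::as_edgelist(g, names = FALSE)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1)]
  dir_el <- cbind(nodes[el[, 1]], nodes[el[, 2]])

  # dedicated DE relays from the planted TF to each strong marker
  relays <- sprintf("DEI%02d", seq_len(max(1L, n_de_intermediates)))
  extra <- NULL
  if (length(strong_markers)) {
    relay_of <- rep_len(relays, length(strong_markers))
    extra <- rbind(cbind(planted_tf, unique(relay_of)),
                   cbind(relay_of, strong_markers))
  }
  signaling <- interaction_network(rbind(dir_el, extra), directed = TRUE,
                                   tf_nodes = tfs,
                                   de_nodes = c(truth_markers,
                                                if (length(strong_markers)) relays))

  planted_pathway <- unique(c(strong_markers,
                              if (length(strong_markers)) rep_len(relays, length(strong_markers))))
  und_el <- rbind(cbind(nodes[el[, 1]], nodes[el[, 2]]), extra)
  if (length(planted_pathway)) {
    anchor <- planted_pathway[1]
    chain <- c(seed_gene,
               if (planted_distance > 1) sprintf("LINK%02d", seq_len(planted_distance - 1)),
               anchor)
    und_el <- rbind(und_el, cbind(chain[-length(chain)], chain[-1]))
  }
  ppi <- interaction_network(und_el, directed = FALSE,
                             de_nodes = c(truth_markers,
                                          if (length(strong_markers)) relays))
  recorded_distance <- NA_real_
  if (length(planted_pathway)) {
    d <- igraph::distances(ppi$graph, v = seed_gene,
                           to = intersect(planted_pathway, network_nodes(ppi)))
    recorded_distance <- min(d)
  }
  truth <- list(tf_list = tfs,
                planted_regulator_tf = planted_tf,
                de_intermediates = if (length(strong_markers)) unique(rep_len(relays, length(strong_markers))) else character(),
                planted_pathway_genes = planted_pathway,
                planted_seed_gene = seed_gene,
                planted_seed_distance = recorded_distance,
                n_nodes = igraph::vcount(signaling$graph),
                n_edges = igraph::ecount(signaling$graph),
                seed = as.integer(seed))
  list(signaling = signaling, ppi = ppi, truth = truth)
}

#' Generate a synthetic gene-set collection with one planted set
#'
#' @param n_sets number of uniform-random sets (in addition to the planted
#'   one).
#' @param set_size_range integer range of random set sizes.
#' @param universe character vector of gene symbols to draw from.
#' @param planted_set symbols forced into the planted set (padded with random
#'   members up to the lower end of `set_size_range` if smaller).
#' @param seed integer RNG seed.
#' @param planted_name name of the planted set.
#' @return A [geneset_collection()] with sets `RANDOM_001`, ... and the
#'   planted set.
#' @export
generate_genesets <- function(n_sets = 50, set_size_range = c(10, 40),
                              universe, planted_set = character(), seed = 1L,
                              planted_name = "PLANTED") {
  universe <- unique(toupper(universe))
  planted_set <- unique(toupper(planted_set))
  if (!all(planted_set %in% universe))
    stop("planted_set must be a subset of the universe")
  if (set_size_range[2] > length(universe))
    stop("set size range exceeds universe size")
  set.seed(as.integer(seed))
  sets <- list()
  if (n_sets > 0) {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(universe, k))
    names(sets) <- sprintf("RANDOM_%03d", seq_len(n_sets))
  }
  if (length(planted_set)) {
    pad <- max(0, set_size_range[1] - length(planted_set))
    padded <- c(planted_set,
                if (pad > 0) sample(setdiff(universe, planted_set), pad))
    sets[[planted_name]] <- padded
  }
  geneset_collection(sets, source = "synthetic")
}

#' Generate a synthetic tissue expression table with planted categories
#'
#' Plants genes that satisfy the rule set used for tissue-specificity
#' categorization (5x thresholds) with at least a 10% margin: tissue
#' enriched, group enriched (2-7 tissues), tissue enhanced, expressed in
#' all, not detected; remaining genes are constructed to fall in the
#' residual `mixed` class.
#'
#' @param n_genes total genes.
#' @param tissues character vector of tissue names (>= 2; >= 4 recommended).
#' @param category_quota named integer vector with any of
#'   `tissue_enriched`, `group_enriched`, `tissue_enhanced`,
#'   `expressed_in_all`, `not_detected`; the remainder becomes `mixed`.
#' @param seed integer RNG seed.
#' @param detection_threshold detection cutoff in expression units.
#' @param target_tissue optional tissue name forced as the elevated tissue
#'   for `tissue_enriched` genes (default: sampled per gene).
#' @param genes optional character vector of gene symbols to use as row
#'   names (length `n_genes`; default `TG0001`, `TG0002`, ...).
#' @return A list with `table` (a [tissue_expression_table()]) and `truth`
#'   (data.frame of gene, planted category and elevated tissue(s)).
#' @export
generate_tissue_table <- function(n_genes, tissues, category_quota, seed = 1L,
                                  detection_threshold = 1.0,
                                  target_tissue = NULL, genes = NULL) {
  tissues <- as.character(tissues)
  nt <- length(tissues)
  if (nt < 2) stop("at least 2 tissues required")
  quota <- setNames(rep(0L, 5), c("tissue_enriched", "group_enriched",
                                  "tissue_enhanced", "expressed_in_all",
                                  "not_detected"))
  unknown <- setdiff(names(category_quota), names(quota))
  if (length(unknown)) stop("unknown categories in quota: ",
                            paste(unknown, collapse = ", "))
  quota[names(category_quota)] <- as.integer(category_quota)
  if (sum(quota) > n_genes) stop("category quotas exceed n_genes")
  if (quota[["group_enriched"]] > 0 && nt < 3)
    stop("group_enriched requires at least 3 tissues")
  if (quota[["tissue_enhanced"]] > 0 && nt < 8)
    stop("tissue_enhanced planting requires at least 8 tissues")
  set.seed(as.integer(seed))
  thr <- detection_threshold

  if (is.null(genes)) genes <- sprintf("TG%04d", seq_len(n_genes))
  if (length(genes) != n_genes) stop("`genes` must have length n_genes")
  vals <- matrix(0, n_genes, nt,
                 dimnames = list(toupper(genes), tissues))
  cat_plan <- rep("mixed", n_genes)
  idx <- 1L
  take <- function(n) { out <- seq(idx, length.out = n); idx <<- idx + n; out }
  truth_tissue <- rep(NA_character_, n_genes)

  for (i in take(quota[["tissue_enriched"]])) {
    t1 <- if (is.null(target_tissue)) sample(nt, 1) else match(target_tissue, tissues)
    others <- runif(nt - 1, thr, 3 * thr)
    vals[i, -t1] <- others
    vals[i, t1] <- 5 * max(others) * runif(1, 1.12, 1.5)
    cat_plan[i] <- "tissue_enriched"
    truth_tissue[i] <- tissues[t1]
  }
  for (i in take(quota[["group_enriched"]])) {
    gmax <- min(7, nt - 1)
    gsz <- if (gmax >= 2) sample(2:gmax, 1) else stop("group size infeasible")
    grp <- sample(nt, gsz)
    rest <- runif(nt - gsz, thr, 2 * thr)
    vals[i, -grp] <- rest
    base <- 5 * max(rest) * 1.12
    vals[i, grp] <- runif(gsz, base, 1.9 * base)
    cat_plan[i] <- "group_enriched"
    truth_tissue[i] <- paste(sort(tissues[grp]), collapse = ";")
  }
  for (i in take(quota[["tissue_enhanced"]])) {
    t1 <- sample(nt, 1)
    prof <- runif(nt, 1.0 * thr, 1.5 * thr)
    third <- setdiff(seq_len(nt), t1)[1]
    prof[third] <- 2.5 * thr
    v_min <- (5.5 * (2.5 * thr + (nt - 3) * 1.25 * thr) / nt) /
      (1 - 5.5 * 1.25 / nt)
    if (v_min <= 0 || v_min > 45 * thr)
      stop("tissue_enhanced planting infeasible for this tissue count")
    v <- runif(1, max(v_min, 20 * thr), 48 * thr)
    second <- setdiff(seq_len(nt), c(t1, third))[1]
    prof[second] <- v / 4
    prof[t1] <- v
    vals[i, ] <- prof
    cat_plan[i] <- "tissue_enhanced"
    truth_tissue[i] <- tissues[t1]
  }
  for (i in take(quota[["expressed_in_all"]])) {
    vals[i, ] <- runif(nt, 1.12 * thr, 2 * thr)
    cat_plan[i] <- "expressed_in_all"
  }
  for (i in take(quota[["not_detected"]])) {
    vals[i, ] <- runif(nt, 0, 0.88 * thr)
    cat_plan[i] <- "not_detected"
  }
  while (idx <= n_genes) {        # residual genes constructed as 'mixed'
    i <- idx; idx <- idx + 1L
    k <- sample(seq_len(nt - 1), 1)
    det <- sample(nt, k)
    vals[i, det] <- runif(k, 1.12 * thr, 2.2 * thr)
    vals[i, -det] <- runif(nt - k, 0.55 * thr, 0.88 * thr)
  }
  list(table = tissue_expression_table(vals, detection_threshold = thr),
       truth = data.frame(gene = rownames(vals), category = cat_plan,
                          tissue = truth_tissue, stringsAsFactors = FALSE))
}

#' Write all synthetic inputs for a pipeline run to a directory
#'
#' Convenience wrapper: generates a cohort, networks, gene sets and a tissue
#' table under one seed and writes them in the package's file dialects plus
#' a `truth.json` ground-truth record.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [cohort_config()].
#' @param seed integer seed for the non-cohort generators.
#' @return Invisibly, the merged truth list.
#' @export
simulate_study <- function(out_dir, config = cohort_config(), seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  truth <- cohort$truth
  write_expression(cohort$dataset,
                   file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "phenotype.tsv"),
                   file.path(out_dir, "annotation.tsv"))
  nets <- generate_network(truth_markers = unname(truth$marker_genes),
                           strong_markers = unname(truth$strong_marker_genes),
                           seed = seed + 1L)
  write_network(nets$signaling, file.path(out_dir, "signaling_edges.tsv"),
                file.path(out_dir, "tfs.txt"))
  write_network(nets$ppi, file.path(out_dir, "ppi_edges.tsv"))
  truth <- c(truth, nets$truth)
  genesets <- generate_genesets(universe = network_nodes(nets$signaling),
                                planted_set = truth$planted_pathway_genes,
                                seed = seed + 2L)
  write_gmt(genesets, file.path(out_dir, "genesets.gmt"))
  set.seed(seed + 4L)
  tissue_genes <- unique(c(unname(truth$marker_genes),
                           sample(unlist(cohort$dataset$gene_map,
                                         use.names = FALSE), 150)))
  tis <- generate_tissue_table(n_genes = length(tissue_genes),
                               tissues = sprintf("tissue%02d", 1:10),
                               category_quota = c(tissue_enriched = 15,
                                                  group_enriched = 15,
                                                  tissue_enhanced = 15,
                                                  expressed_in_all = 60,
                                                  not_detected = 25),
                               seed = seed + 3L,
                               genes = sample(tissue_genes))
  write_tissue_table(tis$table, file.path(out_dir, "tissue.tsv"))
  truth$tissue_truth <- tis$truth
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
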