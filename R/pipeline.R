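default_run_config <- function() {
  list(
    simulate = list(enabled = TRUE, seed = 1L, n_control = 28L,
                    n_affected = 42L, n_proteins = 1128L, n_markers = 52L,
                    n_strong_markers = 6L, n_age_markers = 31L,
                    n_treatment_markers = 32L),
    inputs = list(matrix = NULL, phenotype = NULL, annotation = NULL,
                  signaling = NULL, tfs = NULL, ppi = NULL, gmt = NULL,
                  tissue = NULL),
    classifier = list(k = 5L, weight_exponent = 1, foldchange_preprocess = TRUE,
                      a_min = 0.98, population_size = 40L, generations = 60L,
                      seed = 11L),
    permutation = list(B = 1000L, seed = 12L),
    covariates = list(alpha = 0.05),
    enrichment = list(alpha = 0.05),
    network = list(de_alpha = 0.05, q_threshold = 0.05,
                   n_random = 1000L, seed = 13L, seed_gene = "DMD"),
    out_dir = "results"
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]],
                                     as.list(user[[nm]]),
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate a workflow configuration file
#'
#' Reads a YAML configuration, fills defaults (5 folds, 1000 permutations,
#' 1000 random proximity genes), and rejects unknown keys. When
#' `simulate.enabled` is false, every referenced input path must exist.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  if (!isTRUE(cfg$simulate$enabled)) {
    needed <- c("matrix", "phenotype", "signaling", "tfs", "ppi", "gmt")
    for (nm in needed) {
      if (is.null(cfg$inputs[[nm]]))
        stop("input path '", nm, "' is required when simulate.enabled is false")
      if (!file.exists(cfg$inputs[[nm]]))
        stop("input file not found: ", cfg$inputs[[nm]], " (", nm, ")")
    }
  }
  structure(cfg, class = "run_config")
}

stage_msg <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full biomarker + network workflow
#'
#' Executes the stages in dependency order: simulate (or load) the inputs,
#' optimize the short and long biomarker panels, run the permutation test on
#' the long-panel parameters, screen covariates (age, treatment, age
#' distribution), perform gene-set and tissue enrichment of the long panel,
#' extract TF-rooted sub-networks with pathway attribution, and test
#' seed-gene proximity. Every stage writes its table under `out_dir` and the
#' run report aggregates the headline numbers together with every seed and
#' threshold used.
#'
#' @param config a `run_config` from [validate_config()].
#' @param verbose emit stage-tagged progress messages (default `TRUE`).
#' @return The run report (list), invisibly; also written as
#'   `report.json` under `out_dir`.
#' @export
run_workflow <- function(config = validate_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), package_version =
                   as.character(utils::packageVersion("serosig")))

  if (isTRUE(config$simulate$enabled)) {
    stage_msg(verbose, "simulate", "generating synthetic study (seed %d)",
              config$simulate$seed)
    sim_dir <- file.path(out, "inputs")
    sim <- config$simulate
    truth <- simulate_study(sim_dir,
                            cohort_config(n_control = sim$n_control,
                                          n_affected = sim$n_affected,
                                          n_proteins = sim$n_proteins,
                                          n_markers = sim$n_markers,
                                          n_strong_markers = sim$n_strong_markers,
                                          n_age_markers = sim$n_age_markers,
                                          n_treatment_markers = sim$n_treatment_markers,
                                          seed = sim$seed))
    config$inputs <- list(matrix = file.path(sim_dir, "expression.tsv"),
                          phenotype = file.path(sim_dir, "phenotype.tsv"),
                          annotation = file.path(sim_dir, "annotation.tsv"),
                          signaling = file.path(sim_dir, "signaling_edges.tsv"),
                          tfs = file.path(sim_dir, "tfs.txt"),
                          ppi = file.path(sim_dir, "ppi_edges.tsv"),
                          gmt = file.path(sim_dir, "genesets.gmt"),
                          tissue = file.path(sim_dir, "tissue.tsv"))
    config$network$seed_gene <- truth$planted_seed_gene
  }
  inp <- config$inputs
  report$input_md5 <- vapply(Filter(Negate(is.null), inp),
                             function(f) unname(tools::md5sum(f)), "")

  stage_msg(verbose, "load", "reading expression data")
  dataset <- read_expression(inp$matrix, inp$phenotype, inp$annotation)

  cl <- config$classifier
  stage_msg(verbose, "optimize", "short-mode genetic search")
  short <- optimize_parameters(dataset,
                               ga_config(mode = "short", seed = cl$seed,
                                         population_size = cl$population_size,
                                         generations = cl$generations,
                                         a_min = cl$a_min),
                               k = cl$k, weight_exponent = cl$weight_exponent,
                               foldchange_preprocess = cl$foldchange_preprocess)
  stage_msg(verbose, "optimize", "long-mode genetic search")
  long <- optimize_parameters(dataset,
                              ga_config(mode = "long", seed = cl$seed,
                                        population_size = cl$population_size,
                                        generations = cl$generations,
                                        a_min = cl$a_min),
                              k = cl$k, weight_exponent = cl$weight_exponent,
                              foldchange_preprocess = cl$foldchange_preprocess)
  write_panel <- function(res, file) {
    genes <- vapply(dataset$gene_map[res$panel$protein_ids], paste, "",
                    collapse = ";")
    write.table(data.frame(assay_id = res$panel$protein_ids,
                           gene_symbols = unname(genes),
                           n_contributing = vapply(res$panel$contributing[res$panel$protein_ids],
                                                   length, 1L)),
                file.path(out, file), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_panel(short, "panel_short.tsv")
  write_panel(long, "panel_long.tsv")

  stage_msg(verbose, "permutation", "B = %d label permutations", config$permutation$B)
  perm <- permutation_test(dataset, long$params, k = cl$k,
                           B = config$permutation$B,
                           seed = config$permutation$seed)

  stage_msg(verbose, "covariates", "age and treatment screens on the long panel")
  panel_ids <- long$panel$protein_ids
  age_tab <- age_association(dataset, group = "both", proteins = panel_ids)
  trt_tab <- treatment_association(dataset, proteins = panel_ids)
  ks <- ks_age_compare(dataset$age[dataset$class_label == "affected"],
                       dataset$age[dataset$class_label == "control"])
  write.table(age_tab, file.path(out, "age_association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(trt_tab, file.path(out, "treatment_association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stage_msg(verbose, "enrichment", "gene-set over-representation")
  collection <- read_gmt(inp$gmt)
  background <- mapped_genes(dataset)
  panel_genes <- mapped_genes(dataset, panel_ids)
  ora <- ora_hypergeometric(panel_genes, collection, background)
  write.table(ora, file.path(out, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tissue_tab <- NULL
  if (!is.null(inp$tissue)) {
    tis <- read_tissue_table(inp$tissue)
    cats <- classify_tissue_specificity(tis)
    bg_t <- intersect(background, cats$gene)
    tissue_tab <- fisher_tissue_enrichment(intersect(panel_genes, bg_t),
                                           bg_t, cats)
    write.table(tissue_tab, file.path(out, "tissue_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  stage_msg(verbose, "network", "TF sub-networks and pathway attribution")
  signaling <- read_network(inp$signaling, directed = TRUE,
                            tf_list_path = inp$tfs)
  de_genes <- differential_proteins(dataset, alpha = config$network$de_alpha)
  tfs <- network_nodes(signaling)[igraph::V(signaling$graph)$is_tf]
  regulators <- rank_regulators(signaling, tfs, panel_genes, de_genes,
                                collection,
                                q_threshold = config$network$q_threshold)
  write.table(regulators, file.path(out, "regulators.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  overlap_map <- NULL
  sig_paths <- unique(regulators$pathway)
  if (length(sig_paths) >= 2) {
    pairs <- utils::combn(sort(sig_paths), 2)
    overlap_map <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      oc <- pathway_overlap_coefficient(collection$sets[[pairs[1, j]]],
                                        collection$sets[[pairs[2, j]]])
      data.frame(set_a = pairs[1, j], set_b = pairs[2, j],
                 coefficient = oc$coefficient, shared = oc$shared)
    }))
    write.table(overlap_map, file.path(out, "overlap_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  stage_msg(verbose, "proximity", "seed-gene distance null (n_random = %d)",
            config$network$n_random)
  ppi <- read_network(inp$ppi, directed = FALSE)
  prox <- NULL
  if (nrow(regulators) > 0) {
    top_pathway <- regulators$pathway[1]
    n_random <- min(config$network$n_random,
                    length(network_nodes(ppi)) - 1L)
    prox <- proximity_empirical_p(ppi, config$network$seed_gene,
                                  collection$sets[[top_pathway]],
                                  n_random = n_random,
                                  rng_seed = config$network$seed)
    prox_out <- list(seed_gene = prox$seed_gene, pathway = top_pathway,
                     d_obs = prox$d_obs, p = prox$p, n_random = prox$n_random)
    jsonlite::write_json(prox_out, file.path(out, "proximity.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- c(report, list(
    short_panel_size = length(short$panel$protein_ids),
    short_accuracy = short$cv$mean_accuracy,
    short_params = unclass(short$params),
    long_panel_size = length(long$panel$protein_ids),
    long_accuracy = long$cv$mean_accuracy,
    long_params = unclass(long$params),
    permutation_p = perm$p_value,
    ks_age = ks,
    n_age_significant = sum(age_tab$q < config$covariates$alpha &
                              age_tab$group == "affected"),
    n_treatment_significant = sum(trt_tab$q < config$covariates$alpha),
    n_de_genes = length(de_genes),
    significant_pathways = sig_paths,
    proximity = if (!is.null(prox)) list(d_obs = prox$d_obs, p = prox$p)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  stage_msg(verbose, "done", "report written to %s", file.path(out, "report.json"))
  invisible(report)
}
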