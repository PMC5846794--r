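#' @useDynLib serosig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats p.adjust phyper pnorm pwilcox fisher.test ks.test
#'   pt qnorm runif rnorm setNames var median
#' @importFrom utils read.delim write.table head
NULL

#' Construct a validated expression dataset
#'
#' The container consumed by every pipeline stage: a subjects x proteins
#' matrix of positive abundances (relative fluorescence-like units), a
#' phenotype table and an assay -> gene symbol map.
#'
#' @param values numeric matrix, subjects in rows (rownames = subject ids),
#'   proteins in columns (colnames = assay ids). All entries must be finite
#'   and strictly positive.
#' @param class_label character/factor, one of `"control"`/`"affected"` per
#'   subject, in row order of `values`.
#' @param age numeric, nonnegative age in years per subject.
#' @param treated logical per subject; meaningful for affected subjects only.
#' @param gene_map named list mapping each assay id to a character vector of
#'   uppercase gene symbols (possibly empty for unannotated analytes). If
#'   `NULL`, every assay id maps to itself.
#' @return An object of class `expression_dataset` with fields `values`,
#'   `subject_ids`, `protein_ids`, `class_label`, `age`, `treated`,
#'   `gene_map`.
#' @export
expression_dataset <- function(values, class_label, age, treated = NULL,
                               gene_map = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (subjects x proteins)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry subject rownames and protein colnames")
  subj <- rownames(values)
  prot <- colnames(values)
  if (anyDuplicated(subj)) stop("duplicate subject ids: ",
                                paste(unique(subj[duplicated(subj)]), collapse = ", "))
  if (anyDuplicated(prot)) stop("duplicate protein ids: ",
                                paste(unique(prot[duplicated(prot)]), collapse = ", "))
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive or missing abundance at subject '%s', protein '%s'",
                 subj[bad[1, 1]], prot[bad[1, 2]]))
  class_label <- as.character(class_label)
  if (length(class_label) != length(subj))
    stop("`class_label` must have one entry per subject")
  if (!all(class_label %in% c("control", "affected")))
    stop("class labels must be 'control' or 'affected'; got: ",
         paste(setdiff(unique(class_label), c("control", "affected")), collapse = ", "))
  age <- as.numeric(age)
  if (length(age) != length(subj) || anyNA(age) || any(age < 0))
    stop("`age` must be a nonnegative numeric vector, one entry per subject")
  if (is.null(treated)) treated <- rep(FALSE, length(subj))
  treated <- as.logical(treated)
  if (length(treated) != length(subj) || anyNA(treated))
    stop("`treated` must be a logical vector, one entry per subject")
  if (is.null(gene_map)) {
    gene_map <- as.list(toupper(prot))
    names(gene_map) <- prot
  }
  if (!all(prot %in% names(gene_map)))
    stop("gene_map is missing assay ids: ",
         paste(head(setdiff(prot, names(gene_map)), 5), collapse = ", "))
  gene_map <- lapply(gene_map[prot], function(g) toupper(as.character(g)))
  structure(list(values = values,
                 subject_ids = subj,
                 protein_ids = prot,
                 class_label = setNames(class_label, subj),
                 age = setNames(age, subj),
                 treated = setNames(treated, subj),
                 gene_map = gene_map),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$class_label)
  cat(sprintf("expression_dataset: %d subjects (%d control / %d affected), %d proteins\n",
              length(x$subject_ids),
              if ("control" %in% names(tab)) tab[["control"]] else 0L,
              if ("affected" %in% names(tab)) tab[["affected"]] else 0L,
              length(x$protein_ids)))
  cat(sprintf("  age range %.1f-%.1f y; %d treated\n",
              min(x$age), max(x$age), sum(x$treated)))
  invisible(x)
}

#' Subset an expression dataset by subjects and/or proteins
#'
#' @param dataset an `expression_dataset`.
#' @param subjects,proteins character vectors of ids to keep (default: all).
#' @return An `expression_dataset` restricted to the requested ids.
#' @export
subset_dataset <- function(dataset, subjects = NULL, proteins = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(subjects)) subjects <- dataset$subject_ids
  if (is.null(proteins)) proteins <- dataset$protein_ids
  missing_s <- setdiff(subjects, dataset$subject_ids)
  if (length(missing_s)) stop("unknown subjects: ", paste(missing_s, collapse = ", "))
  missing_p <- setdiff(proteins, dataset$protein_ids)
  if (length(missing_p)) stop("unknown proteins: ", paste(missing_p, collapse = ", "))
  expression_dataset(dataset$values[subjects, proteins, drop = FALSE],
                     dataset$class_label[subjects],
                     dataset$age[subjects],
                     dataset$treated[subjects],
                     dataset$gene_map[proteins])
}

#' Map assay ids to unique gene symbols
#'
#' Multi-gene analytes contribute every mapped symbol; unannotated analytes
#' (empty gene_map entry) are dropped.
#'
#' @param dataset an `expression_dataset`.
#' @param proteins assay ids to map (default: all).
#' @return Character vector of unique uppercase gene symbols.
#' @export
mapped_genes <- function(dataset, proteins = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(proteins)) proteins <- dataset$protein_ids
  out <- unlist(dataset$gene_map[proteins], use.names = FALSE)
  unique(as.character(if (is.null(out)) character(0) else out))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols; symbols are
#'   uppercased and deduplicated, set names must be unique and every set
#'   non-empty.
#' @param source tag describing the provenance of the collection
#'   (e.g. `"hallmark"`, `"KEGG"`, `"synthetic"`).
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, source = "unspecified") {
  if (!is.list(sets)) stop("`sets` must be a named list")
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set must be named")
    if (anyDuplicated(names(sets)))
      stop("duplicate set names: ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  empty <- names(sets)[vapply(sets, length, 1L) == 0]
  if (length(empty)) stop("empty gene sets: ", paste(empty, collapse = ", "))
  structure(list(sets = sets, source = source), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, 1L)
  cat(sprintf("geneset_collection [%s]: %d sets, sizes %s-%s\n", x$source,
              length(x$sets),
              if (length(sz)) min(sz) else 0, if (length(sz)) max(sz) else 0))
  invisible(x)
}

#' Construct an interaction network
#'
#' A gene-symbol graph, directed (signaling) or undirected (physical
#' interactions), with transcription-factor and differential-abundance node
#' flags. Self-loops and duplicate edges are removed.
#'
#' @param edges two-column character matrix or data.frame of gene symbols
#'   (from, to); symbols are uppercased.
#' @param directed logical.
#' @param tf_nodes character vector of transcription-factor symbols; symbols
#'   absent from the node set are ignored with a warning.
#' @param de_nodes character vector of differentially-abundant symbols;
#'   absent symbols are silently ignored (the DE set usually comes from a
#'   wider assay universe than the network).
#' @return An object of class `interaction_network` wrapping an
#'   `igraph` graph with vertex attributes `is_tf` and `is_de`.
#' @export
interaction_network <- function(edges, directed, tf_nodes = character(),
                                de_nodes = character()) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  if (nrow(edges) == 0) stop("edge list is empty")
  mode(edges) <- "character"
  edges[] <- toupper(edges)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
    if (nrow(edges) == 0) stop("edge list is empty after dropping self-loops")
  }
  g <- igraph::graph_from_edgelist(edges, directed = directed)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  nodes <- igraph::V(g)$name
  tf_nodes <- toupper(tf_nodes)
  missing_tf <- setdiff(tf_nodes, nodes)
  if (length(missing_tf))
    warning("TF symbols absent from network ignored: ",
            paste(head(missing_tf, 5), collapse = ", "),
            if (length(missing_tf) > 5) ", ...")
  igraph::V(g)$is_tf <- nodes %in% tf_nodes
  igraph::V(g)$is_de <- nodes %in% toupper(de_nodes)
  structure(list(graph = g, directed = directed), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("interaction_network (%s): %d nodes, %d edges, %d TFs, %d DE-flagged\n",
              if (x$directed) "directed" else "undirected",
              igraph::vcount(g), igraph::ecount(g),
              sum(igraph::V(g)$is_tf), sum(igraph::V(g)$is_de)))
  invisible(x)
}

#' Node symbols of an interaction network
#' @param network an `interaction_network`.
#' @return Character vector of node gene symbols.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::V(network$graph)$name
}

#' Construct a tissue expression table
#'
#' @param values numeric genes x tissues matrix of nonnegative
#'   transcript-abundance values (rownames = gene symbols, uppercased;
#'   colnames = tissue names). At least 2 tissues are required.
#' @param detection_threshold expression level at or above which a gene
#'   counts as detected in a tissue (same units as `values`).
#' @return An object of class `tissue_expression_table`.
#' @export
tissue_expression_table <- function(values, detection_threshold = 1.0) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric genes x tissues matrix")
  if (ncol(values) < 2) stop("at least 2 tissues are required")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and tissue colnames")
  if (anyNA(values) || any(values < 0)) stop("tissue expression values must be nonnegative")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols in tissue table")
  if (!is.numeric(detection_threshold) || detection_threshold < 0)
    stop("`detection_threshold` must be a nonnegative number")
  structure(list(values = values, detection_threshold = detection_threshold),
            class = "tissue_expression_table")
}

#' @export
print.tissue_expression_table <- function(x, ...) {
  cat(sprintf("tissue_expression_table: %d genes x %d tissues (detection threshold %g)\n",
              nrow(x$values), ncol(x$values), x$detection_threshold))
  invisible(x)
}
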