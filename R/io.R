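#' Read an expression dataset from delimited text files
#'
#' The abundance matrix has a header row of assay ids and a first column of
#' subject ids. The phenotype table has columns `subject`, `class`, `age`,
#' `treated`. The annotation table has columns `assay_id`, `uniprot`,
#' `gene_symbols` (semicolon-separated symbols; empty for unannotated
#' analytes). Every subject in the matrix must appear in the phenotype table.
#'
#' @param matrix_path,phenotype_path,annotation_path file paths.
#' @param sep field separator (default tab).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, phenotype_path, annotation_path = NULL,
                            sep = "\t") {
  raw <- read.delim(matrix_path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) stop("expression matrix needs a subject column plus >=1 protein column")
  subj <- raw[[1]]
  prot <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric abundance '%s' at subject '%s', protein '%s'",
                 vals[bad[1, 1], bad[1, 2]], subj[bad[1, 1]], prot[bad[1, 2]]))
  bad <- which(is.na(num) | num <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("missing or non-positive abundance at subject '%s', protein '%s'",
                 subj[bad[1, 1]], prot[bad[1, 2]]))
  rownames(num) <- subj
  colnames(num) <- prot

  ph <- read.delim(phenotype_path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  need <- c("subject", "class", "age", "treated")
  if (!all(need %in% colnames(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ph$subject))
    stop("duplicate subject ids in phenotype table")
  absent <- setdiff(subj, ph$subject)
  if (length(absent))
    stop("subjects present in matrix but absent from phenotype table: ",
         paste(head(absent, 5), collapse = ", "))
  ph <- ph[match(subj, ph$subject), ]
  age <- suppressWarnings(as.numeric(ph$age))
  if (anyNA(age)) stop("non-numeric age for subject '", ph$subject[which(is.na(age))[1]], "'")
  treated <- ph$treated %in% c("TRUE", "true", "1", "yes")
  bad_treat <- !(ph$treated %in% c("TRUE", "true", "1", "yes", "FALSE", "false", "0", "no"))
  if (any(bad_treat))
    stop("unparseable treated flag '", ph$treated[which(bad_treat)[1]], "'")

  gene_map <- NULL
  if (!is.null(annotation_path)) {
    an <- read.delim(annotation_path, sep = sep, header = TRUE,
                     check.names = FALSE, colClasses = "character")
    if (!all(c("assay_id", "gene_symbols") %in% colnames(an)))
      stop("annotation table must have columns assay_id, gene_symbols")
    if (anyDuplicated(an$assay_id)) stop("duplicate assay ids in annotation table")
    gene_map <- lapply(an$gene_symbols, function(s) {
      s <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      toupper(s[nzchar(s)])
    })
    names(gene_map) <- an$assay_id
    absent <- setdiff(prot, an$assay_id)
    if (length(absent))
      stop("assay ids missing from annotation: ", paste(head(absent, 5), collapse = ", "))
  }
  expression_dataset(num, ph$class, age, treated, gene_map)
}

#' Write an expression dataset to delimited text files
#'
#' Inverse of [read_expression()]: values are written with full precision so
#' a write/read round trip reproduces the dataset bit for bit.
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,phenotype_path,annotation_path output paths
#'   (`annotation_path = NULL` skips the annotation table).
#' @param sep field separator.
#' @return Invisibly, `dataset`.
#' @export
write_expression <- function(dataset, matrix_path, phenotype_path,
                             annotation_path = NULL, sep = "\t") {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(subject = dataset$subject_ids,
                   format(dataset$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("subject", dataset$protein_ids)
  write.table(df, matrix_path, sep = sep, quote = FALSE, row.names = FALSE)
  ph <- data.frame(subject = dataset$subject_ids,
                   class = unname(dataset$class_label),
                   age = format(unname(dataset$age), digits = 17, trim = TRUE),
                   treated = unname(dataset$treated))
  write.table(ph, phenotype_path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    an <- data.frame(assay_id = dataset$protein_ids,
                     uniprot = "",
                     gene_symbols = vapply(dataset$gene_map, paste, "", collapse = ";"))
    write.table(an, annotation_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(dataset)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member symbols. Symbols are uppercased and duplicates
#' within a set collapsed.
#'
#' @param path GMT file path.
#' @param source provenance tag stored on the collection.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(geneset_collection(list(), source = source))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  geneset_collection(sets, source = source)
}

#' Write a gene-set collection to a GMT file
#' @param collection a `geneset_collection`.
#' @param path output path.
#' @return Invisibly, `collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}

#' Read an interaction network from an edge-list file
#'
#' Two-column tab-separated edge list (a third relation-tag column, as in SIF
#' files, is ignored). Self-loops are dropped with a message. Optionally a
#' transcription-factor list (one symbol per line) flags TF nodes.
#'
#' @param path edge-list path.
#' @param directed logical; signaling networks are directed, physical
#'   interaction networks undirected.
#' @param tf_list_path optional path of TF symbols, one per line.
#' @param sep field separator.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, directed, tf_list_path = NULL, sep = "\t") {
  if (!file.exists(path)) stop("edge file not found: ", path)
  if (length(readLines(path, n = 1, warn = FALSE)) == 0)
    stop("edge file is empty: ", path)
  raw <- read.delim(path, sep = sep, header = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0) stop("edge file is empty")
  if (ncol(raw) < 2) stop("edge file needs at least two columns")
  tfs <- character()
  if (!is.null(tf_list_path)) {
    tfs <- trimws(readLines(tf_list_path, warn = FALSE))
    tfs <- tfs[nzchar(tfs)]
  }
  interaction_network(raw[, 1:2], directed = directed, tf_nodes = tfs)
}

#' Write an interaction network edge list (and optional TF list)
#' @param network an `interaction_network`.
#' @param path output edge-list path.
#' @param tf_list_path optional output path for the TF symbols.
#' @param sep field separator.
#' @return Invisibly, `network`.
#' @export
write_network <- function(network, path, tf_list_path = NULL, sep = "\t") {
  stopifnot(inherits(network, "interaction_network"))
  el <- igraph::as_edgelist(network$graph)
  write.table(el, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(tf_list_path)) {
    nodes <- igraph::V(network$graph)
    writeLines(nodes$name[nodes$is_tf], tf_list_path)
  }
  invisible(network)
}

#' Read a tissue expression table
#'
#' Genes x tissues TSV with a header of tissue names and a first column of
#' gene symbols.
#'
#' @param path file path.
#' @param detection_threshold detection cutoff in expression units.
#' @param sep field separator.
#' @return A [tissue_expression_table()].
#' @export
read_tissue_table <- function(path, detection_threshold = 1.0, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (ncol(raw) < 3) stop("tissue table needs a gene column plus >=2 tissues")
  genes <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("tissue table contains non-numeric values")
  rownames(vals) <- genes
  tissue_expression_table(vals, detection_threshold = detection_threshold)
}

#' Write a tissue expression table
#' @param table a `tissue_expression_table`.
#' @param path output path.
#' @param sep field separator.
#' @return Invisibly, `table`.
#' @export
write_tissue_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "tissue_expression_table"))
  df <- data.frame(gene = rownames(table$values),
                   format(table$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("gene", colnames(table$values))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(table)
}
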