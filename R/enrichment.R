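#' Tissue-specificity categorization
#'
#' Applies rule-based categories derived from cross-tissue expression ratios
#' with a 5x threshold, in precedence order: `tissue_enriched` (one tissue
#' at least 5x all other tissues), `group_enriched` (smallest qualifying
#' group of 2-7 tissues, each at least 5x all remaining tissues),
#' `tissue_enhanced` (one tissue at least 5x the mean across all tissues),
#' `expressed_in_all` (detected everywhere), `not_detected` (detected
#' nowhere), `mixed` (residual). A tissue counts as detected at or above the
#' table's detection threshold, and the elevated tissue of the rule-based
#' categories must itself be detected.
#'
#' @param table a [tissue_expression_table()].
#' @return A data.frame with one row per gene: `gene`, `category`, `tissue`
#'   (the elevated tissue, semicolon-joined for groups, `NA` otherwise).
#' @export
classify_tissue_specificity <- function(table) {
  stopifnot(inherits(table, "tissue_expression_table"))
  vals <- table$values
  thr <- table$detection_threshold
  nt <- ncol(vals)
  tissues <- colnames(vals)
  res <- vapply(seq_len(nrow(vals)), function(i) {
    v <- vals[i, ]
    ord <- order(-v, tissues)
    vs <- v[ord]
    det <- v >= thr
    if (vs[1] >= thr && vs[1] >= 5 * max(vs[-1], 0))
      return(c("tissue_enriched", tissues[ord[1]]))
    gmax <- min(7, nt - 1)
    if (gmax >= 2) {
      for (g in 2:gmax) {
        if (vs[g] >= thr && vs[g] >= 5 * max(vs[-seq_len(g)], 0))
          return(c("group_enriched", paste(sort(tissues[ord[seq_len(g)]]),
                                           collapse = ";")))
      }
    }
    if (vs[1] >= thr && vs[1] >= 5 * mean(v))
      return(c("tissue_enhanced", tissues[ord[1]]))
    if (all(det)) return(c("expressed_in_all", NA_character_))
    if (!any(det)) return(c("not_detected", NA_character_))
    c("mixed", NA_character_)
  }, character(2))
  data.frame(gene = rownames(vals), category = res[1, ], tissue = res[2, ],
             stringsAsFactors = FALSE)
}

#' Fisher test of tissue enrichment of a panel
#'
#' For each tissue with at least one `tissue_enriched` gene in the
#' background, tests the 2x2 table (in panel / not) x (enriched in that
#' tissue / not) over the background with a one-sided (greater) Fisher
#' exact test.
#'
#' @param panel_genes gene symbols of the biomarker panel (must be a subset
#'   of `background_genes`).
#' @param background_genes the assay universe.
#' @param categories output of [classify_tissue_specificity()] covering the
#'   background genes.
#' @return A data.frame with columns `tissue`, `k` (enriched panel genes),
#'   `K` (enriched background genes), `n` (panel size), `N` (background
#'   size), `p`, sorted by `p`.
#' @export
fisher_tissue_enrichment <- function(panel_genes, background_genes, categories) {
  panel_genes <- unique(toupper(panel_genes))
  background_genes <- unique(toupper(background_genes))
  off <- setdiff(panel_genes, background_genes)
  if (length(off))
    stop("panel genes absent from background: ", paste(off, collapse = ", "))
  cats <- categories[categories$gene %in% background_genes &
                       categories$category == "tissue_enriched", , drop = FALSE]
  tissues <- sort(unique(cats$tissue))
  N <- length(background_genes)
  n <- length(panel_genes)
  rows <- lapply(tissues, function(tt) {
    enr <- cats$gene[cats$tissue == tt]
    k <- length(intersect(panel_genes, enr))
    K <- length(enr)
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2)
    data.frame(tissue = tt, k = k, K = K, n = n, N = N,
               p = fisher.test(tab, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tissue = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric()))
  out[order(out$p, out$tissue), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, intersected with the background first, computes the
#' upper-tail hypergeometric probability `P(X >= k)` of the observed overlap
#' `k` between the panel and the set, with BH correction across the sets
#' that intersect the background. Sets with empty intersection are recorded
#' with `p = 1` and flagged, outside the BH family.
#'
#' @param panel_genes gene symbols of the query panel (subset of the
#'   background).
#' @param collection a [geneset_collection()].
#' @param background_genes the assay universe the panel was drawn from.
#' @return A data.frame sorted by `q` then set name: `set`, `k` (overlap),
#'   `K` (set size in background), `n` (panel size), `N` (background size),
#'   `overlap_genes` (semicolon-joined), `p`, `q`, `empty` flag.
#' @export
ora_hypergeometric <- function(panel_genes, collection, background_genes) {
  stopifnot(inherits(collection, "geneset_collection"))
  panel_genes <- unique(toupper(panel_genes))
  background_genes <- unique(toupper(background_genes))
  off <- setdiff(panel_genes, background_genes)
  if (length(off))
    stop("panel genes absent from background: ", paste(off, collapse = ", "))
  N <- length(background_genes)
  n <- length(panel_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    S <- intersect(collection$sets[[nm]], background_genes)
    K <- length(S)
    ov <- intersect(panel_genes, S)
    k <- length(ov)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               overlap_genes = paste(sort(ov), collapse = ";"),
               p = p, empty = K == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  fam <- !out$empty
  out$q[fam] <- bh_adjust(out$p[fam])
  out[order(out$q, out$set), , drop = FALSE]
}
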