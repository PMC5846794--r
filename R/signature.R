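#' Parameters of the rank-signature classifier
#'
#' @param n1 number of top-ranked proteins per subject signature (>= 0).
#' @param n2 number of bottom-ranked proteins per subject signature (>= 0);
#'   `n1 + n2 >= 1`.
#' @param filter_alpha two-sided Wilcoxon rank-sum pre-filter threshold in
#'   (0, 1].
#' @param weight_exponent exponent `w >= 0` of the rank weights
#'   `(P + 1 - r)^w` in the enrichment score (default 1).
#' @param foldchange_preprocess divide each protein by its mean over the
#'   training subjects before ranking, to emphasise fold changes (default
#'   `TRUE`).
#' @return A list of class `signature_params`.
#' @export
signature_params <- function(n1, n2, filter_alpha = 0.05, weight_exponent = 1,
                             foldchange_preprocess = TRUE) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 0 || n2 < 0 || n1 + n2 < 1)
    stop("need n1 >= 0, n2 >= 0 and n1 + n2 >= 1")
  if (!is.numeric(filter_alpha) || filter_alpha <= 0 || filter_alpha > 1)
    stop("filter_alpha must be in (0, 1]")
  if (weight_exponent < 0) stop("weight_exponent must be >= 0")
  structure(list(n1 = n1, n2 = n2, filter_alpha = filter_alpha,
                 weight_exponent = weight_exponent,
                 foldchange_preprocess = isTRUE(foldchange_preprocess)),
            class = "signature_params")
}

# ---- two-sample Wilcoxon rank-sum p-values, vectorised over proteins ----
#
# Exact tail (via the cached null CDF of the Mann-Whitney U statistic) for
# tie-free columns, normal approximation with tie and continuity correction
# otherwise.

wilcox_cdf_cache <- new.env(parent = emptyenv())

wilcox_exact_cdf <- function(m, n) {
  key <- paste0(m, "_", n)
  if (is.null(wilcox_cdf_cache[[key]]))
    wilcox_cdf_cache[[key]] <- pwilcox(0:(m * n), m, n)
  wilcox_cdf_cache[[key]]
}

ranksum_pvalues <- function(X, in_group1) {
  n1 <- sum(in_group1); n0 <- sum(!in_group1); N <- n1 + n0
  stopifnot(n1 >= 1, n0 >= 1)
  p <- numeric(ncol(X))
  U <- numeric(ncol(X))
  tie_term <- numeric(ncol(X))
  has_ties <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    r <- rank(xj)
    U[j] <- sum(r[in_group1]) - n1 * (n1 + 1) / 2
    if (anyDuplicated(xj)) {        # tie term needed only for tied columns
      has_ties[j] <- TRUE
      t <- table(xj)
      tie_term[j] <- sum(t^3 - t)
    }
  }
  exact_ok <- !has_ties & (n1 * n0) <= 1e6
  if (any(exact_ok)) {
    cdf <- wilcox_exact_cdf(n1, n0)
    u <- U[exact_ok]
    lower <- cdf[u + 1]
    upper <- cdf[n1 * n0 - u + 1]   # P(U >= u) by symmetry about n1*n0/2
    p[exact_ok] <- pmin(1, 2 * pmin(lower, upper))
  }
  if (any(!exact_ok)) {
    u <- U[!exact_ok]
    mu <- n1 * n0 / 2
    sigma2 <- (n1 * n0 / 12) * ((N + 1) - tie_term[!exact_ok] / (N * (N - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[!exact_ok] <- pmin(1, 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }
  p
}

#' Wilcoxon rank-sum pre-filter
#'
#' Retains the proteins whose two-sided rank-sum p-value (affected vs
#' control) is at most `alpha`, preserving the input protein order. The test
#' is exact for tie-free data and uses the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param dataset an [expression_dataset()] (typically restricted to
#'   training subjects); both classes must be present.
#' @param alpha threshold in (0, 1].
#' @return Character vector of retained protein ids, with the per-protein
#'   p-values attached as attribute `"p"`.
#' @export
wilcoxon_prefilter <- function(dataset, alpha) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be a number in (0, 1]")
  grp <- dataset$class_label == "affected"
  if (!any(grp) || !any(!grp)) stop("both classes must be present")
  p <- ranksum_pvalues(dataset$values, grp)
  keep <- p <= alpha
  if (!any(keep))
    stop("no proteins pass the Wilcoxon pre-filter; increase alpha")
  structure(dataset$protein_ids[keep], p = setNames(p, dataset$protein_ids))
}

#' Fold-change preprocessing
#'
#' Divides each protein column by its mean abundance over the (training)
#' subjects, emphasising expression fold changes. The means are recorded so
#' they can be reapplied to held-out subjects.
#'
#' @param dataset an [expression_dataset()].
#' @param means optional named vector of training means to apply (as stored
#'   in the `"protein_means"` attribute of a previous call); by default the
#'   means of `dataset` itself.
#' @return The transformed `expression_dataset`, with the divisor means in
#'   attribute `"protein_means"`.
#' @export
foldchange_preprocess <- function(dataset, means = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(means)) {
    means <- colMeans(dataset$values)
  } else {
    if (!all(dataset$protein_ids %in% names(means)))
      stop("`means` must cover every protein in the dataset")
    means <- means[dataset$protein_ids]
  }
  out <- dataset
  out$values <- sweep(dataset$values, 2, means, `/`)
  attr(out, "protein_means") <- means
  out
}

#' Build a subject signature
#'
#' Ranks the profile by descending value (ties broken by ascending protein
#' id, deterministically) and takes the first `n1` and last `n2` proteins.
#'
#' @param profile named numeric vector: one subject's values over the
#'   retained proteins.
#' @param params a [signature_params()].
#' @param subject_id optional id stored on the signature.
#' @return A list of class `subject_signature` with fields `subject_id`,
#'   `top` (length `n1`, in rank order) and `bottom` (length `n2`, in rank
#'   order, lowest last).
#' @export
make_signature <- function(profile, params, subject_id = NA_character_) {
  stopifnot(inherits(params, "signature_params"))
  P <- length(profile)
  if (is.null(names(profile))) stop("profile must be named by protein id")
  if (params$n1 + params$n2 > P)
    stop(sprintf("n1 + n2 = %d exceeds the %d retained proteins",
                 params$n1 + params$n2, P))
  ord <- order(-profile, names(profile))
  ids <- names(profile)[ord]
  structure(list(subject_id = subject_id,
                 top = if (params$n1 > 0) ids[seq_len(params$n1)] else character(),
                 bottom = if (params$n2 > 0) ids[seq(P - params$n2 + 1, P)] else character()),
            class = "subject_signature")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranking from top to bottom; a protein in `gene_set` ("hit") at
#' rank `r` adds its normalised weight `(P + 1 - r)^w / sum(weights of
#' hits)`, a miss subtracts `1 / (P - |S|)`. The score is the running-sum
#' value of largest magnitude (signed): `+1` when the set occupies exactly
#' the top of the ranking, `-1` for the exact bottom.
#'
#' @param gene_set non-empty character vector, a strict subset of `ranking`.
#' @param ranking full protein ranking (descending value order).
#' @param w rank-weight exponent (>= 0; `w = 0` weights all hits equally).
#' @return Score in `[-1, 1]`.
#' @export
enrichment_score <- function(gene_set, ranking, w = 1) {
  if (length(gene_set) == 0) stop("gene_set is empty")
  if (w < 0) stop("w must be >= 0")
  hits <- match(gene_set, ranking)
  if (anyNA(hits))
    stop("gene_set members absent from ranking: ",
         paste(head(gene_set[is.na(hits)], 5), collapse = ", "))
  if (length(hits) >= length(ranking))
    stop("gene_set must be a strict subset of the ranking")
  .es_score_cpp(as.integer(hits), length(ranking), w)
}

#' Distance between two subject signatures
#'
#' Symmetrised similarity
#' `s = [ES(topA | rankB) - ES(botA | rankB) + ES(topB | rankA) -
#' ES(botB | rankA)] / 4`, mapped to `d = (1 - s) / 2` in `[0, 1]`.
#' When a signature side is empty (`n1 = 0` or `n2 = 0`) the average runs
#' over the defined terms only, so `d(A, A) = 0` always holds.
#'
#' @param sig_a,sig_b [make_signature()] objects built over the same
#'   retained-protein universe.
#' @param ranking_a,ranking_b the two subjects' full rankings.
#' @param w rank-weight exponent.
#' @return Distance in `[0, 1]`; 0 for identical rankings.
#' @export
signature_distance <- function(sig_a, ranking_a, sig_b, ranking_b, w = 1) {
  stopifnot(inherits(sig_a, "subject_signature"),
            inherits(sig_b, "subject_signature"))
  if (length(ranking_a) != length(ranking_b) ||
      !setequal(ranking_a, ranking_b))
    stop("signatures were built over different protein universes")
  terms <- numeric(0)
  if (length(sig_a$top))
    terms <- c(terms, enrichment_score(sig_a$top, ranking_b, w),
               enrichment_score(sig_b$top, ranking_a, w))
  if (length(sig_a$bottom))
    terms <- c(terms, -enrichment_score(sig_a$bottom, ranking_b, w),
               -enrichment_score(sig_b$bottom, ranking_a, w))
  if (length(terms) == 0) stop("both signature sides are empty")
  d <- (1 - mean(terms)) / 2
  min(max(d, 0), 1)
}

#' All-pairs signature distance matrix
#'
#' @param signatures list of [make_signature()] objects (>= 2), one per
#'   subject; all built over the same protein universe, with `top`/`bottom`
#'   taken from the corresponding entry of `rankings`.
#' @param rankings list of full rankings, parallel to `signatures`.
#' @param w rank-weight exponent.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames = subject ids.
#' @export
distance_matrix <- function(signatures, rankings, w = 1) {
  n <- length(signatures)
  if (n < 2) stop("need at least 2 subjects")
  if (length(rankings) != n) stop("signatures and rankings differ in length")
  ids <- vapply(signatures, function(s)
    if (is.na(s$subject_id)) "" else s$subject_id, "")
  if (any(ids == "")) ids <- paste0("S", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- signature_distance(signatures[[i]], rankings[[i]],
                                               signatures[[j]], rankings[[j]], w)
    }
  }
  D
}
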