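#' Classify one subject by group-average distance
#'
#' Assigns the label of the training group with the smaller mean distance to
#' the sample; an exact tie resolves deterministically to `"control"` with a
#' warning.
#'
#' @param distances numeric vector of distances from the sample to each
#'   training subject.
#' @param labels training class labels (`"control"`/`"affected"`), parallel
#'   to `distances`.
#' @return `"control"` or `"affected"`.
#' @export
classify_subject <- function(distances, labels) {
  labels <- as.character(labels)
  if (length(distances) != length(labels))
    stop("distances and labels differ in length")
  m_ctrl <- mean(distances[labels == "control"])
  m_aff <- mean(distances[labels == "affected"])
  if (is.nan(m_ctrl) || is.nan(m_aff))
    stop("both classes must be present in the training set")
  if (m_ctrl == m_aff) {
    warning("mean-distance tie; assigning 'control'")
    return("control")
  }
  if (m_ctrl < m_aff) "control" else "affected"
}

# stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin into k folds
stratified_folds <- function(class_label, k, seed) {
  if (any(table(class_label) < k))
    stop(sprintf("each class needs at least k = %d members", k))
  set.seed(as.integer(seed))
  fold <- integer(length(class_label))
  for (cl in unique(class_label)) {
    idx <- which(class_label == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Precompute the fold-level quantities that do not depend on (n1, n2, alpha):
# per-fold training/test indices, per-fold Wilcoxon p-values on the training
# subjects, and the (optionally fold-change normalised) value matrix using
# training-fold means only, so no information leaks from held-out subjects.
cv_prepare <- function(dataset, k, seed, foldchange = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  fold <- stratified_folds(unname(dataset$class_label), k, seed)
  grp <- dataset$class_label == "affected"
  folds <- lapply(seq_len(k), function(f) {
    train <- which(fold != f)
    test <- which(fold == f)
    p <- ranksum_pvalues(dataset$values[train, , drop = FALSE], grp[train])
    vals <- if (foldchange) {
      sweep(dataset$values, 2, colMeans(dataset$values[train, , drop = FALSE]), `/`)
    } else dataset$values
    list(train = train, test = test, p = p, vals = vals)
  })
  list(dataset = dataset, k = k, seed = as.integer(seed), fold = fold,
       folds = folds, foldchange = foldchange)
}

# Evaluate one parameter setting on a prepared CV object. Returns per-fold
# accuracies, predictions, the union panel and (optionally) every signature.
# With clamp = TRUE (used for the permutation null, where a shuffled
# labelling may leave too few filtered proteins) signature lengths are
# capped at the fold's retained count, and a fold retaining nothing falls
# back to majority-class prediction.
cv_eval <- function(prep, n1, n2, alpha, w = 1, collect_signatures = FALSE,
                    clamp = FALSE) {
  ds <- prep$dataset
  n_sub <- length(ds$subject_ids)
  pred <- rep(NA_character_, n_sub)
  fold_acc <- numeric(prep$k)
  panel <- character(0)
  signatures <- if (collect_signatures) vector("list", prep$k) else NULL
  contributing <- list()
  for (f in seq_len(prep$k)) {
    fd <- prep$folds[[f]]
    retained <- which(fd$p <= alpha)
    if (length(retained) == 0 && clamp) {
      train_lab <- unname(ds$class_label[fd$train])
      maj <- if (sum(train_lab == "control") >= sum(train_lab == "affected"))
        "control" else "affected"
      pred[fd$test] <- maj
      fold_acc[f] <- mean(maj == unname(ds$class_label[fd$test]))
      next
    }
    if (length(retained) == 0)
      stop("no proteins pass the Wilcoxon pre-filter; increase alpha")
    P <- length(retained)
    n1f <- n1; n2f <- n2                        # fold-local lengths
    if (clamp && (n1f + n2f > P || n1f >= P || n2f >= P)) {
      n1f <- min(n1f, as.integer(ceiling(P / 2)))
      n2f <- min(n2f, P - n1f)
      if (n1f >= P) n1f <- P - 1L
      if (n2f >= P) n2f <- P - 1L
      if (n1f + n2f < 1) {
        train_lab <- unname(ds$class_label[fd$train])
        maj <- if (sum(train_lab == "control") >= sum(train_lab == "affected"))
          "control" else "affected"
        pred[fd$test] <- maj
        fold_acc[f] <- mean(maj == unname(ds$class_label[fd$test]))
        next
      }
    }
    if (n1f + n2f > P || n1f >= P || n2f >= P)
      stop(sprintf("signature lengths (n1=%d, n2=%d) infeasible for %d retained proteins",
                   n1f, n2f, P))
    pid <- ds$protein_ids[retained]
    sub_vals <- fd$vals[, retained, drop = FALSE]
    ord <- matrix(0L, n_sub, P)
    for (s in seq_len(n_sub)) ord[s, ] <- order(-sub_vals[s, ], pid)
    pos <- matrix(0L, n_sub, P)
    pos[cbind(rep(seq_len(n_sub), P), as.vector(ord))] <- rep(seq_len(P), each = n_sub)
    D <- .signature_distances_cpp(ord, pos, fd$test, fd$train, n1f, n2f, w)
    train_lab <- unname(ds$class_label[fd$train])
    is_ctrl <- train_lab == "control"
    m_ctrl <- rowMeans(D[, is_ctrl, drop = FALSE])
    m_aff <- rowMeans(D[, !is_ctrl, drop = FALSE])
    pf <- ifelse(m_ctrl <= m_aff, "control", "affected")
    pred[fd$test] <- pf
    fold_acc[f] <- mean(pf == unname(ds$class_label[fd$test]))
    top_ids <- if (n1f > 0) pid[as.vector(ord[, seq_len(n1f), drop = FALSE])] else character()
    bot_ids <- if (n2f > 0) pid[as.vector(ord[, seq(P - n2f + 1, P), drop = FALSE])] else character()
    panel <- union(panel, union(top_ids, bot_ids))
    sig_mat <- cbind(if (n1f > 0) matrix(pid[ord[, seq_len(n1f), drop = FALSE]], n_sub),
                     if (n2f > 0) matrix(pid[ord[, seq(P - n2f + 1, P), drop = FALSE]], n_sub))
    for (s in seq_len(n_sub)) {
      for (pr in sig_mat[s, ]) contributing[[pr]] <- c(contributing[[pr]], ds$subject_ids[s])
    }
    if (collect_signatures) {
      signatures[[f]] <- lapply(seq_len(n_sub), function(s) {
        structure(list(subject_id = ds$subject_ids[s],
                       top = if (n1f > 0) pid[ord[s, seq_len(n1f)]] else character(),
                       bottom = if (n2f > 0) pid[ord[s, seq(P - n2f + 1, P)]] else character()),
                  class = "subject_signature")
      })
    }
  }
  list(mean_accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       predicted = setNames(pred, ds$subject_ids),
       panel_ids = panel,
       contributing = lapply(contributing, unique),
       signatures = signatures)
}

#' Stratified k-fold cross-validation of the rank-signature classifier
#'
#' Per fold: the Wilcoxon pre-filter and (optional) fold-change
#' normalisation are fitted on the training subjects only; signatures are
#' built for all subjects over the training fold's retained proteins, and
#' each held-out subject is classified against the training signatures by
#' group-average distance.
#'
#' @param dataset an [expression_dataset()]; each class must have at least
#'   `k` members.
#' @param params a [signature_params()].
#' @param k number of folds (default 5, i.e. 20% held out per round).
#' @param seed integer seed controlling the stratified fold shuffle.
#' @return A list of class `cv_result`: per-fold and mean held-out accuracy,
#'   per-subject predicted label, fold assignment, the union biomarker panel
#'   with its contributing-subject map, all fold signatures, and the seed.
#' @export
cross_validate <- function(dataset, params, k = 5, seed = 1L) {
  stopifnot(inherits(params, "signature_params"))
  prep <- cv_prepare(dataset, k, seed, params$foldchange_preprocess)
  ev <- cv_eval(prep, params$n1, params$n2, params$filter_alpha,
                params$weight_exponent, collect_signatures = TRUE)
  structure(list(k = k,
                 fold_assignment = setNames(prep$fold, dataset$subject_ids),
                 fold_accuracies = ev$fold_accuracies,
                 mean_accuracy = ev$mean_accuracy,
                 predicted = ev$predicted,
                 panel_ids = ev$panel_ids,
                 contributing = ev$contributing,
                 signatures = ev$signatures,
                 params = params,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold, mean held-out accuracy %.4f (folds: %s)\n",
              x$k, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  panel of %d proteins (n1=%d, n2=%d, alpha=%.3g)\n",
              length(x$panel_ids), x$params$n1, x$params$n2,
              x$params$filter_alpha))
  invisible(x)
}

#' Aggregate subject signatures into a biomarker panel
#'
#' The panel is the union of all proteins appearing in at least one subject
#' signature, with a map recording which subjects contributed each protein.
#'
#' @param signatures list of [make_signature()] objects (possibly pooled
#'   across cross-validation folds; nested lists are flattened).
#' @param mode `"short"` or `"long"` tag stored on the panel.
#' @param params the [signature_params()] the signatures were built with.
#' @return A list of class `biomarker_panel` with fields `protein_ids`,
#'   `mode`, `contributing` and `params`.
#' @export
aggregate_panel <- function(signatures, mode = c("short", "long"),
                            params = NULL) {
  mode <- match.arg(mode)
  if (length(signatures) && !inherits(signatures[[1]], "subject_signature"))
    signatures <- unlist(signatures, recursive = FALSE)
  if (length(signatures) == 0) stop("no signatures to aggregate")
  contributing <- list()
  for (sig in signatures) {
    for (pr in c(sig$top, sig$bottom))
      contributing[[pr]] <- c(contributing[[pr]], sig$subject_id)
  }
  structure(list(protein_ids = names(contributing),
                 mode = mode,
                 contributing = lapply(contributing, unique),
                 params = params),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel (%s): %d proteins\n", x$mode,
              length(x$protein_ids)))
  invisible(x)
}

#' Permutation test of the cross-validated classification accuracy
#'
#' Class labels are shuffled `B` times; the full cross-validation is re-run
#' on each permuted labelling and the empirical p-value is
#' `(#\{null >= observed\} + 1) / (B + 1)`. Because a shuffled labelling can
#' leave fewer filtered proteins than the configured signature lengths, the
#' null runs cap `n1`/`n2` at each fold's retained count; a null fold
#' retaining no protein at all predicts the training majority class.
#'
#' @param dataset an [expression_dataset()].
#' @param params a [signature_params()].
#' @param k folds.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; drives the observed CV folds and each
#'   permutation.
#' @return A list of class `permutation_result`: observed mean CV accuracy,
#'   the `B` null accuracies, the empirical p-value and the seed.
#' @export
permutation_test <- function(dataset, params, k = 5, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  observed <- cross_validate(dataset, params, k, seed)$mean_accuracy
  null_acc <- numeric(B)
  labels <- unname(dataset$class_label)
  for (b in seq_len(B)) {
    set.seed(as.integer(seed) + b)
    ds_b <- dataset
    ds_b$class_label[] <- sample(labels)
    prep <- cv_prepare(ds_b, k, seed = as.integer(seed) + b,
                       foldchange = params$foldchange_preprocess)
    null_acc[b] <- cv_eval(prep, params$n1, params$n2, params$filter_alpha,
                           params$weight_exponent, clamp = TRUE)$mean_accuracy
  }
  p <- (sum(null_acc >= observed) + 1) / (B + 1)
  structure(list(B = B, observed_accuracy = observed, null_accuracies = null_acc,
                 p_value = p, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed accuracy %.4f, B = %d, p = %.4g\n",
              x$observed_accuracy, x$B, x$p_value))
  invisible(x)
}
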