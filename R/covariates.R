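#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i} m p_(j) / j`
#' capped at 1, mapped back to the input order (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# vectorised per-protein OLS of log2(level) on age
ols_slope_table <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(Y, 2, colMeans(Y))
  slope <- as.vector(crossprod(xc, yc)) / sxx
  rss <- colSums(yc^2) - slope^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[se == 0 & slope == 0] <- 1       # constant column: slope 0, no evidence
  data.frame(estimate = slope, p = p)
}

#' Per-protein linear association of log2 level with age
#'
#' Ordinary least squares of `log2(level)` on age, fitted separately within
#' the requested group(s); the BH correction is applied within the family of
#' tested proteins (typically the biomarker panel) for each group.
#'
#' @param dataset an [expression_dataset()].
#' @param group `"affected"`, `"control"` or `"both"` (both groups fitted
#'   separately and stacked).
#' @param proteins assay ids to test (default: all proteins in the dataset;
#'   pass the panel to match the intended multiple-testing family).
#' @return A data.frame with columns `protein`, `estimate` (slope,
#'   log2-units per year), `p`, `q`, `group`.
#' @export
age_association <- function(dataset, group = c("affected", "control", "both"),
                            proteins = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  group <- match.arg(group)
  if (is.null(proteins)) proteins <- dataset$protein_ids
  groups <- if (group == "both") c("affected", "control") else group
  out <- lapply(groups, function(g) {
    idx <- which(dataset$class_label == g)
    if (length(idx) < 3) stop("need at least 3 subjects in group ", g)
    x <- dataset$age[idx]
    if (length(unique(x)) < 2) stop("ages are constant in group ", g)
    tab <- ols_slope_table(log2(dataset$values[idx, proteins, drop = FALSE]), x)
    data.frame(protein = proteins, estimate = tab$estimate, p = tab$p,
               q = bh_adjust(tab$p), group = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Treatment association among affected subjects
#'
#' Two-sided Wilcoxon rank-sum test of treated vs untreated affected
#' subjects per protein (exact for tie-free data, normal approximation with
#' tie and continuity correction otherwise), BH-corrected within the tested
#' protein family.
#'
#' @param dataset an [expression_dataset()]; only affected subjects are
#'   used, and both treatment arms must be non-empty.
#' @param proteins assay ids to test (default: all; pass the panel to match
#'   the intended family).
#' @return A data.frame with columns `protein`, `estimate` (difference of
#'   log2 medians, treated minus untreated), `p`, `q`, `group`.
#' @export
treatment_association <- function(dataset, proteins = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(proteins)) proteins <- dataset$protein_ids
  idx <- which(dataset$class_label == "affected")
  treated <- dataset$treated[idx]
  if (!any(treated) || all(treated))
    stop("both treated and untreated affected subjects are required")
  X <- dataset$values[idx, proteins, drop = FALSE]
  p <- ranksum_pvalues(X, treated)
  est <- log2(apply(X[treated, , drop = FALSE], 2, median)) -
    log2(apply(X[!treated, , drop = FALSE], 2, median))
  data.frame(protein = proteins, estimate = unname(est), p = p,
             q = bh_adjust(p), group = "affected", stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of age distributions
#'
#' @param ages_case,ages_control numeric vectors (non-empty).
#' @return A list with the KS `D` statistic and the p-value
#'   ([stats::ks.test()]; exact when sample sizes permit).
#' @export
ks_age_compare <- function(ages_case, ages_control) {
  if (length(ages_case) == 0 || length(ages_control) == 0)
    stop("both age samples must be non-empty")
  kt <- suppressWarnings(ks.test(ages_case, ages_control))
  list(D = unname(kt$statistic), p = kt$p.value)
}
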