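#' Genetic-optimizer configuration
#'
#' The optimizer searches over the signature lengths and the pre-filter
#' stringency. In `"short"` mode fitness is lexicographic (mean CV accuracy,
#' then smaller panel); in `"long"` mode it is the panel size subject to a
#' mean-accuracy floor `a_min` (the concrete reading of "accuracy close to
#' 100%").
#'
#' @param population_size,generations,tournament_size,crossover_rate,mutation_rate
#'   standard GA hyperparameters (defaults 40, 60, 3, 0.8, 0.15).
#' @param n_bounds inclusive integer search range for each of `n1` and `n2`;
#'   `n1 + n2 >= 1` is enforced. The lower bound 0 admits one-sided
#'   signatures.
#' @param alpha_grid log-spaced grid of pre-filter thresholds searched.
#' @param mode `"short"` or `"long"`.
#' @param a_min long-mode accuracy floor (default 0.98).
#' @param seed integer seed (drives fold assignment and all GA randomness).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, generations = 60,
                      tournament_size = 3, crossover_rate = 0.8,
                      mutation_rate = 0.15, n_bounds = c(0, 40),
                      alpha_grid = 10^seq(log10(1e-12), log10(0.05),
                                          length.out = 12),
                      mode = c("short", "long"), a_min = 0.98, seed = 1L) {
  mode <- match.arg(mode)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop("rates must be in [0, 1]")
  if (population_size < 2 || generations < 1 || tournament_size < 1)
    stop("population_size, generations and tournament_size must be positive")
  if (n_bounds[1] < 0 || n_bounds[2] < max(1, n_bounds[1]))
    stop("invalid n1/n2 search bounds")
  if (any(alpha_grid <= 0 | alpha_grid > 1)) stop("alpha_grid values must be in (0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 n_bounds = as.integer(n_bounds), alpha_grid = sort(alpha_grid),
                 mode = mode, a_min = a_min, seed = as.integer(seed)),
            class = "ga_config")
}

#' Optimize signature length and filter stringency by genetic search
#'
#' Chromosomes are `(n1, n2, alpha-grid index)`. Each chromosome is scored
#' by stratified k-fold cross-validation (fold assignment fixed by the
#' configuration seed, per-fold Wilcoxon p-values cached, so the search
#' explores parameters, not fold noise). Elitism keeps the best chromosome;
#' results are deterministic under the seed.
#'
#' @param dataset an [expression_dataset()].
#' @param ga a [ga_config()].
#' @param k cross-validation folds.
#' @param weight_exponent enrichment-score weight exponent.
#' @param foldchange_preprocess apply fold-change normalisation (default
#'   `TRUE`).
#' @return A list of class `ga_result` with the selected
#'   [signature_params()], the aggregated [aggregate_panel()] biomarker
#'   panel, the winning [cross_validate()] result, and the number of
#'   distinct chromosomes evaluated.
#' @export
optimize_parameters <- function(dataset, ga = ga_config(), k = 5,
                                weight_exponent = 1,
                                foldchange_preprocess = TRUE) {
  stopifnot(inherits(ga, "ga_config"))
  prep <- cv_prepare(dataset, k, seed = ga$seed, foldchange = foldchange_preprocess)
  n_alpha <- length(ga$alpha_grid)
  lo <- ga$n_bounds[1]; hi <- ga$n_bounds[2]

  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- paste(chrom, collapse = "_")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- tryCatch({
      ev <- cv_eval(prep, chrom[1], chrom[2], ga$alpha_grid[chrom[3]],
                    weight_exponent)
      list(acc = ev$mean_accuracy, panel = length(ev$panel_ids), ok = TRUE)
    }, error = function(e) list(acc = NA_real_, panel = NA_integer_, ok = FALSE))
    res$fitness <- if (!res$ok) {
      -Inf
    } else if (ga$mode == "short") {
      # lexicographic (accuracy, -panel): panel <= n_proteins so the 1e-6
      # penalty cannot flip an accuracy difference (granularity 1/n_subjects)
      res$acc - 1e-6 * res$panel
    } else {
      if (res$acc < ga$a_min) -Inf else res$panel
    }
    cache[[key]] <- res
    res
  }

  random_chrom <- function() {
    repeat {
      ch <- c(sample(lo:hi, 1), sample(lo:hi, 1), sample.int(n_alpha, 1))
      if (ch[1] + ch[2] >= 1) return(ch)
    }
  }
  clamp <- function(ch) {
    if (ch[1] + ch[2] < 1) ch[2] <- 1L
    ch
  }

  set.seed(ga$seed + 1L)
  pop <- replicate(ga$population_size, random_chrom(), simplify = FALSE)
  # seed a few minimal chromosomes at the loosest filter so the search
  # starts from a feasible region even when few proteins pass strict alphas
  seeds <- list(c(1L, 1L, n_alpha), c(0L, 1L, n_alpha), c(1L, 0L, n_alpha),
                c(2L, 2L, n_alpha))
  seeds <- Filter(function(ch) ch[1] >= lo && ch[2] >= lo &&
                    ch[1] <= hi && ch[2] <= hi && ch[1] + ch[2] >= 1, seeds)
  pop[seq_along(seeds)] <- seeds
  best <- NULL
  best_fit <- -Inf
  best_acc_seen <- -Inf
  for (gen in seq_len(ga$generations)) {
    fits <- numeric(ga$population_size)
    for (i in seq_along(pop)) {
      r <- evaluate(pop[[i]])
      fits[i] <- r$fitness
      if (r$ok && r$acc > best_acc_seen) best_acc_seen <- r$acc
      if (r$fitness > best_fit) {
        best_fit <- r$fitness
        best <- pop[[i]]
      }
    }
    tournament <- function() {
      cand <- sample.int(ga$population_size, ga$tournament_size, replace = TRUE)
      pop[[cand[which.max(fits[cand])]]]
    }
    next_pop <- vector("list", ga$population_size)
    if (!is.null(best)) next_pop[[1]] <- best      # elitism
    i <- if (is.null(best)) 1L else 2L
    while (i <= ga$population_size) {
      p1 <- tournament(); p2 <- tournament()
      child <- p1
      if (runif(1) < ga$crossover_rate) {
        cut <- sample.int(2, 1)                    # single-point crossover
        child <- c(p1[seq_len(cut)], p2[seq(cut + 1, 3)])
      }
      for (g in 1:2) if (runif(1) < ga$mutation_rate) child[g] <- sample(lo:hi, 1)
      if (runif(1) < ga$mutation_rate) child[3] <- sample.int(n_alpha, 1)
      next_pop[[i]] <- clamp(child)
      i <- i + 1L
    }
    pop <- next_pop
  }
  for (ch in pop) {                                # score the final population
    r <- evaluate(ch)
    if (r$ok && r$acc > best_acc_seen) best_acc_seen <- r$acc
    if (r$fitness > best_fit) { best_fit <- r$fitness; best <- ch }
  }
  if (is.null(best) || !is.finite(best_fit)) {
    if (ga$mode == "long" && is.finite(best_acc_seen))
      stop(sprintf("no parameter setting reached the long-mode accuracy floor %.3f (best accuracy found: %.3f)",
                   ga$a_min, best_acc_seen))
    stop("no feasible parameter setting found")
  }
  params <- signature_params(best[1], best[2],
                             filter_alpha = ga$alpha_grid[best[3]],
                             weight_exponent = weight_exponent,
                             foldchange_preprocess = foldchange_preprocess)
  cv <- cross_validate(dataset, params, k = k, seed = ga$seed)
  panel <- aggregate_panel(unlist(cv$signatures, recursive = FALSE),
                           mode = ga$mode, params = params)
  structure(list(params = params, panel = panel, cv = cv,
                 n_evaluated = length(ls(cache)), ga = ga),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result (%s mode): n1=%d n2=%d alpha=%.3g -> accuracy %.4f, panel %d proteins (%d chromosomes evaluated)\n",
              x$ga$mode, x$params$n1, x$params$n2, x$params$filter_alpha,
              x$cv$mean_accuracy, length(x$panel$protein_ids), x$n_evaluated))
  invisible(x)
}
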