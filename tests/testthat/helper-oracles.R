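# Brute-force running-sum enrichment score: walks every rank position.
# Kept deliberately independent of the package's C++ kernel.
es_oracle <- function(set, ranking, w) {
  P <- length(ranking)
  hit <- ranking %in% set
  s <- sum(hit)
  wts <- ifelse(hit, (P + 1 - seq_len(P))^w, 0)
  run <- cumsum(ifelse(hit, wts / sum(wts), -1 / (P - s)))
  mx <- max(run, 0)
  mn <- min(run, 0)
  if (mx + mn >= -1e-12) mx else mn
}

# distance recomputed from the oracle ES, mirroring the published formula
distance_oracle <- function(sig_a, rank_a, sig_b, rank_b, w) {
  terms <- c()
  if (length(sig_a$top))
    terms <- c(terms, es_oracle(sig_a$top, rank_b, w),
               es_oracle(sig_b$top, rank_a, w))
  if (length(sig_a$bottom))
    terms <- c(terms, -es_oracle(sig_a$bottom, rank_b, w),
               -es_oracle(sig_b$bottom, rank_a, w))
  (1 - mean(terms)) / 2
}

# small dataset built straight from a matrix of positive values
tiny_dataset <- function(values, class_label, age = NULL, treated = NULL) {
  if (is.null(age)) age <- seq_len(nrow(values)) + 4
  expression_dataset(values, class_label, age, treated)
}

# pure-noise cohort: log-normal baselines, no planted structure
noise_cohort <- function(n_control, n_affected, n_proteins, seed) {
  set.seed(seed)
  n <- n_control + n_affected
  vals <- matrix(2^(rnorm(n * n_proteins, mean = 10, sd = 0.5)), n, n_proteins,
                 dimnames = list(sprintf("S%02d", seq_len(n)),
                                 sprintf("P%04d", seq_len(n_proteins))))
  tiny_dataset(vals, rep(c("control", "affected"), c(n_control, n_affected)),
               age = runif(n, 4, 15))
}

# cohort with one (or a few) perfectly separating proteins among tight
# noise; the separating proteins are depleted in affected subjects so that
# both class rankings stay clean after pooled-mean normalisation
separating_cohort <- function(n_control = 12, n_affected = 12,
                              n_proteins = 20, n_sep = 1, seed = 1) {
  set.seed(seed)
  n <- n_control + n_affected
  vals <- matrix(2^(rnorm(n * n_proteins, mean = 10, sd = 0.15)), n, n_proteins,
                 dimnames = list(sprintf("S%02d", seq_len(n)),
                                 sprintf("P%04d", seq_len(n_proteins))))
  cls <- rep(c("control", "affected"), c(n_control, n_affected))
  for (j in seq_len(n_sep))
    vals[cls == "affected", j] <- vals[cls == "affected", j] * 2^-6
  tiny_dataset(vals, cls, age = runif(n, 4, 15))
}
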