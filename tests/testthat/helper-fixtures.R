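# small in-code fixtures and independent oracles shared across tests

# deterministic little genotype matrix with optional missing cells
toy_genotypes <- function(n = 6, m = 8, seed = 42, missing = 0) {
  set.seed(seed)
  counts <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing > 0) {
    holes <- cbind(sample(n, missing, replace = TRUE),
                   sample(m, missing, replace = TRUE))
    counts[holes] <- NA
  }
  genotype_matrix(counts,
                  sample_ids = sprintf("s%02d", seq_len(n)),
                  marker_ids = sprintf("mk%02d", seq_len(m)))
}

# a polymorphic-everywhere matrix (no monomorphic columns), for standardize
toy_polymorphic <- function(n = 10, m = 12, seed = 7) {
  set.seed(seed)
  repeat {
    counts <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                     n, m)
    if (all(apply(counts, 2, stats::sd) > 0)) break
  }
  genotype_matrix(counts,
                  sample_ids = sprintf("s%02d", seq_len(n)),
                  marker_ids = sprintf("mk%02d", seq_len(m)))
}

# triple-loop kinship oracle, independent of the matrix-product path
kinship_oracle <- function(values) {
  n <- nrow(values); m <- ncol(values)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(m)) s <- s + values[i, l] * values[j, l]
    k[i, j] <- s / m
  }
  k
}

# grid-search MLE oracle for the Beta-Binomial F_ST estimator
fst_grid_oracle <- function(g, train_idx, target_idx,
                            grid = seq(0.001, 0.5, by = 0.001)) {
  anc <- colSums(g$counts[train_idx, , drop = FALSE]) /
    (2 * length(train_idx))
  usable <- anc > 0 & anc < 1
  cnt <- colSums(g$counts[target_idx, usable, drop = FALSE])
  nch <- 2 * length(target_idx)
  ll <- vapply(grid, function(f)
    beta_binomial_loglik(f, anc[usable], cnt, nch), numeric(1))
  grid[which.max(ll)]
}

# two-population fixture: training side drawn from the ancestral
# frequencies, target side diverged at F (the quantity the estimator
# defines, training treated as ancestral)
two_pop_fixture <- function(F, n_each = 100, n_markers = 2000, seed = 1) {
  simulate_structured_population(
    population_spec(c(n_each, n_each), c(1e-6, F), n_markers), seed = seed)
}

write_csv_fixture <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
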