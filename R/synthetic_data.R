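#' Specify a structured synthetic population
#'
#' @param sizes per-population sample counts (length defines the number of
#'   populations), each at least 2.
#' @param fst_true per-population divergence from the common ancestral
#'   population, each in (0, 1); recycled to the number of populations.
#'   Use a value near the estimator lower bound (e.g. `1e-6`) for a
#'   population meant to stand in for the ancestral one.
#' @param n_markers number of biallelic markers.
#' @param anc_freq_law ancestral-frequency law: `"uniform"` draws from
#'   U(0.05, 0.95); `"beta"` draws from Beta(`beta_shape[1]`,
#'   `beta_shape[2]`) truncated away from 0 and 1.
#' @param beta_shape shape parameters for `anc_freq_law = "beta"`.
#' @param ld_rho first-order correlation of adjacent-marker haplotype
#'   states, in `[0, 1)`; 0 gives independent markers.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(sizes, fst_true, n_markers,
                            anc_freq_law = c("uniform", "beta"),
                            beta_shape = c(1, 1), ld_rho = 0) {
  anc_freq_law <- match.arg(anc_freq_law)
  if (any(sizes < 2)) stop("each population needs at least 2 samples")
  fst_true <- rep_len(fst_true, length(sizes))
  if (any(fst_true <= 0 | fst_true >= 1)) stop("fst_true must be in (0, 1)")
  if (!(ld_rho >= 0 && ld_rho < 1)) stop("ld_rho must be in [0, 1)")
  structure(list(sizes = as.integer(sizes), fst_true = fst_true,
                 n_markers = as.integer(n_markers),
                 anc_freq_law = anc_freq_law, beta_shape = beta_shape,
                 ld_rho = ld_rho),
            class = "population_spec")
}

# one haplotype (0/1 per marker): first-order Markov chain sharing latent
# uniforms with probability ld_rho, so marginals stay Bernoulli(p_k) while
# adjacent markers are positively associated
.simulate_haplotype <- function(p, ld_rho) {
  m <- length(p)
  if (ld_rho == 0) return(as.integer(runif(m) < p))
  u <- numeric(m)
  u[1] <- runif(1)
  for (k in 2:m) {
    u[k] <- if (runif(1) < ld_rho) u[k - 1] else runif(1)
  }
  as.integer(u < p)
}

#' Simulate a structured population under the Balding-Nichols model
#'
#' Ancestral frequencies \eqn{\pi_k} are drawn from the spec's law; each
#' population j draws its own frequencies
#' \eqn{p_{jk} \sim Beta(\pi_k (1-F_j)/F_j, (1-\pi_k)(1-F_j)/F_j)}, and
#' genotypes are the sum of two haplotypes with those marginal
#' frequencies (independent markers when `ld_rho = 0`, a first-order
#' Markov haplotype chain with the same marginals otherwise). This is
#' exactly the generative model the Beta-Binomial F_ST estimator assumes,
#' so generator and estimator can be round-tripped in tests.
#'
#' @param spec a [population_spec()].
#' @param seed RNG seed.
#' @return a [genotype_matrix()] with `pop_labels` `"P1"`, `"P2"`, ... and
#'   attributes `anc_freq` (the drawn \eqn{\pi}) and `pop_freq` (markers x
#'   populations matrix of the drawn \eqn{p_{jk}}).
#' @export
simulate_structured_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  m <- spec$n_markers
  pi_k <- switch(spec$anc_freq_law,
    uniform = runif(m, 0.05, 0.95),
    beta = pmin(0.999, pmax(0.001,
      stats::rbeta(m, spec$beta_shape[1], spec$beta_shape[2]))))
  n_pops <- length(spec$sizes)
  pop_freq <- matrix(NA_real_, m, n_pops)
  counts <- matrix(NA_real_, sum(spec$sizes), m)
  labels <- rep(paste0("P", seq_len(n_pops)), spec$sizes)
  row <- 0L
  for (j in seq_len(n_pops)) {
    f <- spec$fst_true[j]
    p <- stats::rbeta(m, pi_k * (1 - f) / f, (1 - pi_k) * (1 - f) / f)
    # guard against numerically degenerate Beta draws
    p <- pmin(1, pmax(0, p))
    pop_freq[, j] <- p
    for (i in seq_len(spec$sizes[j])) {
      row <- row + 1L
      counts[row, ] <- if (spec$ld_rho == 0) {
        rbinom(m, 2, p)
      } else {
        .simulate_haplotype(p, spec$ld_rho) +
          .simulate_haplotype(p, spec$ld_rho)
      }
    }
  }
  ids <- sprintf("%s_%03d", labels, unlist(lapply(spec$sizes, seq_len)))
  g <- genotype_matrix(counts, sample_ids = ids,
                       marker_ids = sprintf("m%05d", seq_len(m)),
                       pop_labels = labels)
  attr(g, "anc_freq") <- pi_k
  attr(g, "pop_freq") <- pop_freq
  g
}

#' Write the deterministic fixture suite
#'
#' Generates the small named fixtures used to exercise every pipeline
#' stage without external data — a two-population split fixture, a
#' homogeneous fixture, a missing-data fixture, an LD fixture and a trait
#' fixture — as CSV genotype/phenotype files plus a JSON manifest listing
#' every seed and true parameter. All fixtures are synthetic.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; the same seed reproduces the archive
#'   byte-identically.
#' @return invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(master_seed = seed, fixtures = list())
  add <- function(name, g, true_fst = NULL, extra = list()) {
    path <- file.path(dir, paste0(name, ".csv"))
    write_genotypes(g, path)
    manifest$fixtures[[name]] <<- c(
      list(file = basename(path), n = nrow(g$counts), m = ncol(g$counts),
           true_fst = true_fst), extra)
  }
  two_pop <- simulate_structured_population(
    population_spec(c(60, 60), c(1e-6, 0.05), 800), seed = seed)
  add("two_pop_split", two_pop, true_fst = 0.05)
  homog <- simulate_structured_population(
    population_spec(120, 1e-6, 800), seed = seed + 1L)
  add("homogeneous", homog, true_fst = 1e-6)
  miss <- simulate_structured_population(
    population_spec(40, 0.02, 200), seed = seed + 2L)
  set.seed(seed + 2L)
  holes <- cbind(sample(40, 30, replace = TRUE),
                 sample(200, 30, replace = TRUE))
  miss$counts[holes] <- NA
  add("missing_data", miss, true_fst = 0.02,
      extra = list(n_missing = sum(is.na(miss$counts))))
  ld <- simulate_structured_population(
    population_spec(50, 0.02, 300, ld_rho = 0.8), seed = seed + 3L)
  add("ld_markers", ld, true_fst = 0.02, extra = list(ld_rho = 0.8))
  trait_g <- simulate_structured_population(
    population_spec(100, 0.02, 500), seed = seed + 4L)
  trait <- assign_trait(trait_g, n_causal = 50, h2 = 0.55,
                        seed = seed + 4L)
  y <- simulate_phenotypes(trait_g, trait, seed = seed + 5L)
  add("trait_genotypes", trait_g, true_fst = 0.02,
      extra = list(n_causal = 50, h2_target = 0.55,
                   h2_realized = trait$h2_realized))
  write.csv(data.frame(id = trait_g$sample_ids, y = as.numeric(y)),
            file.path(dir, "trait_phenotypes.csv"),
            row.names = FALSE, quote = FALSE)
  manifest$fixtures[["trait_phenotypes"]] <-
    list(file = "trait_phenotypes.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
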