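#' Uniform genetic map
#'
#' Allocates markers uniformly across chromosomes of fixed genetic length,
#' with evenly spaced positions within each chromosome. The default of 21
#' chromosomes of 1 Morgan each mirrors a hexaploid wheat karyotype with
#' roughly one crossover per chromosome arm pair per meiosis.
#'
#' @param n_markers number of markers.
#' @param n_chrom number of chromosomes, default 21.
#' @param chrom_length genetic length per chromosome in Morgans, default 1.
#' @return an object of class `genetic_map` with fields `chrom_of`,
#'   `pos_morgans` and `chrom_length`.
#' @export
make_genetic_map <- function(n_markers, n_chrom = 21L, chrom_length = 1) {
  chrom_of <- sort(rep_len(seq_len(n_chrom), n_markers))
  pos <- numeric(n_markers)
  for (c in seq_len(n_chrom)) {
    idx <- which(chrom_of == c)
    q <- length(idx)
    pos[idx] <- (seq_len(q) - 0.5) / q * chrom_length
  }
  structure(list(chrom_of = chrom_of, pos_morgans = pos,
                 chrom_length = chrom_length, n_chrom = n_chrom),
            class = "genetic_map")
}

# split unphased genotypes into two haplotype matrices; heterozygote
# alleles are assigned to a haplotype at random (true phase is unknown)
.phase_genotypes <- function(counts) {
  h1 <- (counts == 2) + 0
  h2 <- h1
  het <- counts == 1
  flip <- matrix(runif(length(counts)) < 0.5, nrow(counts))
  h1[het & flip] <- 1
  h2[het & !flip] <- 1
  list(h1 = h1, h2 = h2)
}

# one gamete from a phased parent: per chromosome, Poisson(length)
# crossovers at uniform positions, no interference, random start phase
.gamete <- function(h1_row, h2_row, map) {
  phase <- integer(length(h1_row))
  for (c in seq_len(map$n_chrom)) {
    idx <- which(map$chrom_of == c)
    n_x <- rpois(1, map$chrom_length)
    start <- sample(0:1, 1)
    if (n_x == 0) {
      phase[idx] <- start
    } else {
      bp <- sort(runif(n_x, 0, map$chrom_length))
      phase[idx] <- (start + findInterval(map$pos_morgans[idx], bp)) %% 2
    }
  }
  ifelse(phase == 0, h1_row, h2_row)
}

#' Random mating with recombination
#'
#' Generates progeny marker profiles from a parent panel. Each progeny
#' draws two distinct parents uniformly (no selfing); each parent
#' contributes one recombinant gamete with crossover counts per
#' chromosome Poisson-distributed with mean equal to the chromosome's
#' genetic length in Morgans, breakpoints uniform and no interference.
#' Unphased parent genotypes are phased by random assignment of
#' heterozygote alleles within the call — an approximation, since true
#' phase is unavailable from count data.
#'
#' @param parents a [genotype_matrix()] with at least 2 samples and no
#'   missing entries.
#' @param map a [make_genetic_map()] covering all markers.
#' @param n_progeny number of offspring to generate.
#' @param seed RNG seed.
#' @param id_prefix prefix for progeny sample ids.
#' @return a [genotype_matrix()] of the progeny.
#' @export
random_mating <- function(parents, map, n_progeny, seed = 1L,
                          id_prefix = "prog") {
  stopifnot(inherits(parents, "genotype_matrix"),
            inherits(map, "genetic_map"))
  n_par <- nrow(parents$counts)
  if (n_par < 2) stop("need at least 2 parents (no selfing)")
  if (length(map$chrom_of) != ncol(parents$counts))
    stop("genetic map does not cover the marker set")
  if (anyNA(parents$counts)) stop("missing entries in parents")
  set.seed(seed)
  ph <- .phase_genotypes(parents$counts)
  m <- ncol(parents$counts)
  out <- matrix(NA_real_, n_progeny, m)
  for (i in seq_len(n_progeny)) {
    pp <- sample.int(n_par, 2, replace = FALSE)
    out[i, ] <- .gamete(ph$h1[pp[1], ], ph$h2[pp[1], ], map) +
      .gamete(ph$h1[pp[2], ], ph$h2[pp[2], ], map)
  }
  genotype_matrix(out,
                  sample_ids = sprintf("%s_%04d", id_prefix,
                                       seq_len(n_progeny)),
                  marker_ids = parents$marker_ids,
                  chrom = map$chrom_of, pos = map$pos_morgans)
}

#' Define an additive trait on a founder panel
#'
#' Selects `n_causal` causal variants at random among markers with founder
#' minor allele frequency above `maf_min`, assigns them mean-zero
#' normally distributed additive effects, and rescales the effects so
#' that the realized genetic-variance ratio
#' \eqn{Var(X\beta) / (Var(X\beta) + \sigma_\epsilon^2)} equals `h2` in
#' the founder sample exactly (noise standard deviation fixed at
#' `noise_sd`). The default heritability 0.55 is the midpoint of the
#' 0.40-0.70 range typical of the quantitative traits this framework
#' targets.
#'
#' @param founders a [genotype_matrix()] with no missing entries.
#' @param n_causal number of causal variants.
#' @param h2 target narrow-sense heritability in the founders, default
#'   0.55; `h2 = 0` yields a pure-noise trait with zero effects.
#' @param maf_min eligibility threshold for causal variants, default 0.05.
#' @param noise_sd residual standard deviation, default 1.
#' @param seed RNG seed.
#' @return an object of class `trait_model` with fields `causal_idx`,
#'   `effects`, `noise_sd`, `h2_target`, `h2_realized`.
#' @export
assign_trait <- function(founders, n_causal, h2 = 0.55, maf_min = 0.05,
                         noise_sd = 1, seed = 1L) {
  stopifnot(inherits(founders, "genotype_matrix"))
  if (anyNA(founders$counts)) stop("missing entries in founders")
  if (!(h2 >= 0 && h2 < 1)) stop("h2 must be in [0, 1)")
  p <- colMeans(founders$counts) / 2
  eligible <- which(pmin(p, 1 - p) > maf_min)
  if (length(eligible) < n_causal)
    stop("only ", length(eligible), " markers pass MAF > ", maf_min,
         "; cannot place ", n_causal, " causal variants")
  set.seed(seed)
  causal <- sort(sample(eligible, n_causal))
  if (h2 == 0) {
    effects <- rep(0, n_causal)
    h2_real <- 0
  } else {
    effects <- rnorm(n_causal)
    gv <- as.numeric(founders$counts[, causal, drop = FALSE] %*% effects)
    v <- var(gv)
    if (v == 0) stop("degenerate genetic values: causal markers constant")
    target_var <- h2 / (1 - h2) * noise_sd^2
    effects <- effects * sqrt(target_var / v)
    gv <- as.numeric(founders$counts[, causal, drop = FALSE] %*% effects)
    h2_real <- var(gv) / (var(gv) + noise_sd^2)
  }
  structure(list(causal_idx = causal,
                 effects = setNames(effects, founders$marker_ids[causal]),
                 noise_sd = noise_sd, h2_target = h2,
                 h2_realized = h2_real),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("trait_model: ", length(x$causal_idx), " causal variants, ",
      "noise sd ", x$noise_sd, ", realized h2 = ",
      signif(x$h2_realized, 4), "\n", sep = "")
  invisible(x)
}

#' Genetic values of a trait
#'
#' @param g a [genotype_matrix()] whose markers match the trait model.
#' @param trait a `trait_model`.
#' @return numeric vector \eqn{X\beta} over the causal variants.
#' @export
genetic_values <- function(g, trait) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(trait, "trait_model"))
  if (!all(names(trait$effects) %in% g$marker_ids))
    stop("trait model refers to markers absent from the genotype matrix")
  idx <- match(names(trait$effects), g$marker_ids)
  as.numeric(g$counts[, idx, drop = FALSE] %*% trait$effects)
}

#' Simulate phenotypes under a trait model
#'
#' \eqn{y = X\beta + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}.
#'
#' @param g a [genotype_matrix()].
#' @param trait a `trait_model`.
#' @param seed RNG seed.
#' @return named numeric vector of phenotypes.
#' @export
simulate_phenotypes <- function(g, trait, seed = 1L) {
  gv <- genetic_values(g, trait)
  set.seed(seed)
  setNames(gv + rnorm(length(gv), 0, trait$noise_sd), g$sample_ids)
}

#' Forward simulation of a genomic selection program
#'
#' Repeats, `replicates` times, a sequence of `rounds` rounds of
#' truncation selection starting from the founder panel: each round
#' generates `n_progeny` offspring by random mating (no selfing), draws
#' their phenotypes under the fixed trait model, estimates the
#' Beta-Binomial F_ST between the founders (treated as ancestral) and the
#' progeny, computes the predictive correlation between the
#' founder-fitted model's predictions and the realized phenotypes, and
#' selects the `n_selected` individuals with the largest phenotypes as
#' the parents of the next round. The prediction model is fitted once on
#' the founders and never updated, so the trajectory measures how its
#' accuracy decays as the program drifts away from the training
#' population.
#'
#' @param founders a [genotype_matrix()] with no missing entries.
#' @param trait a `trait_model` defined on the founders.
#' @param model a `gp_model` fitted on the founders with standardization
#'   constants stored (fit on the founders' `standardized_matrix`).
#' @param map a [make_genetic_map()]; defaults to a uniform 21-chromosome
#'   map.
#' @param rounds rounds of selection per replicate, default 10.
#' @param n_progeny offspring per round, default 200.
#' @param n_selected parents kept per round (>= 2), default 20.
#' @param replicates independent program replicates, default 100.
#' @param seed RNG seed.
#' @param keep_progeny number of initial rounds whose progeny (genotypes
#'   and phenotypes, replicate 1 only) are retained for later training-set
#'   augmentation; default 0.
#' @return an object of class `selection_trajectory`: `per_round` (data
#'   frame with `replicate`, `round`, `fst`, `rho`), `summary` (per-round
#'   means), and `retained` (list of kept progeny, possibly empty).
#' @export
run_selection_program <- function(founders, trait, model, map = NULL,
                                  rounds = 10L, n_progeny = 200L,
                                  n_selected = 20L, replicates = 100L,
                                  seed = 1L, keep_progeny = 0L) {
  stopifnot(inherits(founders, "genotype_matrix"),
            inherits(trait, "trait_model"), inherits(model, "gp_model"))
  if (n_selected < 2) stop("n_selected must be at least 2 (no selfing)")
  if (is.null(model$center))
    stop("model lacks standardization constants: fit it on the founders' ",
         "standardized_matrix")
  if (is.null(map)) map <- make_genetic_map(ncol(founders$counts))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  per_round <- vector("list", replicates)
  retained <- list()
  for (rep_i in seq_len(replicates)) {
    set.seed(rep_seeds[rep_i])
    round_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                     2 * rounds), ncol = 2)
    parents <- founders
    rows <- vector("list", rounds)
    for (rd in seq_len(rounds)) {
      progeny <- random_mating(parents, map, n_progeny,
                               seed = round_seeds[rd, 1],
                               id_prefix = sprintf("r%02dg%02d", rep_i, rd))
      y <- simulate_phenotypes(progeny, trait, seed = round_seeds[rd, 2])
      fst <- fst_between_matrices(founders, progeny)$value
      g_pred <- if (identical(progeny$marker_ids, model$marker_ids))
        progeny
      else
        subset_genotypes(progeny, markers = match(model$marker_ids,
                                                  progeny$marker_ids))
      y_hat <- predict_phenotypes(
        model, standardize_with(g_pred, model_ref(model, founders)))
      rho <- predictive_correlation(y_hat, as.numeric(y))
      rows[[rd]] <- data.frame(replicate = rep_i, round = rd,
                               fst = fst, rho = rho)
      if (rep_i == 1L && rd <= keep_progeny)
        retained[[rd]] <- list(genotypes = progeny, phenotypes = y)
      sel <- order(y, decreasing = TRUE)[seq_len(n_selected)]
      parents <- subset_genotypes(progeny, samples = sel)
    }
    per_round[[rep_i]] <- do.call(rbind, rows)
  }
  per_round <- do.call(rbind, per_round)
  summ <- do.call(rbind, lapply(split(per_round, per_round$round),
    function(d) data.frame(round = d$round[1], mean_fst = mean(d$fst),
                           mean_rho = mean(d$rho))))
  rownames(summ) <- NULL
  structure(list(per_round = per_round, summary = summ,
                 retained = retained),
            class = "selection_trajectory")
}

# reference object carrying the model's standardization constants
model_ref <- function(model, g) {
  list(center = model$center, scale = model$scale,
       marker_ids = model$marker_ids %||% g$marker_ids)
}

#' @export
print.selection_trajectory <- function(x, ...) {
  cat("selection_trajectory over", max(x$summary$round), "rounds,",
      max(x$per_round$replicate), "replicates\n")
  print(x$summary)
  invisible(x)
}

#' Augment the training population and refit the prediction model
#'
#' Adds the progeny retained from the first rounds of a selection program
#' to the founder panel (progeny already carry unique ids) and refits the
#' elastic net on the enlarged sample, emulating the recalibration of a
#' genomic prediction model with new varieties from the breeding program.
#'
#' @param founders a [genotype_matrix()].
#' @param y_founders founder phenotypes aligned with `founders`.
#' @param trajectory a `selection_trajectory` run with `keep_progeny >= 1`.
#' @param seed RNG seed for the refit.
#' @param ... further arguments to [fit_elastic_net()].
#' @return a list with `genotypes` (augmented panel), `phenotypes`,
#'   `standardized` and `model` (the refitted `gp_model`).
#' @export
augment_and_refit <- function(founders, y_founders, trajectory, seed = 1L,
                              ...) {
  stopifnot(inherits(trajectory, "selection_trajectory"))
  if (length(trajectory$retained) == 0)
    stop("trajectory retained no progeny: rerun with keep_progeny >= 1")
  gs <- c(list(founders),
          lapply(trajectory$retained, `[[`, "genotypes"))
  counts <- do.call(rbind, lapply(gs, `[[`, "counts"))
  ids <- unlist(lapply(gs, `[[`, "sample_ids"))
  g_aug <- genotype_matrix(counts, sample_ids = ids,
                           marker_ids = founders$marker_ids)
  y_aug <- c(as.numeric(y_founders),
             unlist(lapply(trajectory$retained,
                           function(r) as.numeric(r$phenotypes))))
  x_aug <- standardize(apply_qc(g_aug, maf_min = 1e-9, missing_max = 0.99))
  # QC with a tiny threshold only drops markers fixed in the pooled panel
  g_aug <- subset_genotypes(g_aug,
                            markers = match(x_aug$marker_ids,
                                            g_aug$marker_ids))
  model <- fit_elastic_net(x_aug, y_aug, seed = seed, ...)
  list(genotypes = g_aug, phenotypes = y_aug, standardized = x_aug,
       model = model)
}

#' Cross-population prediction experiment
#'
#' Fits the prediction model on one labelled population and evaluates it
#' on every other: per target population, the Beta-Binomial F_ST from the
#' training population (treated as ancestral), the predictive correlation,
#' and its 95% confidence interval from the Fisher z transform
#' (flagged wide when the target has fewer than 10 members). The same
#' trait model — identical causal variants and effect sizes — applies to
#' all populations.
#'
#' @param g a [genotype_matrix()] with `pop_labels` (>= 2 labels).
#' @param train_pop the label of the training population.
#' @param trait a `trait_model`.
#' @param seed RNG seed (phenotype noise and model tuning).
#' @param ... further arguments to [fit_elastic_net()].
#' @return a data frame with columns `pop`, `n`, `fst`, `rho`, `ci_low`,
#'   `ci_high`, `wide_ci`.
#' @export
cross_population_experiment <- function(g, train_pop, trait, seed = 1L,
                                        ...) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(trait, "trait_model"))
  if (is.null(g$pop_labels) || length(unique(g$pop_labels)) < 2)
    stop("need pop_labels with at least 2 populations")
  if (!train_pop %in% g$pop_labels)
    stop("train_pop '", train_pop, "' not found")
  set.seed(seed)
  y_seed <- sample.int(1e8, 1)
  fit_seed <- sample.int(1e8, 1)
  y <- simulate_phenotypes(g, trait, seed = y_seed)
  tr <- which(g$pop_labels == train_pop)
  g_tr <- subset_genotypes(g, samples = tr)
  # markers monomorphic in the training population carry no information
  poly <- which(apply(g_tr$counts, 2, stats::sd) > 0)
  x_tr <- standardize(subset_genotypes(g_tr, markers = poly))
  model <- fit_elastic_net(x_tr, as.numeric(y[tr]), seed = fit_seed, ...)
  out <- list()
  for (pop in setdiff(unique(g$pop_labels), train_pop)) {
    ta <- which(g$pop_labels == pop)
    g_ta <- subset_genotypes(g, samples = ta, markers = poly)
    y_hat <- predict_phenotypes(model, standardize_with(g_ta, x_tr))
    rho <- predictive_correlation(y_hat, as.numeric(y[ta]))
    n_ta <- length(ta)
    z <- atanh(rho)
    half <- 1.96 / sqrt(n_ta - 3)
    out[[pop]] <- data.frame(
      pop = pop, n = n_ta,
      fst = fst_beta_binomial(g, tr, ta)$value,
      rho = rho, ci_low = tanh(z - half), ci_high = tanh(z + half),
      wide_ci = n_ta < 10)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
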