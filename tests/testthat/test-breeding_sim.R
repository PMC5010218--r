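founder_panel <- function(n = 60, m = 400, seed = 1, F = 0.05) {
  simulate_structured_population(
    population_spec(c(n / 2, n / 2), c(1e-6, F), m), seed = seed)
}

test_that("the genetic map spreads markers uniformly over chromosomes", {
  map <- make_genetic_map(430, n_chrom = 21)
  expect_length(map$chrom_of, 430)
  expect_equal(sort(unique(map$chrom_of)), 1:21)
  for (c in unique(map$chrom_of)) {
    pos <- map$pos_morgans[map$chrom_of == c]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos > 0 & pos < 1))
  }
})

test_that("random mating conserves allele frequencies without selection", {
  g <- founder_panel(seed = 2)
  map <- make_genetic_map(ncol(g$counts))
  deltas <- sapply(1:20, function(s) {
    prog <- random_mating(g, map, 100, seed = s)
    p0 <- colMeans(g$counts) / 2
    p1 <- colMeans(prog$counts) / 2
    se <- sqrt(pmax(p0 * (1 - p0), 1e-6) / 200)
    mean(abs(p1 - p0) < 4 * se)
  })
  expect_gt(mean(deltas), 0.95)
})

test_that("homozygous parents breed true and selfing never occurs", {
  counts <- matrix(0, 5, 60)
  counts[, 1:30] <- 2  # all parents homozygous everywhere
  g <- genotype_matrix(counts)
  map <- make_genetic_map(60, n_chrom = 3)
  prog <- random_mating(g, map, 20, seed = 4)
  expect_true(all(prog$counts[, 1:30] == 2))
  expect_true(all(prog$counts[, 31:60] == 0))
  single <- subset_genotypes(g, samples = 1)
  expect_error(random_mating(single, map, 5), "at least 2 parents")
})

test_that("trait assignment hits the target heritability exactly", {
  g <- founder_panel(n = 200, m = 2000, seed = 11)
  trait <- assign_trait(g, 200, h2 = 0.55, seed = 12)
  expect_equal(trait$h2_realized, 0.55, tolerance = 1e-6)
  gv <- genetic_values(g, trait)
  expect_equal(var(gv) / (var(gv) + 1), 0.55, tolerance = 1e-6)
  # causal variants respect the MAF filter
  p <- colMeans(g$counts) / 2
  expect_true(all(pmin(p, 1 - p)[trait$causal_idx] > 0.05))
  # boundary cases
  flat <- assign_trait(g, 50, h2 = 0, seed = 13)
  expect_true(all(flat$effects == 0))
  one <- assign_trait(g, 1, h2 = 0.3, seed = 14)
  expect_equal(sum(one$effects != 0), 1)
  expect_error(assign_trait(g, ncol(g$counts) + 1, seed = 1),
               "cannot place")
})

test_that("phenotypes are genetic values plus seeded Gaussian noise", {
  g <- founder_panel(n = 200, m = 600, seed = 15)
  trait <- assign_trait(g, 60, h2 = 0.55, seed = 16)
  y1 <- simulate_phenotypes(g, trait, seed = 17)
  y2 <- simulate_phenotypes(g, trait, seed = 17)
  expect_identical(y1, y2)
  # regression of y on the genetic value has slope near 1
  slopes <- sapply(1:20, function(s) {
    y <- simulate_phenotypes(g, trait, seed = 100 + s)
    gv <- genetic_values(g, trait)
    coef(lm(as.numeric(y) ~ gv))[2]
  })
  expect_lt(abs(mean(slopes) - 1), 0.15)
  # zero noise returns the genetic value exactly
  t0 <- trait; t0$noise_sd <- 0
  expect_equal(as.numeric(simulate_phenotypes(g, t0, seed = 1)),
               genetic_values(g, t0), tolerance = 1e-12)
})

test_that("selection drives F_ST up and predictive correlation down", {
  g <- founder_panel(n = 100, m = 500, seed = 21)
  trait <- assign_trait(g, 100, h2 = 0.55, seed = 22)
  y <- simulate_phenotypes(g, trait, seed = 23)
  x <- standardize(g)
  model <- fit_elastic_net(x, as.numeric(y), cv_runs = 1, folds = 5,
                           alphas = c(0.5, 1), seed = 24)
  map <- make_genetic_map(500)
  traj <- run_selection_program(g, trait, model, map, rounds = 4,
                                n_progeny = 80, n_selected = 15,
                                replicates = 5, seed = 25)
  expect_equal(nrow(traj$summary), 4)
  expect_equal(nrow(traj$per_round), 20)
  expect_gt(cor(traj$summary$round, traj$summary$mean_fst,
                method = "spearman"), 0.9)
  expect_gte(traj$summary$mean_rho[1], traj$summary$mean_rho[4])
})

test_that("a zero-heritability trait yields near-zero trajectory accuracy", {
  g <- founder_panel(n = 80, m = 300, seed = 31)
  trait <- assign_trait(g, 50, h2 = 0.4, seed = 32)
  flat <- trait; flat$effects[] <- 0  # no genetic signal in phenotypes
  y <- simulate_phenotypes(g, trait, seed = 33)
  x <- standardize(g)
  model <- fit_elastic_net(x, as.numeric(y), cv_runs = 1, folds = 5,
                           alphas = 1, seed = 34)
  traj <- run_selection_program(g, flat, model, make_genetic_map(300),
                                rounds = 2, n_progeny = 60,
                                n_selected = 15, replicates = 5,
                                seed = 35)
  expect_lt(abs(mean(traj$per_round$rho)), 0.15)
})

test_that("augmentation grows the panel and does not hurt training fit", {
  g <- founder_panel(n = 80, m = 400, seed = 41)
  trait <- assign_trait(g, 80, h2 = 0.55, seed = 42)
  y <- simulate_phenotypes(g, trait, seed = 43)
  x <- standardize(g)
  model <- fit_elastic_net(x, as.numeric(y), cv_runs = 1, folds = 5,
                           alphas = c(0.5, 1), seed = 44)
  traj <- run_selection_program(g, trait, model, make_genetic_map(400),
                                rounds = 2, n_progeny = 60,
                                n_selected = 15, replicates = 1,
                                seed = 45, keep_progeny = 2)
  aug <- augment_and_refit(g, y, traj, seed = 46, cv_runs = 1,
                           folds = 5, alphas = c(0.5, 1))
  expect_equal(nrow(aug$genotypes$counts), 80 + 2 * 60)
  expect_false(anyDuplicated(aug$genotypes$sample_ids) > 0)
  rho_aug <- predictive_correlation(
    predict_phenotypes(aug$model, aug$standardized), aug$phenotypes)
  expect_gt(rho_aug, 0.3)
  bare <- run_selection_program(g, trait, model, make_genetic_map(400),
                                rounds = 1, n_progeny = 20,
                                n_selected = 5, replicates = 1, seed = 1)
  expect_error(augment_and_refit(g, y, bare, seed = 1), "keep_progeny")
})

test_that("cross-population accuracy decreases with divergence on average", {
  rhos <- sapply(1:20, function(s) {
    g <- simulate_structured_population(
      population_spec(c(80, 40, 40), c(1e-6, 0.02, 0.15), 600),
      seed = 3000 + s)
    trait <- assign_trait(g, 80, h2 = 0.55, seed = s)
    res <- cross_population_experiment(g, "P1", trait, seed = s,
                                       cv_runs = 1, folds = 5,
                                       alphas = c(0.5, 1))
    res$rho[order(res$fst)]
  })
  # per-target-population mean over seeds: nearer population predicted
  # better than the more diverged one
  expect_gt(mean(rhos[1, ]), mean(rhos[2, ]))
  expect_gt(mean(rhos[1, ] - rhos[2, ]) /
              (sd(rhos[1, ] - rhos[2, ]) / sqrt(20)), 2)  # clear signal
})

test_that("Fisher-z intervals are ordered and widen for small targets", {
  g <- simulate_structured_population(
    population_spec(c(60, 40, 12), c(1e-6, 0.05, 0.05), 500), seed = 51)
  trait <- assign_trait(g, 50, h2 = 0.55, seed = 52)
  res <- cross_population_experiment(g, "P1", trait, seed = 53,
                                     cv_runs = 1, folds = 5, alphas = 1)
  expect_true(all(res$ci_low < res$rho & res$rho < res$ci_high))
  big <- res[res$pop == "P2", ]; small <- res[res$pop == "P3", ]
  expect_gt(small$ci_high - small$ci_low, big$ci_high - big$ci_low)
})

test_that("neutral drift alone moves F_ST only slowly", {
  g <- founder_panel(n = 100, m = 500, seed = 61, F = 0.02)
  map <- make_genetic_map(500)
  fsts <- sapply(1:10, function(s) {
    pop <- g
    for (gen in 1:5)
      pop <- random_mating(pop, map, 100, seed = 100 * s + gen)
    fst_beta_binomial(
      genotype_matrix(rbind(g$counts,
                            `rownames<-`(pop$counts,
                                         paste0("x", 1:100))),
                      sample_ids = c(g$sample_ids, paste0("x", 1:100)),
                      marker_ids = g$marker_ids),
      1:100, 101:200)$value
  })
  expect_lt(mean(fsts), 0.04)
})
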