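test_that("k-means recovers duplicated-genotype groups exactly", {
  counts <- rbind(matrix(0, 5, 30), matrix(2, 3, 30))
  # jitter one marker so no two samples are exactly identical points
  counts[, 1] <- c(0, 1, 0, 1, 0, 2, 1, 2)
  g <- genotype_matrix(counts)
  pair <- split_minimally_related(standardize(g), seed = 1)
  expect_setequal(pair$train_idx, 1:5)   # larger group trains
  expect_setequal(pair$target_idx, 6:8)
  expect_equal(pair$m, 0L)
})

test_that("clusters match generating populations on structured fixtures", {
  hits <- sapply(1:20, function(s) {
    g <- simulate_structured_population(
      population_spec(c(50, 50), c(0.05, 0.05), 2000), seed = 500 + s)
    pair <- split_minimally_related(standardize(apply_qc(g)), seed = s)
    truth <- g$pop_labels == "P1"
    got <- seq_len(100) %in% pair$train_idx
    max(mean(got == truth), mean(got != truth))  # label alignment
  })
  expect_gte(sum(hits >= 0.95), 18)
})

test_that("the larger cluster becomes the training subsample", {
  g <- simulate_structured_population(
    population_spec(c(120, 80), c(0.08, 0.08), 1500), seed = 77)
  pair <- split_minimally_related(standardize(apply_qc(g)), seed = 2)
  expect_gte(length(pair$train_idx), length(pair$target_idx))
})

test_that("rebalance strips the target greedily, matching brute force", {
  g <- two_pop_fixture(0.10, n_each = 12, n_markers = 400, seed = 9)
  pair <- subset_pair(1:12, 13:24)
  expect_identical(rebalance(pair, g, 12), pair)  # size already met

  suppressWarnings(reb <- rebalance(pair, g, 11))
  # oracle: exhaustive comparison of the 12 possible single moves
  cand_fst <- sapply(13:24, function(j)
    fst_beta_binomial(g, c(1:12, j), setdiff(13:24, j))$value)
  moved <- setdiff(13:24, reb$target_idx)
  expect_equal(moved, (13:24)[which.max(cand_fst)])
  expect_equal(length(reb$train_idx), 13)
  # deterministic
  suppressWarnings(reb2 <- rebalance(pair, g, 11))
  expect_identical(reb$target_idx, reb2$target_idx)
  expect_warning(rebalance(pair, g, 8), "smaller than 10")
  expect_error(rebalance(pair, g, 20), "exceeds")
})

test_that("swaps conserve sizes and disjointness; boundaries behave", {
  pair <- subset_pair(1:10, 11:18)
  s0 <- swap(pair, 0, seed = 3)
  expect_setequal(s0$train_idx, 1:10)
  for (m in c(1, 4, 8)) {
    sm <- swap(pair, m, seed = m)
    expect_length(sm$train_idx, 10)
    expect_length(sm$target_idx, 8)
    expect_length(intersect(sm$train_idx, sm$target_idx), 0)
    expect_setequal(union(sm$train_idx, sm$target_idx), 1:18)
    expect_equal(sm$m, m)
  }
  # full swap of equal sides exchanges them when all members are chosen
  eq <- subset_pair(1:4, 5:8)
  sf <- swap(eq, 4, seed = 1)
  expect_setequal(sf$train_idx, 5:8)
  expect_setequal(sf$target_idx, 1:4)
  expect_error(swap(pair, 9), "exceeds")
})

test_that("swap series stops once mean F_ST reaches the threshold", {
  g <- two_pop_fixture(0.08, n_each = 150, n_markers = 1000, seed = 15)
  x <- standardize(apply_qc(g))
  pair0 <- split_minimally_related(x, seed = 4)
  ser <- generate_swap_series(x, g, pair0, step = 20, reps_per_m = 4,
                              seed = 21)
  expect_equal(ser$schedule[1], 0L)
  expect_equal(sum(sapply(ser$pairs, `[[`, "m") == 0), 1)
  counts_per_m <- table(sapply(ser$pairs, `[[`, "m"))
  expect_true(all(counts_per_m[names(counts_per_m) != "0"] == 4))
  last <- length(ser$mean_fst)
  expect_lte(ser$mean_fst[last], 0.005)
  expect_true(all(ser$mean_fst[-last] > 0.005))
  # every emitted pair respects the invariants
  for (p in ser$pairs) {
    expect_length(intersect(p$train_idx, p$target_idx), 0)
    expect_length(p$train_idx, length(pair0$train_idx))
    expect_length(p$target_idx, length(pair0$target_idx))
  }
})

test_that("an unstructured split below the threshold yields the one-point series", {
  # a random split of a homogeneous population sits at the estimator
  # floor of roughly 1/(2 n_TR), below the 0.005 stopping threshold
  g <- simulate_structured_population(
    population_spec(300, 1e-6, 1500), seed = 33)
  x <- standardize(apply_qc(g))
  pair0 <- subset_pair(1:150, 151:300)
  ser <- generate_swap_series(x, g, pair0, reps_per_m = 3, seed = 6)
  expect_equal(ser$schedule, 0L)
  expect_length(ser$pairs, 1)
  expect_lte(ser$mean_fst, 0.005)
})

test_that("swap counts are capped at the maximal-mixing point", {
  # beyond m* = n_TR n_TA / n swapping re-segregates: a full swap of
  # equal sides restores the original split exactly
  g <- two_pop_fixture(0.10, n_each = 25, n_markers = 600, seed = 35)
  x <- standardize(apply_qc(g))
  pair0 <- subset_pair(1:25, 26:50)
  expect_warning(
    ser <- generate_swap_series(x, g, pair0, step = 10, reps_per_m = 2,
                                seed = 7),
    "never fell")
  expect_equal(max(ser$schedule), round(25 * 25 / 50))
})

test_that("mean F_ST trends downward along the schedule", {
  ok <- sapply(1:20, function(s) {
    g <- two_pop_fixture(0.06, n_each = 30, n_markers = 800,
                         seed = 700 + s)
    x <- standardize(apply_qc(g))
    pair0 <- split_minimally_related(x, seed = s)
    suppressWarnings(  # small fixture cannot reach the stopping threshold
      ser <- generate_swap_series(x, g, pair0, step = 6, reps_per_m = 3,
                                  seed = s))
    length(ser$mean_fst) < 2 ||
      cor(seq_along(ser$mean_fst), ser$mean_fst,
          method = "spearman") <= 0
  })
  expect_gte(sum(ok), 18)
})

test_that("auto step keeps the schedule at no more than 30 points", {
  for (m_max in c(10, 60, 150, 400)) {
    s <- gpdecay:::auto_step(m_max)
    expect_true(s >= 2 && s <= 20)
    expect_lte(floor(m_max / s) + 1, 30)
  }
})

test_that("subset pairs serialize with their JSON sidecar", {
  g <- toy_genotypes(n = 8, m = 6)
  pair <- subset_pair(1:5, 6:8, m = 2L, seed = 99L, fst = 0.04)
  f <- tempfile(fileext = ".csv")
  write_subset_pair(pair, g, f)
  df <- read.csv(f)
  expect_equal(sum(df$role == "train"), 5)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(side$m, 2)
  expect_equal(side$fst, 0.04)
})
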