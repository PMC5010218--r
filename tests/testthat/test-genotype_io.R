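test_that("csv round-trip preserves ids, counts and missingness", {
  f <- write_csv_fixture(c("id,m1,m2,m3,m4",
                           "a,0,1,2,0",
                           "b,1,,2,1",
                           "c,2,0,0,2"))
  g <- read_genotypes(f, "csv")
  expect_equal(dim(g), c(3L, 4L))
  expect_equal(g$sample_ids, c("a", "b", "c"))
  expect_equal(g$marker_ids, c("m1", "m2", "m3", "m4"))
  expect_true(is.na(g$counts["b", "m2"]))
  expect_equal(unname(g$counts["a", ]), c(0, 1, 2, 0))

  out <- tempfile(fileext = ".csv")
  write_genotypes(g, out)
  expect_identical(readLines(out), readLines(f))
  g2 <- read_genotypes(out, "csv")
  expect_equal(g2$counts, g$counts)
})

test_that("plink_raw dialect parses and flags NA as missing", {
  f <- write_csv_fixture(c(
    "FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_T",
    "f1 i1 0 0 1 -9 0 NA",
    "f2 i2 0 0 2 -9 2 1"))
  g <- read_genotypes(f, "plink_raw")
  expect_equal(g$sample_ids, c("i1", "i2"))
  expect_true(is.na(g$counts["i1", "snp2_T"]))
  expect_equal(unname(g$counts["i2", ]), c(2, 1))
})

test_that("malformed inputs raise informative errors", {
  dup <- write_csv_fixture(c("id,m1", "a,0", "a,1"))
  expect_error(read_genotypes(dup, "csv"), "duplicated sample ids")
  bad <- write_csv_fixture(c("id,m1,m2", "a,0,3", "b,1,0"))
  expect_error(read_genotypes(bad, "csv"), "not in \\{0, 1, 2\\}")
  nonnum <- write_csv_fixture(c("id,m1", "a,x"))
  expect_error(read_genotypes(nonnum, "csv"), "line 2")
  expect_error(read_genotypes(tempfile(), "csv"), "not found")
})

test_that("apply_qc retains exactly the markers passing both thresholds", {
  # 10 markers with hand-computed MAF / missingness
  counts <- cbind(
    rep(0, 8),            # MAF 0 -> removed
    c(rep(1, 8)),         # freq .5
    c(2, rep(0, 7)),      # freq 2/16 = .125
    c(1, rep(0, 7)),      # freq 1/16 = .0625
    c(rep(2, 8)),         # freq 1, MAF 0 -> removed
    c(NA, NA, 1, 1, 1, 1, 1, 1),     # 25% missing -> removed at 0.20
    c(NA, 1, 1, 1, 1, 1, 1, 1),      # 12.5% missing, kept
    c(0, 2, 0, 2, 0, 2, 0, 2),       # freq .5
    c(rep(0, 7), 1),      # freq 1/16
    c(rep(1, 4), rep(0, 4)))         # freq .25
  g <- genotype_matrix(counts, sample_ids = paste0("s", 1:8),
                       marker_ids = paste0("m", 1:10))
  kept <- apply_qc(g, maf_min = 0.05, missing_max = 0.20)$marker_ids
  expect_equal(kept, paste0("m", c(2, 3, 4, 7, 8, 9, 10)))
  # the > 20% missing rule is strict: exactly 25% missing is removed
  expect_false("m6" %in% kept)
  # tighter MAF threshold also removes the 1/16-frequency markers
  kept2 <- apply_qc(g, maf_min = 0.10, missing_max = 0.20)$marker_ids
  expect_equal(kept2, paste0("m", c(2, 3, 7, 8, 10)))
  expect_error(apply_qc(g, maf_min = 0.6), "maf_min")
  mono <- genotype_matrix(matrix(0, 4, 2))
  expect_error(apply_qc(mono), "all markers removed")
})

test_that("imputation fills every hole, leaves observed calls, rounds legally", {
  g <- toy_genotypes(n = 12, m = 10, seed = 3, missing = 6)
  imp <- impute_missing(g, k_neighbours = 4)
  expect_false(anyNA(imp$counts))
  obs <- !is.na(g$counts)
  expect_equal(imp$counts[obs], g$counts[obs])
  expect_true(all(imp$counts %in% 0:2))

  # no missing entries -> identity
  full <- toy_genotypes(missing = 0)
  expect_identical(impute_missing(full)$counts, full$counts)

  # identical samples -> the shared value is imputed
  counts <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(0, 1, 2, 1),
                  c(0, 1, NA, 1))
  gi <- genotype_matrix(counts)
  expect_equal(impute_missing(gi, k_neighbours = 3)$counts[4, 3], 2)

  # a fully missing sample is an error
  counts[4, ] <- NA
  expect_error(impute_missing(genotype_matrix(counts)),
               "missing at every marker")
})

test_that("imputation matches a brute-force kNN oracle on a 5x5 fixture", {
  counts <- rbind(c(0, 1, 2, 1, 0),
                  c(0, 1, 2, 1, 0),
                  c(2, 1, 0, 1, 2),
                  c(NA, 1, 2, 1, 0),
                  c(2, 1, NA, 1, 2))
  g <- genotype_matrix(counts)
  imp <- impute_missing(g, k_neighbours = 2)
  # oracle: enumerate neighbour distances by hand
  oracle_impute <- function(i, k) {
    d <- sapply(1:5, function(j) {
      if (j == i) return(Inf)
      sh <- !is.na(counts[i, ]) & !is.na(counts[j, ])
      mean((counts[i, sh] - counts[j, sh])^2)
    })
    ord <- order(d, 1:5)
    nb <- ord[!is.na(counts[ord, k])][1:2]
    w <- 1 / (sqrt(d[nb]) + 1e-8)
    min(2, max(0, floor(sum(w * counts[nb, k]) / sum(w) + 0.5)))
  }
  expect_equal(imp$counts[4, 1], oracle_impute(4, 1))
  expect_equal(imp$counts[5, 3], oracle_impute(5, 3))
})

test_that("pruning removes later members of correlated groups only", {
  set.seed(9)
  base <- matrix(rbinom(40 * 3, 2, 0.5), 40, 3)
  counts <- cbind(base[, 1], base[, 1], base[, 2], base[, 1], base[, 3])
  g <- genotype_matrix(counts, marker_ids = paste0("m", 1:5))
  pruned <- prune_correlated(g)
  expect_equal(pruned$marker_ids, c("m1", "m3", "m5"))
  # retained set has no pair above the threshold
  cm <- abs(cor(pruned$counts))
  expect_true(all(cm[upper.tri(cm)] <= 0.95))

  # independent random markers survive untouched when below threshold
  gi <- toy_polymorphic(n = 50, m = 10, seed = 11)
  ci <- abs(cor(gi$counts))
  expect_lt(max(ci[upper.tri(ci)]), 0.95)  # fixture really is independent
  expect_equal(prune_correlated(gi)$marker_ids, gi$marker_ids)

  # zero-variance marker dropped with a warning
  gz <- genotype_matrix(cbind(base[, 1], 1), marker_ids = c("a", "b"))
  expect_warning(pz <- prune_correlated(gz), "zero-variance")
  expect_equal(pz$marker_ids, "a")
})

test_that("standardization centers, scales with denominator n, and is idempotent", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1), marker_ids = "m1")
  x <- standardize(g)
  expect_equal(unname(x$values[, 1]),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  gp <- toy_polymorphic(n = 25, m = 15)
  xp <- standardize(gp)
  expect_lt(max(abs(colMeans(xp$values))), 1e-10)
  expect_lt(max(abs(colMeans(xp$values^2) - 1)), 1e-8)
  # restandardizing already-standardized values changes nothing
  restd <- sweep(sweep(xp$values, 2, colMeans(xp$values)), 2,
                 sqrt(colMeans(xp$values^2) - colMeans(xp$values)^2), "/")
  expect_lt(max(abs(restd - xp$values)), 1e-10)
  mono <- genotype_matrix(cbind(c(0, 1, 2), 1))
  expect_error(standardize(mono), "monomorphic")
})

test_that("phenotypes join to genotypes by id, erroring on unmatched ids", {
  f <- write_csv_fixture(c("id,y", "s01,1.5", "s03,2.5", "s02,-0.5"))
  ph <- read_phenotypes(f)
  g <- toy_genotypes(n = 3)
  y <- align_phenotypes(g, ph)
  expect_equal(unname(y), c(1.5, -0.5, 2.5))  # reordered to genotype order
  g4 <- toy_genotypes(n = 4)
  expect_error(align_phenotypes(g4, ph), "no phenotype for sample")
  bad <- write_csv_fixture(c("id,y", "a,1", "b,NA"))
  expect_error(read_phenotypes(bad), "non-finite")
})
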