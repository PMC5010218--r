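#' Construct a training/target subset pair
#'
#' @param train_idx,target_idx disjoint sample index sets.
#' @param m number of swaps that produced this pair (0 for the clustering
#'   split).
#' @param seed RNG seed recorded for provenance.
#' @param fst optional `fst_estimate` (or its value) attached to the pair.
#' @return an object of class `subset_pair`.
#' @export
subset_pair <- function(train_idx, target_idx, m = 0L, seed = NA_integer_,
                        fst = NULL) {
  train_idx <- as.integer(train_idx)
  target_idx <- as.integer(target_idx)
  if (length(intersect(train_idx, target_idx)) > 0)
    stop("training and target sets overlap")
  if (anyDuplicated(train_idx) || anyDuplicated(target_idx))
    stop("duplicated indices within a side")
  if (inherits(fst, "fst_estimate")) fst <- fst$value
  structure(list(train_idx = train_idx, target_idx = target_idx,
                 m = as.integer(m), seed = seed, fst = fst),
            class = "subset_pair")
}

#' @export
print.subset_pair <- function(x, ...) {
  cat("subset_pair: n_TR = ", length(x$train_idx), ", n_TA = ",
      length(x$target_idx), ", m = ", x$m,
      if (!is.null(x$fst)) paste0(", F_ST = ", signif(x$fst, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Split a sample into minimally related training and target subsamples
#'
#' Runs k-means with k = 2 on the standardized allele counts (best of
#' `restarts` seeded initializations by total within-cluster sum of
#' squares). Because squared Euclidean distance on standardized counts is
#' an affine function of kinship, the two clusters are the maximally
#' diverged — minimally related — partition of the sample, i.e. the pair
#' with the largest between-subset F_ST attainable by clustering. The
#' larger cluster becomes the training subsample (it is also treated as
#' the ancestral population when F_ST is estimated); on a size tie, the
#' cluster containing the lowest sample index is training.
#'
#' @param x a `standardized_matrix` with at least 4 samples.
#' @param seed RNG seed.
#' @param restarts number of k-means initializations, default 25.
#' @return a [subset_pair()] with `m = 0`.
#' @export
split_minimally_related <- function(x, seed = 1L, restarts = 25L) {
  stopifnot(inherits(x, "standardized_matrix"))
  if (nrow(x$values) < 4) stop("need at least 4 samples to split")
  set.seed(seed)
  km <- tryCatch(kmeans(x$values, centers = 2, nstart = restarts,
                        iter.max = 100),
                 error = function(e)
                   stop("degenerate clustering: ", conditionMessage(e)))
  if (any(km$size == 0)) stop("degenerate clustering: empty cluster")
  train_cl <- if (km$size[1] != km$size[2]) {
    which.max(km$size)
  } else {
    km$cluster[1]  # tie: cluster of the lowest sample index
  }
  subset_pair(which(km$cluster == train_cl),
              which(km$cluster != train_cl), m = 0L, seed = seed)
}

#' Shrink the target subsample while keeping F_ST large
#'
#' Greedily moves one target individual at a time into the training
#' subsample — at each step the individual whose transfer yields the
#' largest resulting between-subsample F_ST — until the target has
#' `n_target_required` members. Used when the clustering split leaves too
#' few training individuals to fit a prediction model and the target can
#' afford to shrink. Deterministic given its inputs (ties broken by index
#' order).
#'
#' @param pair a [subset_pair()].
#' @param g the underlying [genotype_matrix()] (no missing entries).
#' @param n_target_required desired target size, at most the current one.
#' @return a new [subset_pair()] with the same `m`.
#' @export
rebalance <- function(pair, g, n_target_required) {
  stopifnot(inherits(pair, "subset_pair"), inherits(g, "genotype_matrix"))
  n_ta <- length(pair$target_idx)
  if (n_target_required > n_ta)
    stop("n_target_required exceeds the current target size")
  if (n_target_required < 10)
    warning("targets smaller than 10 make the predictive correlation ",
            "estimate highly variable")
  if (n_target_required == n_ta) return(pair)
  train <- pair$train_idx
  target <- pair$target_idx
  while (length(target) > n_target_required) {
    fst_if_moved <- vapply(seq_along(target), function(j) {
      fst_beta_binomial(g, c(train, target[j]), target[-j])$value
    }, numeric(1))
    best <- which.max(fst_if_moved)
    train <- c(train, target[best])
    target <- target[-best]
  }
  subset_pair(sort(train), target, m = pair$m, seed = pair$seed)
}

#' Swap individuals at random between the two sides of a pair
#'
#' Exchanges `m` uniformly chosen members of each side; sizes are
#' preserved. Repeated swapping from the clustering split produces pairs
#' of subsamples at progressively smaller genetic distance.
#'
#' @param pair a [subset_pair()].
#' @param m number of individuals exchanged, `0 <= m <= min(n_TR, n_TA)`.
#' @param seed RNG seed.
#' @return a new [subset_pair()] recording `m` and `seed`.
#' @export
swap <- function(pair, m, seed = 1L) {
  stopifnot(inherits(pair, "subset_pair"))
  if (m > min(length(pair$train_idx), length(pair$target_idx)))
    stop("m exceeds the size of a subsample")
  if (m == 0)
    return(subset_pair(pair$train_idx, pair$target_idx, m = 0L, seed = seed))
  set.seed(seed)
  out_tr <- sample(length(pair$train_idx), m)
  out_ta <- sample(length(pair$target_idx), m)
  new_train <- c(pair$train_idx[-out_tr], pair$target_idx[out_ta])
  new_target <- c(pair$target_idx[-out_ta], pair$train_idx[out_tr])
  subset_pair(new_train, new_target, m = m, seed = seed)
}

# smallest step in [2, 20] giving at most `max_points` schedule entries
auto_step <- function(m_max, max_points = 30L) {
  for (s in 2:20) if (floor(m_max / s) + 1 <= max_points) return(s)
  20L
}

#' Generate the swap-resampling series of subsample pairs
#'
#' Starting from the clustering split (`m = 0`), increases the swap count
#' `m` in steps and, for each `m > 0`, draws `reps_per_m` independent
#' swapped pairs, estimating the Beta-Binomial F_ST of each. Generation
#' stops after the first `m` whose mean F_ST falls to at most `fst_stop`
#' (the subsamples are then effectively unstructured); if that never
#' happens the series stops at `m = min(n_TR, n_TA)` with a warning.
#'
#' @param x a `standardized_matrix` of the full sample (unused beyond size
#'   checks; kept so callers hold the shared coordinate system alongside).
#' @param g the underlying [genotype_matrix()] (no missing entries).
#' @param pair0 the [subset_pair()] from [split_minimally_related()] /
#'   [rebalance()].
#' @param step swap-count increment in `[2, 20]`; `NULL` (default) picks
#'   the smallest step that keeps the schedule at <= 30 points.
#' @param reps_per_m pairs drawn per swap count, default 40.
#' Swap counts are capped at the maximal-mixing point
#' `m* = n_TR * n_TA / (n_TR + n_TA)` (always included as the final
#' schedule entry): beyond `m*` further swapping re-segregates the pair —
#' at `m = n_TA` a full exchange simply restores the original split — so
#' F_ST would rise again.
#'
#' @param fst_stop stopping threshold on the mean F_ST, default 0.005.
#' @param seed RNG seed governing all swaps.
#' @return an object of class `swap_series` with fields `pairs` (list of
#'   [subset_pair()], each with its F_ST attached), `schedule`,
#'   `reps_per_m` and `mean_fst` (per schedule entry).
#' @export
generate_swap_series <- function(x, g, pair0, step = NULL, reps_per_m = 40L,
                                 fst_stop = 0.005, seed = 1L) {
  stopifnot(inherits(pair0, "subset_pair"), inherits(g, "genotype_matrix"))
  n_tr <- length(pair0$train_idx)
  n_ta <- length(pair0$target_idx)
  m_max <- max(1L, round(n_tr * n_ta / (n_tr + n_ta)))  # maximal mixing
  if (is.null(step)) step <- auto_step(m_max)
  if (!(step >= 2 && step <= 20)) stop("step must be in [2, 20]")
  set.seed(seed)
  fst0 <- fst_beta_binomial(g, pair0$train_idx, pair0$target_idx)
  p0 <- subset_pair(pair0$train_idx, pair0$target_idx, m = 0L,
                    seed = pair0$seed, fst = fst0)
  pairs <- list(p0)
  schedule <- 0L
  mean_fst <- fst0$value
  if (fst0$value <= fst_stop) {
    return(structure(list(pairs = pairs, schedule = schedule,
                          reps_per_m = as.integer(reps_per_m),
                          mean_fst = mean_fst),
                     class = "swap_series"))
  }
  stopped <- FALSE
  ms <- if (m_max >= step) unique(c(seq(step, m_max, by = step), m_max))
        else m_max
  for (m in ms) {
    fsts <- numeric(reps_per_m)
    for (r in seq_len(reps_per_m)) {
      s <- sample.int(.Machine$integer.max - 1L, 1)
      sp <- swap(pair0, m, seed = s)
      est <- fst_beta_binomial(g, sp$train_idx, sp$target_idx)
      sp$fst <- est$value
      fsts[r] <- est$value
      pairs[[length(pairs) + 1L]] <- sp
    }
    schedule <- c(schedule, m)
    mean_fst <- c(mean_fst, mean(fsts))
    if (mean(fsts) <= fst_stop) { stopped <- TRUE; break }
  }
  if (!stopped)
    warning("mean F_ST never fell to ", fst_stop,
            "; series stopped at m = ", max(schedule))
  structure(list(pairs = pairs, schedule = schedule,
                 reps_per_m = as.integer(reps_per_m), mean_fst = mean_fst),
            class = "swap_series")
}

#' @export
print.swap_series <- function(x, ...) {
  cat("swap_series: ", length(x$pairs), " pairs, m in {",
      paste(x$schedule, collapse = ", "), "}, final mean F_ST ",
      signif(x$mean_fst[length(x$mean_fst)], 3), "\n", sep = "")
  invisible(x)
}

#' Serialize a subset pair as CSV plus JSON sidecar
#'
#' @param pair a [subset_pair()].
#' @param g the [genotype_matrix()] providing sample ids.
#' @param path CSV path; a `.json` sidecar with `m`, `seed` and F_ST is
#'   written next to it.
#' @export
write_subset_pair <- function(pair, g, path) {
  stopifnot(inherits(pair, "subset_pair"), inherits(g, "genotype_matrix"))
  df <- data.frame(
    id = g$sample_ids[c(pair$train_idx, pair$target_idx)],
    role = rep(c("train", "target"),
               c(length(pair$train_idx), length(pair$target_idx))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(m = pair$m, seed = pair$seed, fst = pair$fst)
  jsonlite::write_json(side, sub("\\.csv$", "", path) |> paste0(".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
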