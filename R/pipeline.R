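#' Fit and evaluate a prediction model on every pair of a swap series
#'
#' For each pair, fits the elastic net on the training subsample's rows of
#' the shared standardized matrix, predicts the target subsample, and
#' records `(m, F_ST, rho)` — the raw material of the decay curve.
#'
#' @param series a `swap_series` from [generate_swap_series()].
#' @param x the full-sample `standardized_matrix`.
#' @param y numeric phenotype vector aligned with the sample.
#' @param seed RNG seed (per-pair tuning seeds are derived from it).
#' @param ... further arguments to [fit_elastic_net()].
#' @return a `decay_points` data frame.
#' @export
evaluate_pairs <- function(series, x, y, seed = 1L, ...) {
  stopifnot(inherits(series, "swap_series"),
            inherits(x, "standardized_matrix"))
  set.seed(seed)
  fit_seeds <- sample.int(1e8, length(series$pairs))
  rows <- vector("list", length(series$pairs))
  for (i in seq_along(series$pairs)) {
    p <- series$pairs[[i]]
    model <- fit_elastic_net(as_value_matrix(x, p$train_idx),
                             y[p$train_idx], seed = fit_seeds[i], ...)
    y_hat <- predict_phenotypes(model, as_value_matrix(x, p$target_idx))
    rows[[i]] <- data.frame(m = p$m, fst = p$fst,
                            rho = predictive_correlation(y_hat,
                                                         y[p$target_idx]))
  }
  out <- do.call(rbind, rows)
  decay_points(out$m, out$fst, out$rho)
}

# fill configuration defaults; `config` may be a list or a YAML path
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    format = "csv", maf_min = 0.01, missing_max = 0.20,
    impute_k = 10, r_max = 0.95, n_target = NULL,
    step = NULL, reps_per_m = 40, fst_stop = 0.005,
    span = 0.75, cv_runs = 5, folds = 10,
    alphas = seq(0.1, 1, by = 0.1), seed = 1,
    restarts = 25, out_dir = NULL,
    # simulation defaults
    n_markers = 1000, n_founders = 200, founder_fst = 0.05,
    n_causal = 200, h2 = 0.55, rounds = 10, n_progeny = 200,
    n_selected = 20, replicates = 100, n_chrom = 21,
    pop_sizes = c(100, 80, 60), pop_fst = c(1e-6, 0.05, 0.10))
  utils::modifyList(defaults, config)
}

log_stage <- function(...) message("[gpdecay] ", ...)

# run a stage, prefixing any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full decay-curve workflow
#'
#' QC, imputation and pruning; standardization of the full sample;
#' minimally related split by k-means (optionally rebalanced to a
#' required target size); swap-resampling series; per-pair elastic-net
#' fit and prediction; LOESS decay curve, linear approximation and the
#' squared-scale comparison. Every random operation is driven by seeds
#' derived from `config$seed` and the run is reproducible bit-for-bit
#' given the same configuration.
#'
#' @param config a list (or YAML path) with entries `genotypes` (path or
#'   [genotype_matrix()]), `phenotypes` (path, data frame or named
#'   vector), and any of the tuning fields understood by the pipeline
#'   stages (`maf_min`, `missing_max`, `impute_k`, `r_max`, `n_target`,
#'   `step`, `reps_per_m`, `fst_stop`, `span`, `cv_runs`, `folds`,
#'   `alphas`, `restarts`, `seed`, `out_dir`).
#' @return a list with `genotypes`, `standardized`, `pair0`, `series`,
#'   `points`, `curve`, `linear`, `scale_comparison`; written as CSVs
#'   (plus a curve plot) under `config$out_dir` when set.
#' @export
run_decay <- function(config) {
  cfg <- resolve_config(config)
  g <- stage("read", {
    if (inherits(cfg$genotypes, "genotype_matrix")) cfg$genotypes
    else read_genotypes(cfg$genotypes, cfg$format)
  })
  y <- stage("phenotypes", {
    ph <- cfg$phenotypes
    if (is.character(ph)) ph <- read_phenotypes(ph)
    align_phenotypes(g, ph)
  })
  log_stage("input: ", nrow(g$counts), " samples x ", ncol(g$counts),
            " markers")
  g <- stage("qc", apply_qc(g, cfg$maf_min, cfg$missing_max))
  g <- stage("impute", impute_missing(g, cfg$impute_k))
  g <- stage("prune", prune_correlated(g, cfg$r_max))
  log_stage("after QC/impute/prune: ", ncol(g$counts), " markers")
  x <- stage("standardize", standardize(g))
  pair0 <- stage("split",
                 split_minimally_related(x, seed = cfg$seed,
                                         restarts = cfg$restarts))
  if (!is.null(cfg$n_target))
    pair0 <- stage("rebalance", rebalance(pair0, g, cfg$n_target))
  log_stage("split: n_TR = ", length(pair0$train_idx), ", n_TA = ",
            length(pair0$target_idx), " (seed ", cfg$seed, ")")
  series <- stage("swap_series",
                  generate_swap_series(x, g, pair0, step = cfg$step,
                                       reps_per_m = cfg$reps_per_m,
                                       fst_stop = cfg$fst_stop,
                                       seed = cfg$seed + 1))
  log_stage("swap series: ", length(series$pairs), " pairs, m up to ",
            max(series$schedule))
  points <- stage("evaluate",
                  evaluate_pairs(series, x, y, seed = cfg$seed + 2,
                                 cv_runs = cfg$cv_runs, folds = cfg$folds,
                                 alphas = cfg$alphas))
  curve <- stage("curve", fit_decay_curve(points, span = cfg$span))
  linear <- stage("linear", fit_linear(points))
  cmp <- stage("scale_comparison", squared_scale_regression(points))
  res <- list(genotypes = g, standardized = x, pair0 = pair0,
              series = series, points = points, curve = curve,
              linear = linear, scale_comparison = cmp, config = cfg)
  if (!is.null(cfg$out_dir)) write_decay_artifacts(res, cfg$out_dir)
  res
}

write_decay_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$points, file.path(out_dir, "points.csv"),
            row.names = FALSE)
  write_decay_curve(res$curve, file.path(out_dir, "curve.csv"))
  write_subset_pair(res$pair0, res$genotypes,
                    file.path(out_dir, "split.csv"))
  grDevices::png(file.path(out_dir, "curve.png"), width = 800,
                 height = 600)
  plot(res$curve, linear = res$linear)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Run a simulation experiment with a decay-curve overlay
#'
#' `which = "breeding"`: builds a structured synthetic founder panel,
#' defines an additive trait, fits the prediction model on the founders,
#' runs the forward selection program, estimates the decay curve from the
#' founders, and overlays the per-generation mean `(F_ST, rho)` reference
#' points on it. `which = "cross_population"`: builds several populations
#' at increasing divergence, fits on the first, and compares the decay
#' curve of the training population with the per-population `(F_ST,
#' rho_P)` points.
#'
#' @param config a list (or YAML path); see [run_decay()] plus the
#'   simulation fields (`n_founders`, `n_markers`, `founder_fst`,
#'   `n_causal`, `h2`, `rounds`, `n_progeny`, `n_selected`, `replicates`,
#'   `pop_sizes`, `pop_fst`).
#' @param which `"breeding"` or `"cross_population"`.
#' @return a list with the simulation outputs, the decay-curve results
#'   and the reference points; artifacts written under `config$out_dir`
#'   when set.
#' @export
run_simulation <- function(config, which = c("breeding",
                                             "cross_population")) {
  which <- match.arg(which)
  cfg <- resolve_config(config)
  set.seed(cfg$seed)
  if (which == "breeding") {
    founders <- stage("founders", {
      half <- cfg$n_founders %/% 2
      simulate_structured_population(
        population_spec(c(half, cfg$n_founders - half),
                        c(1e-6, cfg$founder_fst), cfg$n_markers),
        seed = cfg$seed)
    })
    trait <- stage("trait",
                   assign_trait(founders, cfg$n_causal, h2 = cfg$h2,
                                seed = cfg$seed + 1))
    y <- simulate_phenotypes(founders, trait, seed = cfg$seed + 2)
    x <- standardize(founders)
    model <- stage("model",
                   fit_elastic_net(x, as.numeric(y), seed = cfg$seed + 3,
                                   cv_runs = cfg$cv_runs,
                                   folds = cfg$folds,
                                   alphas = cfg$alphas))
    map <- make_genetic_map(cfg$n_markers, n_chrom = cfg$n_chrom)
    traj <- stage("selection",
                  run_selection_program(founders, trait, model, map,
                                        rounds = cfg$rounds,
                                        n_progeny = cfg$n_progeny,
                                        n_selected = cfg$n_selected,
                                        replicates = cfg$replicates,
                                        seed = cfg$seed + 4))
    dec <- run_decay(utils::modifyList(
      cfg, list(genotypes = founders, phenotypes = setNames(
        as.numeric(y), founders$sample_ids), out_dir = NULL)))
    reference <- data.frame(fst = traj$summary$mean_fst,
                            rho = traj$summary$mean_rho)
    res <- list(trajectory = traj, decay = dec, reference = reference,
                trait = trait, model = model, config = cfg)
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(traj$summary,
                file.path(cfg$out_dir, "trajectory.csv"),
                row.names = FALSE)
      write.csv(dec$points, file.path(cfg$out_dir, "points.csv"),
                row.names = FALSE)
      grDevices::png(file.path(cfg$out_dir, "overlay.png"),
                     width = 800, height = 600)
      plot(dec$curve, linear = dec$linear, reference = reference)
      grDevices::dev.off()
    }
    res
  } else {
    g <- stage("populations", simulate_structured_population(
      population_spec(cfg$pop_sizes, cfg$pop_fst, cfg$n_markers),
      seed = cfg$seed))
    trait <- stage("trait",
                   assign_trait(g, cfg$n_causal, h2 = cfg$h2,
                                seed = cfg$seed + 1))
    targets <- stage("cross_population",
                     cross_population_experiment(
                       g, "P1", trait, seed = cfg$seed + 2,
                       cv_runs = cfg$cv_runs, folds = cfg$folds,
                       alphas = cfg$alphas))
    y <- simulate_phenotypes(g, trait, seed = cfg$seed + 3)
    tr <- base::which(g$pop_labels == "P1")  # `which` names the experiment
    g_tr <- subset_genotypes(g, samples = tr)
    dec <- run_decay(utils::modifyList(
      cfg, list(genotypes = g_tr,
                phenotypes = setNames(as.numeric(y[tr]),
                                      g_tr$sample_ids),
                out_dir = NULL)))
    res <- list(targets = targets, decay = dec, trait = trait,
                config = cfg)
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(targets, file.path(cfg$out_dir, "targets.csv"),
                row.names = FALSE)
      grDevices::png(file.path(cfg$out_dir, "overlay.png"),
                     width = 800, height = 600)
      plot(dec$curve, linear = dec$linear,
           reference = targets[, c("fst", "rho")])
      grDevices::dev.off()
    }
    res
  }
}
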