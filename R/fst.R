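#' Per-marker allele frequencies of a subsample
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param idx non-empty sample index set.
#' @return numeric vector of frequencies, `colSums(counts) / (2 * |idx|)`.
#' @export
allele_frequencies <- function(g, idx) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(idx) == 0) stop("idx must be non-empty")
  sub <- g$counts[idx, , drop = FALSE]
  if (anyNA(sub)) stop("missing entries present: impute first")
  colSums(sub) / (2 * length(idx))
}

# core Beta-Binomial log-likelihood; no validation, vectorised over markers
.bb_loglik <- function(f, anc_freq, target_counts, n_chrom) {
  a <- anc_freq * (1 - f) / f
  b <- (1 - anc_freq) * (1 - f) / f
  sum(lbeta(target_counts + a, n_chrom - target_counts + b) - lbeta(a, b))
}

#' Beta-Binomial log-likelihood of target allele counts
#'
#' Under the Balding-Nichols model, the allele frequency of a population
#' that has diverged by \eqn{F_{ST} = f} from an ancestral population with
#' frequency \eqn{\pi} is Beta-distributed with shape parameters
#' \eqn{\alpha = \pi (1-f)/f} and \eqn{\beta = (1-\pi)(1-f)/f}. The allele
#' count \eqn{c} observed on \eqn{n} chromosomes in the diverged population
#' is then Beta-Binomial, and (up to the combinatorial constant, which does
#' not depend on \eqn{f} and is omitted) its log-likelihood summed over
#' independent markers is
#' \deqn{\sum_k \ln B(c_k + \alpha_k, n_k - c_k + \beta_k) -
#'       \ln B(\alpha_k, \beta_k).}
#'
#' @param f divergence parameter, strictly in (0, 1).
#' @param anc_freq ancestral frequencies, strictly in (0, 1) per marker.
#' @param target_counts observed allele counts per marker, `0 <= c <= n`.
#' @param n_chrom chromosomes observed per marker (scalar or vector).
#' @return the scalar log-likelihood.
#' @export
beta_binomial_loglik <- function(f, anc_freq, target_counts, n_chrom) {
  if (!(length(f) == 1 && f > 0 && f < 1))
    stop("f must be a single value strictly in (0, 1)")
  if (any(anc_freq <= 0 | anc_freq >= 1))
    stop("ancestral frequencies must be strictly in (0, 1); ",
         "filter monomorphic markers first")
  n_chrom <- rep_len(n_chrom, length(anc_freq))
  if (any(target_counts < 0 | target_counts > n_chrom))
    stop("target counts must satisfy 0 <= c <= n_chrom")
  .bb_loglik(f, anc_freq, target_counts, n_chrom)
}

# shared MLE core: maximize over f given ancestral freqs and target counts
.fst_mle <- function(anc_freq, target_counts, n_chrom,
                     bounds = c(1e-6, 0.99), tol = 1e-6) {
  usable <- anc_freq > 0 & anc_freq < 1
  if (sum(usable) < 10)
    stop("fewer than 10 markers polymorphic in the training subsample; ",
         "the F_ST estimate would be unstable")
  n_chrom <- rep_len(n_chrom, length(anc_freq))
  opt <- optimize(.bb_loglik, interval = bounds, maximum = TRUE, tol = tol,
                  anc_freq = anc_freq[usable],
                  target_counts = target_counts[usable],
                  n_chrom = n_chrom[usable])
  structure(list(value = opt$maximum, loglik = opt$objective,
                 n_markers_used = sum(usable),
                 converged = is.finite(opt$objective)),
            class = "fst_estimate")
}

#' Maximum-likelihood F_ST between a training and a target subsample
#'
#' Treats the training subsample as the ancestral population: its observed
#' allele frequencies are plugged in as \eqn{\pi}, and the target
#' subsample's allele counts (over `2 * n_target` chromosomes per marker)
#' enter a Beta-Binomial likelihood which is maximized over
#' \eqn{F_{ST} \in} `bounds` by Brent's method. Markers monomorphic in the
#' training subsample are excluded (their Beta parameters would be zero).
#' The estimator's precision depends primarily on the number of markers
#' rather than on the subsample sizes.
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param train_idx,target_idx disjoint non-empty sample index sets.
#' @param bounds optimization interval, default `c(1e-6, 0.99)`.
#' @return an object of class `fst_estimate` with fields `value`, `loglik`,
#'   `n_markers_used` and `converged`.
#' @export
fst_beta_binomial <- function(g, train_idx, target_idx,
                              bounds = c(1e-6, 0.99)) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(train_idx) == 0 || length(target_idx) == 0)
    stop("index sets must be non-empty")
  if (length(intersect(train_idx, target_idx)) > 0)
    stop("training and target index sets overlap")
  anc <- allele_frequencies(g, train_idx)
  tc <- colSums(g$counts[target_idx, , drop = FALSE])
  if (anyNA(tc)) stop("missing entries present: impute first")
  .fst_mle(anc, tc, 2 * length(target_idx), bounds = bounds)
}

# F_ST between two genotype matrices over the same markers, first treated
# as ancestral (used by the breeding simulation: founders -> progeny)
fst_between_matrices <- function(g_anc, g_target, bounds = c(1e-6, 0.99)) {
  if (!identical(g_anc$marker_ids, g_target$marker_ids))
    stop("marker sets differ")
  anc <- colSums(g_anc$counts) / (2 * nrow(g_anc$counts))
  tc <- colSums(g_target$counts)
  .fst_mle(anc, tc, 2 * nrow(g_target$counts), bounds = bounds)
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat("F_ST estimate: ", signif(x$value, 4), " (log-likelihood ",
      signif(x$loglik, 6), ", ", x$n_markers_used, " markers)\n", sep = "")
  invisible(x)
}
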