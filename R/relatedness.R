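#' Allelic-correlation kinship matrix
#'
#' The genomic relationship between individuals i and j is the average
#' allelic correlation over markers,
#' \deqn{k_{ij} = \frac{1}{m} \sum_{k=1}^{m} \tilde X_{ik} \tilde X_{jk},}
#' where \eqn{\tilde X} are the standardized allele counts. Because every
#' standardized column has unit (denominator-n) variance, the diagonal of
#' the matrix averages to 1 and its trace equals the sample size.
#'
#' @param x a `standardized_matrix` from [standardize()], with at least
#'   two samples and one marker.
#' @return an object of class `kinship_matrix` with fields `values`
#'   (n x n symmetric) and `sample_ids`.
#' @export
kinship_matrix <- function(x) {
  stopifnot(inherits(x, "standardized_matrix"))
  if (nrow(x$values) < 2) stop("need at least two samples")
  if (ncol(x$values) < 1) stop("need at least one marker")
  k <- tcrossprod(x$values) / ncol(x$values)
  k <- (k + t(k)) / 2
  dimnames(k) <- list(x$sample_ids, x$sample_ids)
  structure(list(values = k, sample_ids = x$sample_ids),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix: ", length(x$sample_ids), " samples, mean diagonal ",
      signif(mean(diag(x$values)), 4), "\n", sep = "")
  invisible(x)
}

#' Write a kinship matrix as square CSV
#'
#' @param k a `kinship_matrix`.
#' @param path output path; ids form the header row and first column.
#' @export
write_kinship <- function(k, path) {
  stopifnot(inherits(k, "kinship_matrix"))
  df <- data.frame(id = k$sample_ids, k$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean cross-group kinship
#'
#' Average kinship coefficient over all pairs (i in A, j in B) of two
#' disjoint groups. Within the Balding-Nichols world this quantity is
#' inversely related to the F_ST between the two groups: the less related
#' two sets of individuals are, the further their allele frequencies have
#' diverged.
#'
#' @param k a `kinship_matrix`.
#' @param idx_a,idx_b non-empty, disjoint sample index sets.
#' @return the scalar mean kinship \eqn{\bar k}.
#' @export
mean_cross_kinship <- function(k, idx_a, idx_b) {
  stopifnot(inherits(k, "kinship_matrix"))
  if (length(idx_a) == 0 || length(idx_b) == 0)
    stop("index sets must be non-empty")
  if (length(intersect(idx_a, idx_b)) > 0)
    stop("index sets overlap")
  mean(k$values[idx_a, idx_b, drop = FALSE])
}

#' Squared Euclidean distance between standardized marker profiles
#'
#' Returns \eqn{\sum_k (\tilde X_{ik} - \tilde X_{jk})^2}. On standardized
#' counts this distance carries the same information as kinship through the
#' identity \eqn{d^2_{ij} = m\,(k_{ii} + k_{jj} - 2 k_{ij})}, which is why
#' Euclidean clustering (k-means) of standardized genotypes partitions a
#' sample into minimally related subsets.
#'
#' @param x a `standardized_matrix`.
#' @param i,j sample indices.
#' @return the squared distance (a non-negative scalar).
#' @export
squared_distance <- function(x, i, j) {
  stopifnot(inherits(x, "standardized_matrix"))
  n <- nrow(x$values)
  if (!(i >= 1 && i <= n && j >= 1 && j <= n))
    stop("sample index out of range")
  sum((x$values[i, ] - x$values[j, ])^2)
}
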