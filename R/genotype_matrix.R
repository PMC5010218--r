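#' Construct a genotype matrix
#'
#' The central container of the package: an individuals x markers matrix of
#' biallelic allele counts coded 0, 1, 2 (1 = heterozygote), with `NA` for
#' missing calls. Optional per-marker chromosome labels and genetic-map
#' positions, and an optional per-sample population/family label.
#'
#' @param counts numeric matrix, n samples x m markers, entries in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the row names of `counts`.
#' @param marker_ids character vector of unique marker identifiers; defaults
#'   to the column names of `counts`.
#' @param chrom optional per-marker chromosome label.
#' @param pos optional per-marker position in genetic-map units.
#' @param pop_labels optional per-sample group label (population, family,
#'   country of origin, ...).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, sample_ids = rownames(counts),
                            marker_ids = colnames(counts),
                            chrom = NULL, pos = NULL, pop_labels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(counts))
    stop("length(sample_ids) must equal nrow(counts)")
  if (length(marker_ids) != ncol(counts))
    stop("length(marker_ids) must equal ncol(counts)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicated marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid allele count ", counts[bad][1], " for sample '",
         sample_ids[w[1]], "', marker '", marker_ids[w[2]],
         "': counts must be 0, 1, 2 or missing")
  }
  if (!is.null(chrom) && length(chrom) != ncol(counts))
    stop("chrom must have one entry per marker")
  if (!is.null(pos) && length(pos) != ncol(counts))
    stop("pos must have one entry per marker")
  if (!is.null(pop_labels) && length(pop_labels) != nrow(counts))
    stop("pop_labels must have one entry per sample")
  dimnames(counts) <- list(sample_ids, marker_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 marker_ids = marker_ids, chrom = chrom, pos = pos,
                 pop_labels = pop_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$counts))
  cat("genotype_matrix: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " markers", if (n_miss > 0) paste0(" (", n_miss, " missing calls)"),
      "\n", sep = "")
  if (!is.null(x$pop_labels))
    cat("  populations:", paste(names(table(x$pop_labels)), table(x$pop_labels),
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param samples,markers index vectors (positions); `NULL` keeps all.
#'   Marker metadata and population labels stay aligned.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- samples %||% seq_along(g$sample_ids)
  mi <- markers %||% seq_along(g$marker_ids)
  genotype_matrix(g$counts[si, mi, drop = FALSE],
                  sample_ids = g$sample_ids[si],
                  marker_ids = g$marker_ids[mi],
                  chrom = g$chrom[mi], pos = g$pos[mi],
                  pop_labels = g$pop_labels[si])
}

#' Standardize allele counts
#'
#' Centers each marker by its sample mean and scales by its sample standard
#' deviation computed with denominator n (population form), so that each
#' column of the result has mean 0 and variance 1 over the sample used.
#' The centering/scaling constants are stored so that new samples (progeny,
#' external target populations) can be projected into the same coordinate
#' system with [standardize_with()]. Standardization is always computed on
#' the full sample before any training/target split, so both sides of a
#' split share one coordinate system.
#'
#' @param g a [genotype_matrix()] with no missing entries, all markers
#'   polymorphic.
#' @return an object of class `standardized_matrix` with fields `values`,
#'   `center`, `scale`, `sample_ids`, `marker_ids`.
#' @export
standardize <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$counts))
    stop("missing entries present: run impute_missing() first")
  n <- nrow(g$counts)
  ctr <- colMeans(g$counts)
  scl <- sqrt(colMeans(g$counts^2) - ctr^2)  # denominator-n sd
  if (any(scl <= 0))
    stop("monomorphic marker(s) present (e.g. '",
         g$marker_ids[which(scl <= 0)[1]],
         "'): apply_qc() must be run before standardize()")
  vals <- sweep(sweep(g$counts, 2, ctr, "-"), 2, scl, "/")
  structure(list(values = vals, center = ctr, scale = scl,
                 sample_ids = g$sample_ids, marker_ids = g$marker_ids),
            class = "standardized_matrix")
}

#' Project new samples onto an existing standardization
#'
#' @param g a [genotype_matrix()] with no missing entries whose markers match
#'   those of `ref`.
#' @param ref a `standardized_matrix` (or any object with `center`, `scale`
#'   and `marker_ids`) whose constants are reused.
#' @return a `standardized_matrix` for the new samples (its `values` are not
#'   re-centered on the new sample).
#' @export
standardize_with <- function(g, ref) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!identical(g$marker_ids, ref$marker_ids))
    stop("marker sets of the new sample and the reference differ")
  if (anyNA(g$counts)) stop("missing entries present")
  vals <- sweep(sweep(g$counts, 2, ref$center, "-"), 2, ref$scale, "/")
  structure(list(values = vals, center = ref$center, scale = ref$scale,
                 sample_ids = g$sample_ids, marker_ids = g$marker_ids),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("standardized_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " markers\n", sep = "")
  invisible(x)
}

#' @export
dim.standardized_matrix <- function(x) dim(x$values)

# rows of a standardized matrix (or plain matrix) as a numeric matrix
as_value_matrix <- function(x, rows = NULL) {
  m <- if (inherits(x, "standardized_matrix")) x$values else as.matrix(x)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}
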