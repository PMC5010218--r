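#' Read a genotype matrix from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`csv`}{comma-separated; first column the sample id, remaining
#'     columns one marker each; empty cells are missing.}
#'   \item{`plink_raw`}{whitespace-separated PLINK `.raw` export: header
#'     `FID IID PAT MAT SEX PHENOTYPE` followed by one column per marker;
#'     `NA` is missing. The `IID` column is used as the sample id.}
#' }
#'
#' @param path path to the file.
#' @param format `"csv"` or `"plink_raw"`.
#' @return a [genotype_matrix()]; sample order is file order and missing
#'   entries are preserved as `NA`.
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- tryCatch(
      read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE,
                 na.strings = c("NA", "")),
      error = function(e) stop("parse error in '", path, "': ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("parse error in '", path,
                           "': need an id column plus >= 1 marker column")
    ids <- df[[1]]
    raw <- df[, -1, drop = FALSE]
  } else {
    df <- tryCatch(
      read.table(path, header = TRUE, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE,
                 na.strings = "NA"),
      error = function(e) stop("parse error in '", path, "': ",
                               conditionMessage(e)))
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 7 || !identical(names(df)[1:6], need))
      stop("parse error in '", path,
           "': plink_raw header must start with ", paste(need, collapse = " "))
    ids <- df[["IID"]]
    raw <- df[, -(1:6), drop = FALSE]
  }
  counts <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  bad_parse <- is.na(counts) & !is.na(as.matrix(raw))
  if (any(bad_parse)) {
    w <- which(bad_parse, arr.ind = TRUE)[1, ]
    stop("parse error in '", path, "', line ", w[1] + 1L,
         ": non-numeric genotype '", as.matrix(raw)[bad_parse][1], "'")
  }
  bad_code <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad_code)) {
    w <- which(bad_code, arr.ind = TRUE)[1, ]
    stop("validation error in '", path, "', line ", w[1] + 1L,
         ": allele count ", counts[bad_code][1], " is not in {0, 1, 2}")
  }
  genotype_matrix(counts, sample_ids = ids, marker_ids = colnames(raw))
}

#' Write a genotype matrix in the CSV dialect
#'
#' Inverse of `read_genotypes(format = "csv")`; round-trips exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(id = g$sample_ids, check.names = FALSE)
  df[g$marker_ids] <- as.data.frame(g$counts, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a two-column phenotype file
#'
#' @param path delimited file with columns (id, value); comma, tab or
#'   whitespace separated, with or without a header line.
#' @return a data frame with columns `sample_id` (character) and `y`
#'   (numeric, finite).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  fields <- strsplit(first, if (sep == ",") "," else "[ \t]+")[[1]]
  header <- suppressWarnings(is.na(as.numeric(fields[2])))
  df <- read.table(path, sep = sep, header = header,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("phenotype file must have exactly two columns")
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(y) || any(!is.finite(y)))
    stop("non-finite phenotype value at line ",
         which(!is.finite(y))[1] + header)
  data.frame(sample_id = as.character(df[[1]]), y = y,
             stringsAsFactors = FALSE)
}

#' Align a phenotype table to a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param pheno data frame as returned by [read_phenotypes()], or a named
#'   numeric vector.
#' @return numeric vector of phenotypes in `g`'s sample order.
#' @export
align_phenotypes <- function(g, pheno) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.numeric(pheno) && !is.null(names(pheno)))
    pheno <- data.frame(sample_id = names(pheno), y = unname(pheno))
  idx <- match(g$sample_ids, pheno$sample_id)
  if (anyNA(idx))
    stop("no phenotype for sample(s): ",
         paste(head(g$sample_ids[is.na(idx)], 5), collapse = ", "))
  setNames(pheno$y[idx], g$sample_ids)
}

#' Marker quality control
#'
#' Retains exactly the markers with minor allele frequency (computed on
#' non-missing entries) at least `maf_min` and missing fraction at most
#' `missing_max`. The sample set is unchanged. These are the standard
#' pre-processing thresholds for genomic prediction panels (MAF < 1% and
#' > 20% missingness removed).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, in (0, 0.5].
#' @param missing_max maximum missing fraction per marker, in (0, 1).
#' @return a [genotype_matrix()] with the failing markers removed.
#' @export
apply_qc <- function(g, maf_min = 0.01, missing_max = 0.20) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!(maf_min > 0 && maf_min <= 0.5))
    stop("maf_min must be in (0, 0.5]")
  if (!(missing_max > 0 && missing_max < 1))
    stop("missing_max must be in (0, 1)")
  p <- colMeans(g$counts, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(g$counts))
  keep <- which(!is.na(maf) & maf >= maf_min & miss <= missing_max)
  if (length(keep) == 0) stop("all markers removed by QC")
  subset_genotypes(g, markers = keep)
}

#' k-nearest-neighbour imputation of missing genotypes
#'
#' Each missing call is replaced by the weighted mean (weights inverse to
#' distance) of the `k_neighbours` nearest samples that are genotyped at
#' that marker, with distances computed as root mean squared difference
#' over the markers non-missing in both samples, then rounded to the
#' nearest legal count in \{0, 1, 2\}. Ties in distance are broken by
#' sample order, making the procedure deterministic; the `seed` argument
#' is accepted for interface stability but not used.
#'
#' @param g a [genotype_matrix()]; every marker must have at least one
#'   non-missing entry.
#' @param k_neighbours number of neighbours, default 10.
#' @param seed unused; imputation is deterministic.
#' @return a [genotype_matrix()] with no missing entries; non-missing
#'   entries are unchanged.
#' @export
impute_missing <- function(g, k_neighbours = 10, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), k_neighbours >= 1)
  x <- g$counts
  if (!anyNA(x)) return(g)
  if (any(colSums(!is.na(x)) == 0))
    stop("marker '", g$marker_ids[which(colSums(!is.na(x)) == 0)[1]],
         "' has no non-missing entries")
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("sample '", g$sample_ids[which(all_missing)[1]],
         "' is missing at every marker")
  n <- nrow(x)
  need <- which(rowSums(is.na(x)) > 0)
  for (i in need) {
    # mean squared difference over markers observed in both samples
    d2 <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(shared)) return(Inf)
      mean((x[i, shared] - x[j, shared])^2)
    }, numeric(1))
    ord <- order(d2, seq_len(n))  # sample order breaks ties
    for (k in which(is.na(x[i, ]))) {
      cand <- ord[!is.na(x[ord, k]) & is.finite(d2[ord])]
      if (length(cand) == 0)
        stop("cannot impute sample '", g$sample_ids[i], "', marker '",
             g$marker_ids[k], "': no usable neighbour")
      nb <- cand[seq_len(min(k_neighbours, length(cand)))]
      w <- 1 / (sqrt(d2[nb]) + 1e-8)
      val <- sum(w * x[nb, k]) / sum(w)
      x[i, k] <- min(2, max(0, floor(val + 0.5)))
    }
  }
  genotype_matrix(x, sample_ids = g$sample_ids, marker_ids = g$marker_ids,
                  chrom = g$chrom, pos = g$pos, pop_labels = g$pop_labels)
}

#' Prune highly correlated markers
#'
#' Greedy left-to-right scan in marker order: a marker is dropped if its
#' absolute Pearson correlation with any earlier retained marker exceeds
#' `r_max`. Removing one member of each near-duplicate pair improves the
#' numerical stability of penalized regression fits. Zero-variance markers
#' are dropped with a warning (their correlation is undefined).
#'
#' @param g a [genotype_matrix()] with no missing entries.
#' @param r_max correlation threshold, default 0.95.
#' @return a [genotype_matrix()] in which no retained pair has |r| >
#'   `r_max`.
#' @export
prune_correlated <- function(g, r_max = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$counts)) stop("missing entries present: impute first")
  x <- g$counts
  v <- apply(x, 2, stats::sd)
  zero_var <- v == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance marker(s) dropped ",
            "(correlation undefined)")
  }
  cols <- which(!zero_var)
  if (length(cols) == 0) stop("no markers with positive variance")
  cm <- abs(stats::cor(x[, cols, drop = FALSE]))
  keep <- logical(length(cols))
  for (j in seq_along(cols)) {
    keep[j] <- !any(cm[j, seq_len(j - 1)][keep[seq_len(j - 1)]] > r_max)
  }
  subset_genotypes(g, markers = cols[keep])
}
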