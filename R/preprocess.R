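#' Prevalence and abundance filtering of a count matrix
#'
#' Retains features that are (a) expressed (non-zero) in at least
#' `min_nonzero_frac` of samples and (b) reliably expressed
#' (count >= `min_count`) in at least `min_count_frac` of samples.
#' Sample set and feature order are preserved.
#'
#' @param counts features x samples count matrix.
#' @param min_nonzero_frac minimum fraction of samples with non-zero counts
#'   (default 0.80).
#' @param min_count count threshold for "reliable" expression (default 5).
#' @param min_count_frac minimum fraction of samples reaching `min_count`
#'   (default 0.10).
#' @return the filtered count matrix.
#' @export
filter_features <- function(counts, min_nonzero_frac = 0.80,
                            min_count = 5, min_count_frac = 0.10) {
  stopifnot(is.matrix(counts), min_nonzero_frac >= 0, min_nonzero_frac <= 1,
            min_count >= 0, min_count_frac >= 0, min_count_frac <= 1)
  keep <- rowMeans(counts > 0) >= min_nonzero_frac &
    rowMeans(counts >= min_count) >= min_count_frac
  if (!any(keep)) warning("no feature passed the expression filters")
  counts[keep, , drop = FALSE]
}

#' Log2(CPM + 1) normalization
#'
#' Values are `log2(count / effective_library_size * 1e6 + 1)`. The effective
#' library size is the raw column total (`"total-count"`, default) or the
#' column total rescaled by a trimmed-mean-of-M-values factor
#' (`"trimmed-mean"`, via edgeR with its standard 30%/5% trims).
#'
#' @param counts features x samples count matrix.
#' @param method `"total-count"` or `"trimmed-mean"`.
#' @return list of class `normalized_matrix` with elements `values`
#'   (log2(CPM+1) matrix) and `effective_library_sizes`.
#' @export
normalize_cpm <- function(counts, method = c("total-count", "trimmed-mean")) {
  method <- match.arg(method)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  if (method == "trimmed-mean") {
    lib <- lib * edgeR::calcNormFactors(counts, method = "TMM")
  }
  values <- log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
  structure(list(values = values, effective_library_sizes = lib,
                 method = method),
            class = "normalized_matrix")
}

#' Harmonize RNA-type strata of a normalized matrix
#'
#' Removes multiplicative (additive on the log scale) offsets between
#' feature-level strata such as RNA types. Within each stratum, values are
#' standardized against stratum-level location and scale estimates shrunk
#' toward the grand estimates by an empirical-Bayes step (shrinkage weight
#' `n_s / (n_s + prior_features)` for a stratum of `n_s` features), then
#' re-expressed on the common scale. Strata with fewer than 2 features are
#' passed through unadjusted with a warning.
#'
#' @param norm a `normalized_matrix` (or a bare numeric matrix).
#' @param features feature metadata data.frame with `feature_id` and
#'   `rna_type`; row order need not match the matrix.
#' @param prior_features prior pseudo-count (in features) of the EB shrinkage.
#' @return an object of the same shape with harmonized `values`.
#' @export
harmonize_strata <- function(norm, features, prior_features = 10) {
  is_nm <- inherits(norm, "normalized_matrix")
  values <- if (is_nm) norm$values else norm
  stopifnot(is.matrix(values))
  stratum <- features$rna_type[match(rownames(values), features$feature_id)]
  if (anyNA(stratum)) stop("every feature needs an rna_type")

  grand_loc <- mean(values)
  grand_scale <- stats::sd(values)
  out <- values
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    if (length(rows) < 2) {
      warning("stratum '", s, "' has fewer than 2 features; passed through")
      next
    }
    x <- values[rows, , drop = FALSE]
    w <- length(rows) / (length(rows) + prior_features)
    loc <- w * mean(x) + (1 - w) * grand_loc
    scl <- sqrt(w * stats::var(as.vector(x)) + (1 - w) * grand_scale^2)
    out[rows, ] <- (x - loc) / scl * grand_scale + grand_loc
  }
  if (any(!is.finite(out))) stop("harmonization produced non-finite values")
  if (is_nm) {
    norm$values <- out
    norm
  } else {
    out
  }
}
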