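# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Coerce labels to a 0/1 case indicator. "case" is the positive class.
as_case_indicator <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("case", "control"))) {
    stop("labels must be 'case'/'control' (or 0/1)")
  }
  as.integer(y == "case")
}

# Derive a reproducible sub-seed for a named stage from a master seed.
# Kept below 2^31 - 1 so the result is a valid R integer.
stage_seed <- function(seed, stage, i = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 97 + i) %% 2147483629)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so per-fold class counts differ by at most one.
make_folds <- function(y, k, seed, stratified = TRUE) {
  y <- as_case_indicator(y)
  n <- length(y)
  if (k < 2L) stop("need at least 2 folds")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(k), n)
    }
  })
  if (any(tabulate(fold[y == 1], k) == 0) || any(tabulate(fold[y == 0], k) == 0)) {
    stop("a fold is missing a class; reduce the number of folds")
  }
  fold
}

# Fast per-row variance for a matrix (base R, no matrixStats dependency).
# Two-pass centered form: numerically stable and safe for integer input.
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

# Vectorized per-feature Welch t-test p-values on a features x samples matrix.
welch_t_pvalues <- function(X, y) {
  y <- as_case_indicator(y)
  a <- X[, y == 1, drop = FALSE]
  b <- X[, y == 0, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  va <- row_vars(a) / na
  vb <- row_vars(b) / nb
  se2 <- va + vb
  tt <- (rowMeans(a) - rowMeans(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1
  p
}

# Atomic text write: write to a temporary file in the target directory,
# then rename, so partial outputs never masquerade as complete.
atomic_write <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}
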