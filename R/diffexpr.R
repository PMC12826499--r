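#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of its count to the feature's geometric mean, computed over features
#' with strictly positive counts in every sample. If no such feature exists,
#' the ratios fall back to positive counts only, with a warning. Factors are
#' rescaled to unit geometric mean, so rescaling a single sample's counts
#' moves only that sample's factor.
#'
#' @param counts features x samples count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    loggeo <- rowMeans(log(sub))
    sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - loggeo)))
  } else {
    warning("no feature with all-positive counts; ",
            "using positive-count-only median of ratios")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    sf <- apply(logc, 2, function(col) {
      exp(stats::median(col - loggeo, na.rm = TRUE))
    })
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("size factor estimation failed")
  # rescale to unit geometric mean so factors are comparable across runs
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion per feature, pooled across groups, on
# size-factor-normalized counts: Var(q) ~ mu * mean(1/s) + phi * mu^2.
mom_dispersion <- function(counts, case, sf, floor = 1e-8) {
  q <- sweep(counts, 2, sf, "/")
  est <- matrix(0, nrow(counts), 2)
  wts <- numeric(2)
  for (g in 1:2) {
    cols <- if (g == 1) case else !case
    qs <- q[, cols, drop = FALSE]
    m <- rowMeans(qs)
    v <- row_vars(qs)
    est[, g] <- (v - m * mean(1 / sf[cols])) / pmax(m, 1e-12)^2
    wts[g] <- sum(cols) - 1
  }
  pmax((est[, 1] * wts[1] + est[, 2] * wts[2]) / sum(wts), floor)
}

# One-group NB mean fit by Fisher scoring on eta = log(mu), vectorized over
# features. y: features x samples counts for one group; s: size factors;
# phi: per-feature dispersion. Returns eta and the Fisher information.
nb_group_fit <- function(y, s, phi, max_iter = 50, tol = 1e-10) {
  tot <- rowSums(y)
  zero <- tot == 0
  tot[zero] <- 0.5  # continuity correction for an all-zero group
  eta <- log(tot / sum(s))
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta) %o% s
    denom <- 1 + phi * mu
    U <- rowSums((y - mu) / denom)
    I <- rowSums(mu / denom)
    step <- pmin(pmax(U / I, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% s
  list(eta = eta, info = rowSums(mu / (1 + phi * mu)), all_zero = zero)
}

#' Negative-binomial Wald differential expression
#'
#' Per feature, a negative-binomial log-linear model with a case/control
#' group indicator and `log(size_factor)` offsets is fitted by Fisher
#' scoring at a fixed per-feature dispersion (method-of-moments estimate
#' with a floor of 1e-8 unless supplied). The Wald statistic is the group
#' log-fold-change divided by its standard error, with a two-sided normal
#' p-value; fold changes are estimated in natural log and reported in log2.
#'
#' @param counts features x samples count matrix.
#' @param samples sample metadata with `sample_id` and `group` columns
#'   (`case`/`control`), or a label vector aligned with the columns.
#' @param sf optional size factors; defaults to [size_factors()].
#' @param dispersion optional fixed per-feature dispersion(s).
#' @return data.frame of class `de_result`: feature_id, log2fc, se (log2
#'   scale), wald_stat, p, padj (Benjamini-Hochberg), base_mean (mean of
#'   size-factor-normalized counts), dispersion, all_zero flag. Size factors
#'   attached as attribute `size_factors`.
#' @export
nb_wald <- function(counts, samples, sf = NULL, dispersion = NULL) {
  y <- if (is.data.frame(samples)) {
    samples$group[match(colnames(counts), samples$sample_id)]
  } else samples
  case <- as_case_indicator(y) == 1
  if (sum(case) < 2 || sum(!case) < 2) {
    stop("each group needs at least 2 samples")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersion)) {
    dispersion <- mom_dispersion(counts, case, sf)
  } else {
    dispersion <- rep_len(dispersion, nrow(counts))
  }

  fit_case <- nb_group_fit(counts[, case, drop = FALSE], sf[case], dispersion)
  fit_ctrl <- nb_group_fit(counts[, !case, drop = FALSE], sf[!case], dispersion)

  lfc_nat <- fit_case$eta - fit_ctrl$eta
  se_nat <- sqrt(1 / fit_case$info + 1 / fit_ctrl$info)
  wald <- lfc_nat / se_nat
  p <- 2 * stats::pnorm(-abs(wald))

  both_zero <- fit_case$all_zero & fit_ctrl$all_zero
  lfc_nat[both_zero] <- 0
  wald[both_zero] <- 0
  p[both_zero] <- 1

  res <- data.frame(feature_id = rownames(counts),
                    log2fc = lfc_nat / log(2),
                    se = se_nat / log(2),
                    wald_stat = wald,
                    p = p,
                    padj = bh_adjust(p),
                    base_mean = rowMeans(sweep(counts, 2, sf, "/")),
                    dispersion = dispersion,
                    all_zero = both_zero,
                    stringsAsFactors = FALSE)
  attr(res, "size_factors") <- sf
  class(res) <- c("de_result", class(res))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (false-discovery-rate scale), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the triple differential-expression screening gate
#'
#' Features pass if `padj < alpha`, `|log2fc| > min_abs_log2fc`, and
#' `base_mean > min_base_mean` (all strict, matching the reported criteria
#' adjusted p < 0.05, |log2FC| > 1.2, mean abundance > 50).
#'
#' @param de a `de_result` data.frame from [nb_wald()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1.2).
#' @param min_base_mean minimum mean normalized abundance (default 50).
#' @return character vector of passing feature_ids (possibly empty).
#' @export
select_de <- function(de, alpha = 0.05, min_abs_log2fc = 1.2,
                      min_base_mean = 50) {
  stopifnot(nrow(de) > 0, alpha > 0, alpha < 1,
            min_abs_log2fc >= 0, min_base_mean >= 0)
  pass <- de$padj < alpha & abs(de$log2fc) > min_abs_log2fc &
    de$base_mean > min_base_mean
  de$feature_id[pass]
}
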