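# Equal-frequency binning of predicted probabilities; ties go to the lower
# bin. Returns an integer bin index per observation.
risk_bins <- function(p, bins) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1),
                               type = 7))
  if (length(br) < 3) return(rep(1L, length(p)))
  cut(p, breaks = br, include.lowest = TRUE, labels = FALSE, right = TRUE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are grouped into `bins` equal-frequency risk deciles of the
#' predicted probability (ties assigned to the lower bin; bins with expected
#' event count below 1 merged with their neighbor). The statistic is
#' `sum (O - E)^2 / (E (1 - E / n_bin))` with an upper-tail chi-square
#' p-value on `bins_used - 2` degrees of freedom (the in-sample convention;
#' `df = "external"` uses `bins_used`, appropriate for probabilities not
#' fitted on these data).
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @param bins number of risk bins (default 10).
#' @param df `"fit"` (bins - 2, default) or `"external"` (bins).
#' @return list: `stat`, `df`, `p_value`, `bins_used`.
#' @export
hosmer_lemeshow <- function(p, y, bins = 10, df = c("fit", "external")) {
  df <- match.arg(df)
  y <- as_case_indicator(y)
  stopifnot(length(p) == length(y), all(p >= 0 & p <= 1))
  if (length(p) < bins) stop("need at least as many observations as bins")
  bin <- risk_bins(p, bins)
  O <- tapply(y, bin, sum)
  E <- tapply(p, bin, sum)
  n_b <- tapply(y, bin, length)
  # merge bins with expected event count below 1 into a neighbor
  while (length(E) > 3 && any(E < 1)) {
    i <- which(E < 1)[1]
    j <- if (i == 1) 2L else i - 1L
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; n_b[j] <- n_b[j] + n_b[i]
    O <- O[-i]; E <- E[-i]; n_b <- n_b[-i]
  }
  g <- length(E)
  if (g < 3) stop("fewer than 3 usable bins after merging")
  stat <- sum((O - E)^2 / pmax(E * (1 - E / n_b), 1e-10))
  dof <- if (df == "fit") g - 2L else g
  list(stat = unname(stat), df = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       bins_used = g)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @inheritParams hosmer_lemeshow
#' @return numeric scalar in `[0, 1]`.
#' @export
brier_score <- function(p, y) {
  y <- as_case_indicator(y)
  if (length(p) == 0) stop("empty input")
  stopifnot(length(p) == length(y))
  mean((p - y)^2)
}

#' Calibration slope and intercept
#'
#' Logistic regression of the outcome on `logit(p)` (probabilities clipped to
#' `[1e-6, 1 - 1e-6]`). A slope of 1 indicates accurate probability
#' predictions; below 1, overconfidence.
#'
#' @inheritParams hosmer_lemeshow
#' @return list: `slope`, `intercept`, `separation` flag (TRUE when the fit
#'   showed signs of perfect separation).
#' @export
calibration_slope <- function(p, y) {
  y <- as_case_indicator(y)
  lp <- stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ lp, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) warning("possible separation in calibration-slope fit")
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), separation = sep)
}

#' Calibration curve points
#'
#' Per equal-frequency risk bin: mean predicted probability, observed event
#' fraction, and bin count.
#'
#' @inheritParams hosmer_lemeshow
#' @return data.frame: `mean_predicted`, `observed_freq`, `n`.
#' @export
calibration_curve <- function(p, y, bins = 10) {
  y <- as_case_indicator(y)
  stopifnot(length(p) == length(y))
  bin <- risk_bins(p, bins)
  out <- data.frame(mean_predicted = as.numeric(tapply(p, bin, mean)),
                    observed_freq = as.numeric(tapply(y, bin, mean)),
                    n = as.integer(tapply(y, bin, length)))
  out[out$n > 0, , drop = FALSE]
}

#' Full calibration report
#'
#' @inheritParams hosmer_lemeshow
#' @return list of class `calibration_report`: Hosmer-Lemeshow statistic/df/p,
#'   Brier score, calibration slope and intercept, and curve points.
#' @export
calibration_report <- function(p, y, bins = 10, df = "fit") {
  hl <- tryCatch(hosmer_lemeshow(p, y, bins = bins, df = df),
                 error = function(e) {
                   warning("Hosmer-Lemeshow not computable: ",
                           conditionMessage(e))
                   list(stat = NA_real_, df = NA_integer_,
                        p_value = NA_real_, bins_used = NA_integer_)
                 })
  sl <- suppressWarnings(calibration_slope(p, y))
  structure(list(hl_stat = hl$stat, hl_df = hl$df, hl_p = hl$p_value,
                 brier = brier_score(p, y),
                 slope = sl$slope, intercept = sl$intercept,
                 curve_points = calibration_curve(p, y, bins = bins)),
            class = "calibration_report")
}
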