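#' Configuration for ensemble stability selection
#'
#' @param n_iterations resampling iterations for stability scores (default 20).
#' @param subsample_frac stratified subsample fraction per iteration
#'   (default 0.8, without replacement).
#' @param top_k features kept per iteration by the ranking selectors
#'   (random forest, SVM-RFE; default 20).
#' @param trees random-forest tree count (default 500).
#' @param rfe_step_frac fraction of remaining features eliminated per SVM-RFE
#'   round (default 0.10, at least one feature).
#' @param rfe_cost linear-SVM cost for SVM-RFE (default 1).
#' @param lambda_grid L1 penalty grid, log-spaced 1e2..1e-4.
#' @param consensus_threshold minimum per-selector stability for the
#'   consensus flag (default 0.5).
#' @return list of class `selector_config`.
#' @export
selector_config <- function(n_iterations = 20, subsample_frac = 0.8,
                            top_k = 20, trees = 500, rfe_step_frac = 0.10,
                            rfe_cost = 1,
                            lambda_grid = 10^seq(2, -4, length.out = 50),
                            consensus_threshold = 0.5) {
  stopifnot(n_iterations >= 1, subsample_frac > 0, subsample_frac <= 1,
            top_k >= 1, trees >= 1, rfe_step_frac > 0, rfe_step_frac < 1)
  structure(list(n_iterations = n_iterations, subsample_frac = subsample_frac,
                 top_k = top_k, trees = trees, rfe_step_frac = rfe_step_frac,
                 rfe_cost = rfe_cost, lambda_grid = lambda_grid,
                 consensus_threshold = consensus_threshold),
            class = "selector_config")
}

check_two_classes <- function(y) {
  y <- as_case_indicator(y)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 samples per class")
  }
  y
}

#' L1-penalized logistic selection (non-zero coefficients)
#'
#' The penalty is chosen by cross-validated binomial deviance over
#' `config$lambda_grid`; features with non-zero coefficients at the
#' deviance-minimizing penalty are returned. A single-feature input is
#' returned as-is (nothing to shrink against).
#'
#' @param X features x samples numeric matrix.
#' @param y case/control labels.
#' @param config a [selector_config()].
#' @param seed optional seed for the internal cross-validation folds.
#' @return character vector of selected feature ids.
#' @export
select_l1 <- function(X, y, config = selector_config(), seed = NULL) {
  y <- check_two_classes(y)
  if (nrow(X) < 2) return(rownames(X))
  run <- function() {
    fit <- glmnet::cv.glmnet(t(X), y, family = "binomial", alpha = 1,
                             lambda = config$lambda_grid, nfolds = 5,
                             type.measure = "deviance", standardize = TRUE)
    co <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
    names(co)[co != 0]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random-forest impurity-importance selection (top k)
#'
#' Ranks features by mean decrease in Gini impurity across the forest and
#' returns the top `config$top_k`.
#'
#' @inheritParams select_l1
#' @return character vector of selected feature ids.
#' @export
select_rf <- function(X, y, config = selector_config(), seed = NULL) {
  y <- check_two_classes(y)
  if (config$top_k >= nrow(X)) {
    warning("top_k >= number of features; returning all features")
    return(rownames(X))
  }
  run <- function() {
    fit <- randomForest::randomForest(t(X), factor(y, levels = c(0, 1)),
                                      ntree = config$trees)
    imp <- fit$importance[, "MeanDecreaseGini"]
    names(sort(imp, decreasing = TRUE))[seq_len(config$top_k)]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Linear SVM squared weights on standardized features; constant features get
# weight 0. Returns the weight vector named by feature.
svm_weights2 <- function(Xs, y, cost) {
  fit <- tryCatch(
    e1071::svm(Xs, factor(y, levels = c(0, 1)), kernel = "linear",
               cost = cost, scale = FALSE),
    error = function(e) e1071::svm(Xs, factor(y, levels = c(0, 1)),
                                   kernel = "linear", cost = cost / 10,
                                   scale = FALSE))
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  stats::setNames(w^2, colnames(Xs))
}

#' Linear-SVM recursive feature elimination (top k)
#'
#' Repeatedly fits a linear maximum-margin classifier on the surviving
#' features, ranks them by squared weight, and removes the lowest-ranked
#' `rfe_step_frac` fraction (at least one) until `top_k` remain. The full
#' elimination order is attached as attribute `elimination_order`
#' (first eliminated first; survivors appended by final weight rank,
#' strongest last).
#'
#' @inheritParams select_l1
#' @return character vector of the `top_k` surviving feature ids.
#' @export
select_svmrfe <- function(X, y, config = selector_config(), seed = NULL) {
  y <- check_two_classes(y)
  if (config$top_k >= nrow(X)) {
    warning("top_k >= number of features; returning all features")
    return(rownames(X))
  }
  Xs <- scale(t(X))
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  run <- function() {
    surviving <- colnames(Xs)
    eliminated <- character(0)
    while (length(surviving) > config$top_k) {
      w2 <- svm_weights2(Xs[, surviving, drop = FALSE], y, config$rfe_cost)
      n_drop <- min(max(1L, floor(config$rfe_step_frac * length(surviving))),
                    length(surviving) - config$top_k)
      drop <- names(sort(w2))[seq_len(n_drop)]
      eliminated <- c(eliminated, drop)
      surviving <- setdiff(surviving, drop)
    }
    w2 <- svm_weights2(Xs[, surviving, drop = FALSE], y, config$rfe_cost)
    structure(surviving,
              elimination_order = c(eliminated, names(sort(w2))))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

default_selectors <- function() {
  list(l1 = select_l1, rf = select_rf, rfe = select_svmrfe)
}

# Stratified subsample (without replacement) of sample indices.
stratified_subsample <- function(y, frac) {
  idx <- integer(0)
  for (cls in unique(y)) {
    pool <- which(y == cls)
    take <- max(1L, round(frac * length(pool)))
    idx <- c(idx, sample(pool, take))
  }
  sort(idx)
}

#' Resampling stability scores for an ensemble of selectors
#'
#' For each of `n_iterations` stratified subsamples (fraction
#' `subsample_frac` of each class, without replacement), every selector is
#' run and feature membership recorded. The stability score of a feature
#' under a selector is the exact fraction of iterations in which it was
#' selected. A feature is consensus-flagged when its stability reaches
#' `consensus_threshold` under every selector.
#'
#' @param X features x samples numeric matrix.
#' @param y case/control labels.
#' @param selectors named list of selector functions `(X, y, config, seed)`;
#'   defaults to L1-logistic, random forest, and SVM-RFE.
#' @param config a [selector_config()].
#' @param seed integer seed driving subsampling and selector randomness.
#' @return data.frame of class `stability_report`: feature_id, one
#'   `stab_<name>` column per selector, mean_stability, and consensus flag.
#' @export
stability_scores <- function(X, y, selectors = default_selectors(),
                             config = selector_config(), seed = 1) {
  y <- check_two_classes(y)
  counts <- matrix(0L, nrow(X), length(selectors),
                   dimnames = list(rownames(X), names(selectors)))
  for (it in seq_len(config$n_iterations)) {
    idx <- withr::with_seed(stage_seed(seed, "subsample", it),
                            stratified_subsample(y, config$subsample_frac))
    if (length(unique(y[idx])) < 2) stop("subsample left a class empty")
    Xi <- X[, idx, drop = FALSE]
    for (s in seq_along(selectors)) {
      picked <- suppressWarnings(
        selectors[[s]](Xi, y[idx], config,
                       seed = stage_seed(seed, names(selectors)[s], it)))
      counts[picked, s] <- counts[picked, s] + 1L
    }
  }
  stab <- counts / config$n_iterations
  out <- data.frame(feature_id = rownames(X), stringsAsFactors = FALSE)
  for (s in colnames(stab)) out[[paste0("stab_", s)]] <- stab[, s]
  out$mean_stability <- rowMeans(stab)
  out$consensus <- apply(stab >= config$consensus_threshold, 1, all)
  class(out) <- c("stability_report", class(out))
  out
}

#' Outer-fold consistency scores for the selector consensus
#'
#' Splits samples into `scheme$outer_folds` stratified folds; within each
#' fold's training partition (the other folds), all selectors are run and a
#' feature counts as selected in that fold when every selector picks it.
#' The consistency score is the number of folds (out of `outer_folds`) in
#' which the feature entered this consensus set.
#'
#' @inheritParams stability_scores
#' @param scheme a [cv_scheme()].
#' @return data.frame: feature_id, consistency_num, consistency_den.
#' @export
fold_consistency <- function(X, y, selectors = default_selectors(),
                             config = selector_config(),
                             scheme = cv_scheme(), seed = 1) {
  y <- check_two_classes(y)
  fold <- make_folds(y, scheme$outer_folds, stage_seed(seed, "outer"),
                     scheme$stratified)
  hits <- stats::setNames(integer(nrow(X)), rownames(X))
  for (f in seq_len(scheme$outer_folds)) {
    tr <- fold != f
    picked <- lapply(seq_along(selectors), function(s) {
      suppressWarnings(
        selectors[[s]](X[, tr, drop = FALSE], y[tr], config,
                       seed = stage_seed(seed, paste0("fold_", names(selectors)[s]), f)))
    })
    consensus <- Reduce(intersect, picked)
    hits[consensus] <- hits[consensus] + 1L
  }
  data.frame(feature_id = rownames(X), consistency_num = as.integer(hits),
             consistency_den = scheme$outer_folds, stringsAsFactors = FALSE)
}

#' Build the consensus biomarker panel
#'
#' Consensus-flagged features (stable under every selector) are ordered by
#' outer-fold consistency (descending), then mean stability (descending),
#' then adjusted differential-expression p-value (ascending), and the first
#' `size` are returned.
#'
#' @param report a `stability_report` from [stability_scores()], merged or
#'   supplied together with consistency scores.
#' @param consistency data.frame from [fold_consistency()] (optional if the
#'   report already has `consistency_num`).
#' @param de a `de_result` used for the adjusted-p tie-break.
#' @param size panel size requested.
#' @return data.frame of class `consensus_panel`, `size` rows (fewer, with a
#'   warning, if not enough consensus features exist).
#' @export
consensus_panel <- function(report, de, size, consistency = NULL) {
  if (!is.null(consistency)) {
    report <- merge(report, consistency, by = "feature_id", sort = FALSE)
  }
  if (is.null(report$consistency_num)) {
    report$consistency_num <- 0L
    report$consistency_den <- 0L
  }
  report$padj <- de$padj[match(report$feature_id, de$feature_id)]
  cand <- report[report$consensus, , drop = FALSE]
  if (nrow(cand) < size) {
    warning("only ", nrow(cand), " consensus features available; returning all")
    size <- nrow(cand)
  }
  ord <- order(-cand$consistency_num, -cand$mean_stability, cand$padj)
  panel <- cand[ord, , drop = FALSE][seq_len(size), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("consensus_panel", "data.frame")
  panel
}
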