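#' Nested cross-validation scheme
#'
#' @param outer_folds outer folds for generalization estimation (default 10,
#'   i.e. 90%/10% train/test splits).
#' @param inner_folds inner folds for tuning and selection (default 5).
#' @param stratified preserve the class ratio within folds (default TRUE).
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(outer_folds = 10, inner_folds = 5, stratified = TRUE) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 stratified = stratified), class = "cv_scheme")
}

#' RBF-SVM classifier specification
#'
#' @param C_grid cost grid for the grid search (default 0.1, 1, 10, 100).
#' @param gamma_grid kernel width grid; `NA` entries are replaced by `1/d`
#'   for `d` panel features at fit time (default 1e-3, 1e-2, 1e-1, 1/d).
#' @param rebalance `"smote"` (default) or `"none"`.
#' @param smote_k SMOTE neighbor count (default 5).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(C_grid = c(0.1, 1, 10, 100),
                            gamma_grid = c(1e-3, 1e-2, 1e-1, NA),
                            rebalance = c("smote", "none"), smote_k = 5) {
  rebalance <- match.arg(rebalance)
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1, smote_k >= 1,
            all(C_grid > 0), all(is.na(gamma_grid) | gamma_grid > 0))
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 rebalance = rebalance, smote_k = smote_k),
            class = "classifier_spec")
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class samples as `x + u * (neighbor - x)` with
#' `u ~ Uniform(0, 1)` and the neighbor drawn among the `k` nearest minority
#' samples (Euclidean), until the classes are balanced. Original samples are
#' preserved verbatim; an already balanced input is returned unchanged.
#'
#' @param X samples x features numeric matrix.
#' @param y case/control labels (any 0/1-codable form).
#' @param k neighbor count (default 5; capped at minority size - 1).
#' @param seed integer seed.
#' @return list with `X`, `y` (0/1 integer) and `synthetic` (logical flag per
#'   output row; original rows first).
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1) {
  y <- as_case_indicator(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, length(y))))
  }
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(y == minority)
  if (length(min_idx) < 2) stop("minority class needs at least 2 samples")
  n_new <- abs(n1 - n0)
  M <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  k_eff <- min(k, length(min_idx) - 1L)
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k_eff)]),
               ncol = k_eff, byrow = TRUE)
  synth <- withr::with_seed(seed, {
    base_i <- sample(length(min_idx), n_new, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample(k_eff, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    M[base_i, , drop = FALSE] +
      u * (M[nb_i, , drop = FALSE] - M[base_i, , drop = FALSE])
  })
  rownames(synth) <- sprintf("synthetic_%04d", seq_len(n_new))
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_new)))
}

#' ROC analysis of continuous scores
#'
#' The ROC curve is built by a threshold sweep in which tied scores move
#' together; the AUC is the trapezoidal area, which equals the pairwise
#' concordance probability with ties counted 1/2. Sensitivity, specificity
#' and accuracy are reported at `threshold` (predicted positive when
#' `score >= threshold`); when no threshold is supplied, the Youden-optimal
#' point on these data is used and recorded.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param y case/control labels.
#' @param threshold optional operating point.
#' @return list of class `metric_set`: auc, sensitivity, specificity,
#'   accuracy, threshold, roc_points (fpr, tpr).
#' @export
evaluate_roc <- function(scores, y, threshold = NULL) {
  y <- as_case_indicator(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tp <- cumsum(vapply(thr, function(t) sum(scores == t & y == 1), 0))
  fp <- cumsum(vapply(thr, function(t) sum(scores == t & y == 0), 0))
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (is.null(threshold)) {
    j <- (tpr - fpr)[-1]
    threshold <- thr[which.max(j)]
  }
  pred <- as.integer(scores >= threshold)
  structure(list(auc = auc,
                 sensitivity = sum(pred == 1 & y == 1) / n1,
                 specificity = sum(pred == 0 & y == 0) / n0,
                 accuracy = mean(pred == y),
                 threshold = threshold,
                 roc_points = data.frame(fpr = fpr, tpr = tpr)),
            class = "metric_set")
}

#' t-distribution confidence interval for fold AUCs
#'
#' `mean +/- t_{n-1, 1-alpha/2} * sd / sqrt(n)`, clipped to `[0, 1]`;
#' accounts for the small number of folds.
#'
#' @param fold_aucs per-fold AUC values (>= 2).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
fold_auc_ci <- function(fold_aucs, level = 0.95) {
  n <- length(fold_aucs)
  if (n < 2) stop("need at least 2 folds")
  m <- mean(fold_aucs)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(fold_aucs) / sqrt(n)
  c(low = max(0, m - half), high = min(1, m + half))
}

# SMOTE or pass-through according to the classifier spec.
rebalance_training <- function(X, y, spec, seed) {
  if (spec$rebalance == "smote") {
    smote_oversample(X, y, k = spec$smote_k, seed = seed)
  } else {
    list(X = X, y = as_case_indicator(y), synthetic = rep(FALSE, length(y)))
  }
}

#' Fit an RBF-kernel SVM with inner-CV grid search and SMOTE rebalancing
#'
#' `(C, gamma)` is chosen to maximize mean inner-fold AUC, with SMOTE applied
#' inside each inner training split only (never to validation data). The
#' final model is refit on the full rebalanced training partition, and a
#' Platt-style sigmoid mapping margins to probabilities is fitted on the
#' original (non-synthetic) training samples. A single-point grid skips the
#' inner search.
#'
#' @param X samples x features training matrix.
#' @param y case/control labels.
#' @param spec a [classifier_spec()].
#' @param inner a [cv_scheme()] supplying `inner_folds`.
#' @param seed integer seed.
#' @return object of class `rbf_svm_fit` with the chosen `C`, `gamma`, the
#'   fitted model, and the Platt coefficients; use `predict(fit, newdata)`
#'   for calibrated probabilities.
#' @export
fit_rbf_svm <- function(X, y, spec = classifier_spec(), inner = cv_scheme(),
                        seed = 1) {
  y <- as_case_indicator(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(apply(X, 2, stats::sd) == 0) && ncol(X) == sum(apply(X, 2, stats::sd) == 0)) {
    stop("all feature columns are constant")
  }
  gamma_grid <- ifelse(is.na(spec$gamma_grid), 1 / ncol(X), spec$gamma_grid)
  grid <- expand.grid(C = spec$C_grid, gamma = unique(gamma_grid))

  if (nrow(grid) > 1) {
    fold <- make_folds(y, inner$inner_folds, stage_seed(seed, "inner"),
                       inner$stratified)
    score <- numeric(nrow(grid))
    for (f in seq_len(inner$inner_folds)) {
      tr <- fold != f
      bal <- rebalance_training(X[tr, , drop = FALSE], y[tr], spec,
                                stage_seed(seed, "smote_inner", f))
      for (g in seq_len(nrow(grid))) {
        fit <- svm_quiet(bal$X, bal$y, grid$C[g], grid$gamma[g])
        dv <- svm_decision(fit, X[!tr, , drop = FALSE])
        # orient decision values toward the case class before averaging
        a <- evaluate_roc(dv, y[!tr])$auc
        score[g] <- score[g] + max(a, 1 - a) / inner$inner_folds
      }
    }
    best <- which.max(score)
  } else {
    best <- 1L
  }

  bal <- rebalance_training(X, y, spec, stage_seed(seed, "smote_final"))
  model <- svm_quiet(bal$X, bal$y, grid$C[best], grid$gamma[best])
  dv_train <- svm_decision(model, X)
  platt <- suppressWarnings(
    stats::glm(y ~ dv, family = stats::binomial(),
               data = data.frame(y = y, dv = dv_train)))
  structure(list(model = model, platt = platt,
                 C = grid$C[best], gamma = grid$gamma[best],
                 features = colnames(X)),
            class = "rbf_svm_fit")
}

svm_quiet <- function(X, y, C, gamma) {
  suppressWarnings(
    e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
               cost = C, gamma = gamma, scale = TRUE))
}

svm_decision <- function(fit, X) {
  as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values"))
}

#' @export
predict.rbf_svm_fit <- function(object, newdata, type = c("prob", "decision"),
                                ...) {
  type <- match.arg(type)
  X <- newdata[, object$features, drop = FALSE]
  dv <- svm_decision(object$model, X)
  if (type == "decision") return(dv)
  as.numeric(stats::predict(object$platt, data.frame(dv = dv),
                            type = "response"))
}

# Per-fold screening + ensemble selection on training data only.
# Returns the fold panel (ordered by training t-test p) and the consensus set.
fold_select <- function(Xtr, ytr, selectors, config, n_screen, seed) {
  p <- welch_t_pvalues(Xtr, ytr)
  keep <- order(p)[seq_len(min(n_screen, nrow(Xtr)))]
  Xc <- Xtr[keep, , drop = FALSE]
  picked <- lapply(seq_along(selectors), function(s) {
    suppressWarnings(selectors[[s]](Xc, ytr, config,
                                    seed = stage_seed(seed, names(selectors)[s])))
  })
  consensus <- Reduce(intersect, picked)
  panel <- if (length(consensus) >= 2) {
    consensus[order(p[match(consensus, rownames(Xtr))])]
  } else {
    # degenerate fold: fall back to the strongest screened features
    rownames(Xtr)[order(p)[seq_len(min(3, nrow(Xtr)))]]
  }
  list(panel = panel, consensus = consensus)
}

#' Leakage-safe nested cross-validation
#'
#' Outer folds estimate generalization; all feature selection, SMOTE
#' rebalancing and hyperparameter tuning happen strictly inside each outer
#' training partition (90% of samples at the default 10 folds), and metrics
#' are computed on the untouched held-out 10%. The operating point for
#' sensitivity/specificity is the Youden-optimal threshold on the training
#' partition, applied unchanged to the test partition.
#'
#' @param X features x samples numeric matrix (normalized expression).
#' @param y case/control labels aligned with columns of `X`.
#' @param panel optional fixed feature panel; when `NULL`, features are
#'   selected per fold by t-test screening (top `n_screen`) followed by the
#'   selector ensemble consensus.
#' @param spec a [classifier_spec()].
#' @param scheme a [cv_scheme()].
#' @param selectors,selector_cfg ensemble used when `panel` is `NULL`.
#' @param n_screen training-fold screening size before the ensemble
#'   (default 50).
#' @param seed integer seed.
#' @return object of class `nested_cv`: per-fold `metric_set`s and chosen
#'   hyperparameters, pooled out-of-fold metrics, `auc_ci`, per-fold selected
#'   features, per-feature consistency counts, and the pooled out-of-fold
#'   probabilities/labels (inputs of the calibration module).
#' @export
run_nested <- function(X, y, panel = NULL, spec = classifier_spec(),
                       scheme = cv_scheme(), selectors = default_selectors(),
                       selector_cfg = selector_config(), n_screen = 50,
                       seed = 1) {
  y <- as_case_indicator(y)
  fold <- make_folds(y, scheme$outer_folds, stage_seed(seed, "outer"),
                     scheme$stratified)
  folds <- vector("list", scheme$outer_folds)
  consistency <- stats::setNames(integer(nrow(X)), rownames(X))
  oof_prob <- numeric(length(y))
  test_ids <- character(0)
  for (f in seq_len(scheme$outer_folds)) {
    tr <- fold != f
    Xtr <- X[, tr, drop = FALSE]
    if (is.null(panel)) {
      sel <- fold_select(Xtr, y[tr], selectors, selector_cfg, n_screen,
                         stage_seed(seed, "fold_select", f))
      fold_panel <- sel$panel
      consistency[sel$consensus] <- consistency[sel$consensus] + 1L
    } else {
      fold_panel <- intersect(panel, rownames(X))
      if (length(fold_panel) == 0) stop("no panel feature present in the matrix")
    }
    fit <- fit_rbf_svm(t(Xtr[fold_panel, , drop = FALSE]), y[tr], spec,
                       scheme, seed = stage_seed(seed, "svm", f))
    prob_tr <- predict(fit, t(Xtr[fold_panel, , drop = FALSE]))
    thr <- evaluate_roc(prob_tr, y[tr])$threshold
    prob_te <- predict(fit, t(X[fold_panel, !tr, drop = FALSE]))
    oof_prob[!tr] <- prob_te
    test_ids <- c(test_ids, colnames(X)[!tr])
    folds[[f]] <- list(metrics = evaluate_roc(prob_te, y[!tr], threshold = thr),
                       C = fit$C, gamma = fit$gamma, features = fold_panel,
                       test_samples = colnames(X)[!tr])
  }
  fold_aucs <- vapply(folds, function(f) f$metrics$auc, 0)
  structure(list(folds = folds,
                 fold_aucs = fold_aucs,
                 pooled = evaluate_roc(oof_prob, y),
                 auc_ci = fold_auc_ci(fold_aucs),
                 mean_auc = mean(fold_aucs),
                 consistency = consistency,
                 oof_prob = oof_prob,
                 labels = y,
                 test_samples = test_ids,
                 scheme = scheme, seed = seed),
            class = "nested_cv")
}

#' Panel-size sweep over ranked features
#'
#' For each `k` in `k_range`, runs nested cross-validation with the top-`k`
#' panel and records AUC, sensitivity, specificity and the comprehensive
#' score (their unweighted mean).
#'
#' @param X,y,spec,scheme,seed as in [run_nested()].
#' @param ranked_features features ordered by priority; must cover
#'   `max(k_range)`.
#' @param k_range panel sizes to evaluate (default 2:10).
#' @return list of class `panel_sweep`: `table` (one row per k) and `best_k`.
#' @export
sweep_panel_size <- function(X, y, ranked_features, spec = classifier_spec(),
                             scheme = cv_scheme(), k_range = 2:10, seed = 1) {
  if (length(ranked_features) < max(k_range)) {
    stop("ranked_features shorter than max(k_range)")
  }
  rows <- lapply(k_range, function(k) {
    res <- run_nested(X, y, panel = ranked_features[seq_len(k)], spec = spec,
                      scheme = scheme, seed = stage_seed(seed, "sweep", k))
    data.frame(k = k, auc = res$mean_auc,
               sensitivity = mean(vapply(res$folds, function(f) f$metrics$sensitivity, 0)),
               specificity = mean(vapply(res$folds, function(f) f$metrics$specificity, 0)))
  })
  tab <- do.call(rbind, rows)
  tab$comprehensive_score <- rowMeans(tab[, c("auc", "sensitivity", "specificity")])
  structure(list(table = tab, best_k = pick_best_panel(tab)),
            class = "panel_sweep")
}

#' Pick the optimal panel size from a sweep table
#'
#' @param table data.frame with columns `k` and `comprehensive_score`.
#' @return the `k` maximizing the comprehensive score (smallest k on ties).
#' @export
pick_best_panel <- function(table) {
  table$k[which.max(table$comprehensive_score)]
}
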