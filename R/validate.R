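# Cross-validated out-of-fold scores for one linear model on a
# samples x features matrix. Returns list(scores, fold).
linear_cv_scores <- function(X, y, model, folds, seed) {
  fold <- make_folds(y, folds, seed, stratified = TRUE)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    scores[!tr] <- switch(
      model,
      "linear-svm" = {
        fit <- suppressWarnings(
          e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)), kernel = "linear",
                     cost = 1, scale = TRUE))
        dv <- svm_decision(fit, Xte)
        # orient toward the case class using the training margin
        if (evaluate_roc(svm_decision(fit, Xtr), y[tr])$auc < 0.5) -dv else dv
      },
      "logistic" = {
        fit <- suppressWarnings(
          stats::glm(y ~ ., family = stats::binomial(),
                     data = data.frame(y = y[tr], Xtr, check.names = TRUE)))
        stats::predict(fit, data.frame(Xte, check.names = TRUE),
                       type = "response")
      },
      "lda" = {
        fit <- MASS::lda(Xtr, grouping = factor(y[tr], levels = c(0, 1)))
        stats::predict(fit, Xte)$posterior[, "1"]
      },
      stop("unknown model: ", model))
  }
  list(scores = scores, fold = fold)
}

#' External-cohort validation with linear classifiers
#'
#' Fits each linear model to the validation cohort under stratified k-fold
#' cross-validation (folds capped so every fold holds at least one sample of
#' each class) and reports out-of-fold AUC with a fold-based t confidence
#' interval, plus sensitivity/specificity at the pooled Youden point. Panel
#' members absent from the matrix are dropped with a warning, mirroring
#' validation against platforms with incomplete biomarker coverage.
#'
#' @param X features x samples numeric matrix of the validation cohort.
#' @param y case/control labels.
#' @param panel character vector of panel feature ids.
#' @param models subset of `c("linear-svm", "logistic", "lda")`.
#' @param folds cross-validation folds (default 5, capped by class sizes).
#' @param seed integer seed.
#' @return data.frame of class `validation_result`: one row per model with
#'   auc, ci_low, ci_high, sensitivity, specificity, panel used, n_case,
#'   n_control.
#' @export
external_validate <- function(X, y, panel,
                              models = c("linear-svm", "logistic", "lda"),
                              folds = 5, seed = 1) {
  y <- as_case_indicator(y)
  if (length(unique(y)) < 2) stop("single-class validation cohort")
  present <- intersect(panel, rownames(X))
  if (length(present) == 0) stop("no panel feature present in the matrix")
  if (length(present) < length(panel)) {
    warning("panel members missing from the matrix: ",
            paste(setdiff(panel, present), collapse = ", "))
  }
  folds <- min(folds, sum(y == 1), sum(y == 0))
  if (folds < 2) stop("too few samples per class for cross-validation")
  Xs <- t(X[present, , drop = FALSE])
  rows <- lapply(models, function(m) {
    cv <- linear_cv_scores(Xs, y, m, folds, stage_seed(seed, m))
    fold_aucs <- vapply(seq_len(folds), function(f) {
      te <- cv$fold == f
      if (length(unique(y[te])) < 2) NA_real_
      else evaluate_roc(cv$scores[te], y[te])$auc
    }, 0)
    fold_aucs <- fold_aucs[!is.na(fold_aucs)]
    ci <- if (length(fold_aucs) >= 2) fold_auc_ci(fold_aucs) else c(NA, NA)
    pooled <- evaluate_roc(cv$scores, y)
    data.frame(model = m, auc = pooled$auc, ci_low = ci[1], ci_high = ci[2],
               sensitivity = pooled$sensitivity,
               specificity = pooled$specificity,
               panel = paste(present, collapse = ","),
               n_case = sum(y == 1), n_control = sum(y == 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_result", class(out))
  out
}

#' Cross-cancer specificity panel
#'
#' Evaluates a fixed biomarker panel across several cohorts. By default the
#' classifier is retrained per cohort under the nested cross-validation
#' scheme; with `mode = "transfer"`, a single model trained on the
#' `reference` cohort is applied unchanged to every cohort.
#'
#' @param cohorts named list; each element a list with `X` (features x
#'   samples) and `y` (labels).
#' @param panel fixed feature panel.
#' @param mode `"retrain"` (default) or `"transfer"`.
#' @param reference cohort name used for training in transfer mode.
#' @param spec,scheme classifier and CV settings for retraining.
#' @param seed integer seed.
#' @return data.frame: cohort, auc (one row per cohort).
#' @export
specificity_panel <- function(cohorts, panel, mode = c("retrain", "transfer"),
                              reference = NULL, spec = classifier_spec(),
                              scheme = cv_scheme(), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "transfer") {
    if (is.null(reference) || !reference %in% names(cohorts)) {
      stop("transfer mode needs a reference cohort name")
    }
    ref <- cohorts[[reference]]
    miss <- setdiff(panel, rownames(ref$X))
    if (length(miss)) stop("reference cohort lacks panel features: ",
                           paste(miss, collapse = ", "))
    fit <- fit_rbf_svm(t(ref$X[panel, , drop = FALSE]), ref$y, spec, scheme,
                       seed = stage_seed(seed, "transfer"))
  }
  aucs <- vapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    miss <- setdiff(panel, rownames(co$X))
    if (length(miss)) stop("cohort '", nm, "' lacks panel features: ",
                           paste(miss, collapse = ", "))
    if (mode == "retrain") {
      run_nested(co$X, co$y, panel = panel, spec = spec, scheme = scheme,
                 seed = stage_seed(seed, nm))$mean_auc
    } else {
      prob <- predict(fit, t(co$X[panel, , drop = FALSE]))
      evaluate_roc(prob, co$y)$auc
    }
  }, 0)
  data.frame(cohort = names(cohorts), auc = unname(aucs),
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set id, description, members...).
#' @return named list of character vectors of member feature ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the actual overlap between the query and the set, with the given
#' universe as population; Benjamini-Hochberg correction across sets. Sets
#' are restricted to the universe; sets empty after restriction are dropped.
#'
#' @param query character vector of feature ids (must lie in the universe).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe background feature ids.
#' @return data.frame of class `enrichment_result`: set_id, overlap,
#'   set_size, query_size, universe_size, p, padj.
#' @export
enrich_hypergeom <- function(query, sets, universe) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query")
  if (length(sets) == 0) stop("empty gene-set collection")
  if (!all(query %in% universe)) {
    stop("query features outside the universe: ",
         paste(setdiff(query, universe), collapse = ", "))
  }
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    K <- length(sets[[id]])
    x <- length(intersect(query, sets[[id]]))
    data.frame(set_id = id, overlap = x, set_size = K, query_size = n,
               universe_size = N,
               p = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  class(out) <- c("enrichment_result", class(out))
  out
}
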