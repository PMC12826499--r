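#' Screen an exosome-RNA cohort for a consensus diagnostic biomarker panel
#'
#' The main fitting function of the package. Given a feature-by-sample count
#' matrix with sample and feature metadata, it
#' \enumerate{
#'   \item filters features by prevalence and reliable expression,
#'   \item normalizes to log2(CPM+1) and harmonizes RNA-type strata,
#'   \item runs negative-binomial Wald differential expression and gates
#'     candidates on adjusted p, |log2FC| and mean abundance,
#'   \item scores candidates by ensemble stability selection (L1-logistic,
#'     random-forest importance, SVM-RFE) over resampling iterations and by
#'     consensus consistency across stratified outer folds,
#'   \item assembles the consensus panel and, if `evaluate = TRUE`, estimates
#'     its performance by leakage-safe nested cross-validation with SMOTE
#'     rebalancing and an RBF-SVM grid search, assesses the calibration of
#'     the pooled out-of-fold probabilities, and fits a final classifier on
#'     the full cohort for [predict.exoscreen()].
#' }
#'
#' @param counts features x samples count matrix.
#' @param samples data.frame with `sample_id` and `group` (`case`/`control`).
#' @param features data.frame with `feature_id` and `rna_type`.
#' @param panel_size consensus panel size (default 3).
#' @param norm_method CPM library-size method (see [normalize_cpm()]).
#' @param filter list of [filter_features()] thresholds.
#' @param gate list of [select_de()] thresholds.
#' @param selector_cfg a [selector_config()].
#' @param spec a [classifier_spec()].
#' @param scheme a [cv_scheme()].
#' @param max_candidates cap on gated candidates carried into selection
#'   (best by adjusted p; default 200).
#' @param evaluate run the nested-CV evaluation/calibration stages
#'   (default TRUE; FALSE stops after panel construction).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return an object of class `exoscreen`; see [print.exoscreen()],
#'   [summary.exoscreen()], [coef.exoscreen()], [predict.exoscreen()] and
#'   [plot.exoscreen()].
#' @export
exoscreen <- function(counts, samples, features, panel_size = 3,
                      norm_method = "total-count",
                      filter = list(min_nonzero_frac = 0.80, min_count = 5,
                                    min_count_frac = 0.10),
                      gate = list(alpha = 0.05, min_abs_log2fc = 1.2,
                                  min_base_mean = 50),
                      selector_cfg = selector_config(),
                      spec = classifier_spec(), scheme = cv_scheme(),
                      max_candidates = 200, evaluate = TRUE, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  stage("input", validate_cohort(counts, samples, features))
  y <- samples$group[match(colnames(counts), samples$sample_id)]

  filtered <- stage("preprocess", do.call(filter_features, c(list(counts), filter)))
  if (nrow(filtered) < 2) stop("stage 'preprocess': too few features retained")
  norm <- stage("preprocess", normalize_cpm(filtered, method = norm_method))
  norm <- stage("preprocess", harmonize_strata(norm, features))

  de <- stage("diffexpr", nb_wald(filtered, samples))
  candidates <- stage("diffexpr", do.call(select_de, c(list(de), gate)))
  gated <- length(candidates)
  if (gated < max(2, panel_size)) {
    message("only ", gated, " features pass the DE gate; ",
            "falling back to the top features by adjusted p")
    candidates <- de$feature_id[order(de$padj, de$p)][
      seq_len(min(max(20, panel_size), nrow(de)))]
  } else if (gated > max_candidates) {
    keep <- de[de$feature_id %in% candidates, ]
    candidates <- keep$feature_id[order(keep$padj)][seq_len(max_candidates)]
  }

  Xc <- norm$values[candidates, , drop = FALSE]
  consistency <- stage("screen",
    fold_consistency(Xc, y, config = selector_cfg, scheme = scheme,
                     seed = stage_seed(seed, "consistency")))
  stability <- stage("screen",
    stability_scores(Xc, y, config = selector_cfg,
                     seed = stage_seed(seed, "stability")))
  panel <- stage("screen",
    consensus_panel(stability, de, panel_size, consistency))
  stability_table <- merge(stability, consistency, by = "feature_id",
                           sort = FALSE)

  evaluation <- calibration <- final_fit <- NULL
  if (evaluate) {
    evaluation <- stage("evaluate",
      run_nested(norm$values, y, panel = panel$feature_id, spec = spec,
                 scheme = scheme, seed = stage_seed(seed, "evaluate")))
    calibration <- stage("calibrate",
      calibration_report(evaluation$oof_prob, y))
    final_fit <- stage("evaluate",
      fit_rbf_svm(t(norm$values[panel$feature_id, , drop = FALSE]), y,
                  spec, scheme, seed = stage_seed(seed, "final")))
  }

  structure(list(call = match.call(),
                 n_case = sum(y == "case"), n_control = sum(y == "control"),
                 n_input_features = nrow(counts),
                 filtered_counts = filtered,
                 normalized = norm,
                 de = de,
                 n_gated = gated,
                 candidates = candidates,
                 stability_table = stability_table,
                 panel = panel,
                 evaluation = evaluation,
                 calibration = calibration,
                 final_fit = final_fit,
                 norm_method = norm_method,
                 seed = seed),
            class = "exoscreen")
}

#' @describeIn exoscreen compact description of the fitted screen.
#' @param x,object an `exoscreen` object.
#' @param ... unused.
#' @method print exoscreen
#' @export
print.exoscreen <- function(x, ...) {
  cat("Exosome-RNA biomarker screen\n")
  cat(sprintf("  cohort: %d case / %d control; %d features (%d retained)\n",
              x$n_case, x$n_control, x$n_input_features,
              nrow(x$filtered_counts)))
  cat(sprintf("  differentially expressed (gate): %d\n", x$n_gated))
  cat(sprintf("  consensus panel (%d): %s\n", nrow(x$panel),
              paste(x$panel$feature_id, collapse = ", ")))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  nested-CV AUC: %.3f (95%% CI %.3f-%.3f)\n",
                x$evaluation$mean_auc, x$evaluation$auc_ci[1],
                x$evaluation$auc_ci[2]))
  }
  invisible(x)
}

#' @describeIn exoscreen panel table plus evaluation and calibration detail.
#' @method summary exoscreen
#' @export
summary.exoscreen <- function(object, ...) {
  print(object)
  cat("\nPanel detail:\n")
  print(as.data.frame(object$panel))
  if (!is.null(object$evaluation)) {
    p <- object$evaluation$pooled
    cat(sprintf("\nPooled out-of-fold: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
                p$sensitivity, p$specificity, p$accuracy))
  }
  if (!is.null(object$calibration)) {
    cal <- object$calibration
    cat(sprintf("Calibration: slope %.3f, Brier %.3f, Hosmer-Lemeshow p %.3f\n",
                cal$slope, cal$brier, cal$hl_p))
  }
  invisible(object)
}

#' @describeIn exoscreen the consensus panel with stability, consistency and
#'   adjusted-p columns.
#' @export
coef.exoscreen <- function(object, ...) {
  as.data.frame(object$panel)
}

#' @describeIn exoscreen calibrated case probabilities for new samples.
#' @param newdata features x samples count matrix containing the panel
#'   features (normalized internally with its own library sizes).
#' @param type `"prob"` for calibrated probabilities, `"class"` for
#'   case/control labels at the pooled Youden threshold.
#' @export
predict.exoscreen <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  if (is.null(object$final_fit)) {
    stop("screen was fitted with evaluate = FALSE; no classifier available")
  }
  miss <- setdiff(object$panel$feature_id, rownames(newdata))
  if (length(miss)) stop("newdata lacks panel features: ",
                         paste(miss, collapse = ", "))
  norm <- normalize_cpm(newdata, method = object$norm_method)
  prob <- predict(object$final_fit,
                  t(norm$values[object$panel$feature_id, , drop = FALSE]))
  if (type == "prob") return(prob)
  thr <- if (!is.null(object$evaluation)) object$evaluation$pooled$threshold else 0.5
  ifelse(prob >= thr, "case", "control")
}

#' @describeIn exoscreen pooled out-of-fold ROC curve.
#' @export
plot.exoscreen <- function(x, ...) {
  if (is.null(x$evaluation)) stop("no evaluation to plot")
  rp <- x$evaluation$pooled$roc_points
  graphics::plot(rp$fpr, rp$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Pooled ROC (AUC = %.3f)",
                                x$evaluation$pooled$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
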