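test_that("SMOTE balances classes and preserves originals verbatim", {
  withr::with_seed(51, {
    X <- matrix(rnorm(60 * 4), ncol = 4,
                dimnames = list(sprintf("s%d", 1:60), paste0("f", 1:4)))
    y <- c(rep(1, 12), rep(0, 48))
  })
  out <- smote_oversample(X, y, k = 5, seed = 3)
  expect_identical(sum(out$y == 1), sum(out$y == 0))
  expect_identical(out$X[1:60, ], X)
  expect_identical(out$synthetic, c(rep(FALSE, 60), rep(TRUE, 36)))
  # arbitrary imbalance ratios balance exactly
  for (n1 in c(3, 7, 20)) {
    yy <- c(rep(1, n1), rep(0, 40))
    oo <- smote_oversample(X[seq_along(yy), ], yy, seed = 4)
    expect_identical(sum(oo$y == 1), sum(oo$y == 0))
  }
})

test_that("SMOTE is a no-op on balanced input and errors on singletons", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_identical(smote_oversample(X, rep(c(1, 0), 5), seed = 1)$X, X)
  expect_error(smote_oversample(X, c(1, rep(0, 9)), seed = 1), "at least 2")
})

test_that("synthetic points with two minority samples lie on their segment", {
  X <- rbind(a = c(0, 0), b = c(2, 4),
             matrix(rnorm(20, 10), ncol = 2,
                    dimnames = list(sprintf("c%d", 1:10), NULL)))
  y <- c(1, 1, rep(0, 10))
  out <- smote_oversample(X, y, k = 1, seed = 5)
  synth <- out$X[out$synthetic, , drop = FALSE]
  # segment between (0,0) and (2,4): x2 = 2 * x1, 0 <= x1 <= 2
  expect_true(all(abs(synth[, 2] - 2 * synth[, 1]) < 1e-12))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 2))
})

test_that("ROC sweep matches hand examples and the tie convention", {
  expect_equal(evaluate_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(evaluate_roc(1:10, rep(c(0, 1), each = 5))$auc, 1.0)
  expect_equal(evaluate_roc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  roc <- evaluate_roc(c(0.2, 0.9, 0.5, 0.7), c(0, 1, 0, 1))$roc_points
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
})

test_that("sweep AUC equals the pairwise-concordance oracle with ties", {
  withr::with_seed(52, {
    for (i in 1:50) {
      n <- sample(4:200, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.4))
      scores <- round(rnorm(n), sample(c(1, 2, Inf), 1))
      expect_equal(evaluate_roc(scores, y)$auc, auc_concordance(scores, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("fold AUC confidence interval matches the t formula", {
  ci <- fold_auc_ci(c(0.90, 0.92, 0.94, 0.96, 0.98))
  expect_equal(unname(ci), c(0.9007, 0.9793), tolerance = 1e-3)
  expect_equal(unname(fold_auc_ci(rep(0.8, 6))), c(0.8, 0.8))
  aucs <- c(0.7, 0.85, 0.9)
  ci2 <- fold_auc_ci(aucs)
  expect_true(ci2[1] <= mean(aucs) && mean(aucs) <= ci2[2])
  expect_error(fold_auc_ci(0.9), "at least 2")
})

test_that("grid search returns the exhaustive inner-CV maximizer", {
  sim <- small_cohort(n_case = 30, n_control = 50, n_features = 40, seed = 53)
  norm <- normalize_cohort(sim)
  y <- labels_of(sim, norm)
  X <- t(norm$values[sim$truth$planted_features, ])
  spec <- classifier_spec(C_grid = c(0.1, 10), gamma_grid = c(0.01, 1),
                          rebalance = "none")
  fit <- fit_rbf_svm(X, y, spec, cv_scheme(inner_folds = 3), seed = 9)

  # oracle: independent loop over the same folds and grid
  y01 <- exoscreen:::as_case_indicator(y)
  fold <- exoscreen:::make_folds(y01, 3, exoscreen:::stage_seed(9, "inner"), TRUE)
  grid <- expand.grid(C = c(0.1, 10), gamma = c(0.01, 1))
  score <- sapply(seq_len(nrow(grid)), function(g) {
    mean(sapply(1:3, function(f) {
      m <- e1071::svm(X[fold != f, ], factor(y01[fold != f], levels = c(0, 1)),
                      kernel = "radial", cost = grid$C[g],
                      gamma = grid$gamma[g], scale = TRUE)
      dv <- as.numeric(attr(predict(m, X[fold == f, ], decision.values = TRUE),
                            "decision.values"))
      a <- auc_concordance(dv, y01[fold == f])
      max(a, 1 - a)
    }))
  })
  expect_identical(c(fit$C, fit$gamma),
                   unlist(grid[which.max(score), ], use.names = FALSE))
  # determinism
  fit2 <- fit_rbf_svm(X, y, spec, cv_scheme(inner_folds = 3), seed = 9)
  expect_identical(c(fit$C, fit$gamma), c(fit2$C, fit2$gamma))
})

test_that("a separable problem reaches perfect training accuracy", {
  withr::with_seed(54, {
    X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c(0, 1), each = 20)
  })
  fit <- fit_rbf_svm(X, y, spec_single(), seed = 1)
  prob <- predict(fit, X)
  expect_identical(as.integer(prob > 0.5), as.integer(y))
})

test_that("outer folds partition samples with balanced stratification", {
  y <- c(rep(1, 23), rep(0, 77))
  fold <- exoscreen:::make_folds(y, 10, seed = 3)
  expect_identical(sort(unique(fold)), 1:10)
  expect_identical(length(fold), 100L)
  case_counts <- tabulate(fold[y == 1], 10)
  expect_lte(max(case_counts) - min(case_counts), 1)
})

test_that("nested CV returns one entry per outer fold with a fixed panel", {
  sim <- small_cohort(seed = 55)
  norm <- normalize_cohort(sim)
  y <- labels_of(sim, norm)
  res <- run_nested(norm$values, y, panel = sim$truth$planted_features,
                    spec = spec_single(), scheme = cv_scheme(10, 3), seed = 4)
  expect_length(res$folds, 10)
  expect_identical(sort(unlist(lapply(res$folds, `[[`, "test_samples"))),
                   sort(colnames(norm$values)))
  expect_true(all(res$fold_aucs >= 0 & res$fold_aucs <= 1))
  expect_true(res$auc_ci[1] <= res$mean_auc && res$mean_auc <= res$auc_ci[2])
  expect_gte(res$mean_auc, 0.9)  # planted Table-1 effects are easy
})

test_that("panel-size sweep emits one row per k and finds the best k", {
  sim <- small_cohort(n_case = 30, n_control = 60, n_features = 100, seed = 56)
  norm <- normalize_cohort(sim)
  y <- labels_of(sim, norm)
  ranked <- rownames(norm$values)[
    order(exoscreen:::welch_t_pvalues(norm$values, y))][1:10]
  sw <- sweep_panel_size(norm$values, y, ranked, spec = spec_single(),
                         scheme = cv_scheme(5, 3), seed = 6)
  expect_identical(sw$table$k, 2:10)
  expect_identical(nrow(sw$table), 9L)
  expect_identical(sw$best_k,
                   sw$table$k[which.max(sw$table$comprehensive_score)])
})

test_that("the best-k rule equals brute force on a precomputed metric table", {
  tab <- data.frame(k = 2:10,
                    comprehensive_score = c(0.81, 0.93, 0.90, 0.94, 0.88,
                                            0.94, 0.85, 0.80, 0.79))
  best <- -Inf; arg <- NA
  for (i in seq_len(nrow(tab))) {
    if (tab$comprehensive_score[i] > best) {
      best <- tab$comprehensive_score[i]; arg <- tab$k[i]
    }
  }
  expect_identical(pick_best_panel(tab), arg)
  expect_identical(pick_best_panel(tab), 5L)
})
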