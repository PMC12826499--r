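# Toy two-class expression matrix: `signal` features shift with the label.
toy_matrix <- function(n_per_class = 60, n_noise = 20, shift = 3, seed = 1,
                       n_signal = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c(1, 0), each = n_per_class)
    X <- matrix(rnorm((n_signal + n_noise) * n), ncol = n)
    rownames(X) <- c(sprintf("sig%d", seq_len(n_signal)),
                     sprintf("noise%02d", seq_len(n_noise)))
    X[seq_len(n_signal), y == 1] <- X[seq_len(n_signal), y == 1] + shift
    colnames(X) <- sprintf("s%d", seq_len(n))
    list(X = X, y = y)
  })
}

test_that("an infinite L1 penalty selects nothing", {
  d <- toy_matrix(seed = 41)
  cfg <- selector_config(lambda_grid = c(1e6, 5e5))
  expect_length(select_l1(d$X, d$y, cfg, seed = 1), 0)
})

test_that("L1 keeps a separating feature among noise across seeds", {
  for (s in 1:10) {
    d <- toy_matrix(n_per_class = 100, n_noise = 50, seed = 100 + s)
    picked <- select_l1(d$X, d$y, seed = s)
    expect_true("sig1" %in% picked)
  }
})

test_that("a duplicated informative feature is still represented", {
  d <- toy_matrix(n_per_class = 100, n_noise = 30, seed = 42)
  X <- rbind(d$X, sig_copy = d$X["sig1", ])
  for (s in 1:5) {
    picked <- select_l1(X, d$y, seed = s)
    expect_true(any(c("sig1", "sig_copy") %in% picked))
  }
})

test_that("random-forest importance ranks a planted effect first", {
  cfg <- selector_config(top_k = 5, trees = 500)
  for (s in 1:5) {
    d <- toy_matrix(n_per_class = 80, n_noise = 15, seed = 200 + s)
    picked <- select_rf(d$X, d$y, cfg, seed = s)
    expect_identical(picked[1], "sig1")
  }
})

test_that("a constant feature never outranks splitting features", {
  d <- toy_matrix(seed = 43)
  X <- rbind(d$X, flat = rep(2, ncol(d$X)))
  fit <- withr::with_seed(7, randomForest::randomForest(
    t(X), factor(d$y), ntree = 300))
  imp <- fit$importance[, "MeanDecreaseGini"]
  expect_identical(unname(imp["flat"]), 0)
  expect_true(all(imp >= 0))
  cfg <- selector_config(top_k = 5)
  expect_false("flat" %in% select_rf(X, d$y, cfg, seed = 1))
})

test_that("top_k covering all features returns everything with a warning", {
  d <- toy_matrix(n_noise = 3, seed = 44)
  cfg <- selector_config(top_k = 20)
  expect_warning(picked <- select_rf(d$X, d$y, cfg, seed = 1), "top_k")
  expect_setequal(picked, rownames(d$X))
  expect_warning(picked2 <- select_svmrfe(d$X, d$y, cfg, seed = 1), "top_k")
  expect_setequal(picked2, rownames(d$X))
})

test_that("SVM-RFE eliminates an uncorrelated feature before a separator", {
  withr::with_seed(45, {
    n <- 80
    y <- rep(c(1, 0), each = n / 2)
    X <- rbind(sep = y * 4 + rnorm(n, sd = 0.2),
               weak = y * 0.5 + rnorm(n),
               junk = rnorm(n))
    colnames(X) <- sprintf("s%d", 1:n)
  })
  cfg <- selector_config(top_k = 1)
  picked <- select_svmrfe(X, y, cfg, seed = 1)
  expect_identical(as.character(picked), "sep")
  ord <- attr(picked, "elimination_order")
  expect_setequal(ord, rownames(X))            # order is a permutation
  expect_lt(which(ord == "junk"), which(ord == "sep"))
})

test_that("SVM-RFE matches an independent greedy elimination oracle", {
  withr::with_seed(46, {
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    X <- matrix(rnorm(4 * n), nrow = 4,
                dimnames = list(paste0("f", 1:4), sprintf("s%d", 1:n)))
    X[1, y == 1] <- X[1, y == 1] + 2
    X[2, y == 1] <- X[2, y == 1] + 1
  })
  cfg <- selector_config(top_k = 2, rfe_step_frac = 0.1)
  picked <- select_svmrfe(X, y, cfg, seed = 1)

  # oracle: direct greedy weight-based elimination with e1071 only
  Xs <- scale(t(X))
  left <- rownames(X)
  while (length(left) > 2) {
    fit <- e1071::svm(Xs[, left, drop = FALSE], factor(y, levels = c(0, 1)),
                      kernel = "linear", cost = 1, scale = FALSE)
    w2 <- (crossprod(fit$SV, fit$coefs)[, 1])^2
    left <- setdiff(left, names(which.min(w2)))
  }
  expect_setequal(as.character(picked), left)
})

test_that("stability scores equal scripted selection frequencies exactly", {
  sim <- small_cohort(n_features = 12, seed = 47)
  X <- log2(sim$counts[1:6, ] + 1)
  feats <- rownames(X)
  counter <- new.env()
  counter$i <- 0L
  mock <- function(X, y, config, seed = NULL) {
    counter$i <- counter$i + 1L
    # f1 always; f2 on even iterations; f3 never
    out <- feats[1]
    if (counter$i %% 2 == 0) out <- c(out, feats[2])
    out
  }
  cfg <- selector_config(n_iterations = 20)
  rep <- stability_scores(X, sim$samples$group, selectors = list(mock = mock),
                          config = cfg, seed = 1)
  expect_identical(rep$stab_mock[rep$feature_id == feats[1]], 1.0)
  expect_identical(rep$stab_mock[rep$feature_id == feats[2]], 0.5)
  expect_identical(rep$stab_mock[rep$feature_id == feats[3]], 0.0)
  expect_true(rep$consensus[rep$feature_id == feats[1]])
  expect_false(rep$consensus[rep$feature_id == feats[3]])
})

test_that("consensus panel ordering breaks ties by adjusted p", {
  report <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    stab_l1 = c(1, 1, 1, 0.2),
    mean_stability = c(0.9, 0.9, 0.8, 0.2),
    consensus = c(TRUE, TRUE, TRUE, FALSE))
  consistency <- data.frame(feature_id = c("a", "b", "c", "d"),
                            consistency_num = c(10L, 10L, 10L, 2L),
                            consistency_den = 10L)
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   padj = c(1e-3, 1e-8, 1e-5, 1e-9))
  panel <- consensus_panel(report, de, size = 2, consistency = consistency)
  # a and b tie on consistency; b wins on padj; c trails on mean stability
  expect_identical(panel$feature_id, c("b", "a"))
  one <- consensus_panel(report, de, size = 1, consistency = consistency)
  expect_identical(one$feature_id, "b")
  expect_warning(all4 <- consensus_panel(report, de, size = 4,
                                         consistency = consistency),
                 "consensus")
  expect_identical(nrow(all4), 3L)
})

test_that("planted biomarkers dominate consistency across outer folds", {
  sim <- small_cohort(n_case = 50, n_control = 120, n_features = 200, seed = 48)
  norm <- normalize_cohort(sim)
  y <- labels_of(sim, norm)
  de <- nb_wald(filter_features(sim$counts), sim$samples)
  cand <- union(sim$truth$planted_features,
                de$feature_id[order(de$padj)][1:10])
  cand <- intersect(cand, rownames(norm$values))
  cons <- fold_consistency(norm$values[cand, ], y, scheme = cv_scheme(),
                           seed = 2)
  hit <- cons$consistency_num[match(sim$truth$planted_features,
                                    cons$feature_id)]
  expect_true(all(hit >= 9))
  expect_true(all(cons$consistency_den == 10))
  expect_true(all(cons$consistency_num <= cons$consistency_den))
})
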