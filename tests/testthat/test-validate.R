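two_gaussian_cohort <- function(n1 = 40, n0 = 40, sep = 4, seed = 71) {
  withr::with_seed(seed, {
    X <- rbind(marker = c(rnorm(n1, sep), rnorm(n0, 0)),
               noise = rnorm(n1 + n0))
    colnames(X) <- sprintf("s%d", seq_len(n1 + n0))
    list(X = X, y = c(rep("case", n1), rep("control", n0)))
  })
}

test_that("well-separated classes give near-perfect LDA validation AUC", {
  co <- two_gaussian_cohort()
  res <- external_validate(co$X, co$y, panel = c("marker", "noise"),
                           models = "lda", seed = 1)
  expect_gte(res$auc, 0.99)
  expect_true(res$ci_low <= res$auc)
})

test_that("logistic coefficients match an independent IRLS solve", {
  X <- cbind(x1 = c(0, 1, 2, 3, 1.5, 2.5), x2 = c(1, 0, 0, 1, 1, 0))
  y <- c(0, 1, 0, 1, 0, 1)
  fit <- glm(y ~ X, family = binomial())
  # independent IRLS loop
  Z <- cbind(1, X)
  beta <- rep(0, 3)
  for (i in 1:50) {
    eta <- Z %*% beta
    mu <- plogis(eta)
    W <- as.numeric(mu * (1 - mu))
    beta <- solve(t(Z) %*% (W * Z), t(Z) %*% (W * eta + (y - mu)))
  }
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-6)
})

test_that("missing panel members are dropped with an explicit warning", {
  co <- two_gaussian_cohort()
  expect_warning(
    res <- external_validate(co$X, co$y, panel = c("marker", "absent_rna"),
                             models = "logistic", seed = 2),
    "absent_rna")
  expect_identical(res$panel, "marker")
  expect_error(external_validate(co$X, co$y, panel = "nothing_here"),
               "no panel feature")
})

test_that("a tiny control arm caps the fold count instead of failing", {
  co <- two_gaussian_cohort(n1 = 30, n0 = 4, seed = 72)
  res <- external_validate(co$X, co$y, panel = "marker",
                           models = c("linear-svm", "logistic", "lda"),
                           folds = 5, seed = 3)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_identical(unique(res$n_control), 4L)
})

test_that("identical class distributions validate at chance level", {
  withr::with_seed(73, {
    X <- matrix(rnorm(2 * 300), nrow = 2,
                dimnames = list(c("a", "b"), sprintf("s%d", 1:300)))
    y <- rep(c("case", "control"), each = 150)
  })
  res <- external_validate(X, y, panel = c("a", "b"), models = "logistic",
                           seed = 4)
  expect_lt(abs(res$auc - 0.5), 0.12)
})

test_that("specificity panel AUC ordering follows planted effect scaling", {
  make_cohort <- function(scale, seed) {
    sim <- simulate_cohort(n_case = 30, n_control = 60, n_features = 40,
                           n_planted = 2, planted_log2fc = c(-3, -3) * scale,
                           seed = seed)
    list(X = log2(sim$counts + 1), y = sim$samples$group,
         panel = sim$truth$planted_features)
  }
  full <- make_cohort(1, 74)
  cohorts <- list(strong = full[c("X", "y")],
                  weak = make_cohort(0.3, 74)[c("X", "y")],
                  null = make_cohort(0, 74)[c("X", "y")])
  sp <- specificity_panel(cohorts, full$panel, spec = spec_single(),
                          scheme = cv_scheme(5, 3), seed = 5)
  expect_identical(nrow(sp), 3L)
  expect_gt(sp$auc[sp$cohort == "strong"], sp$auc[sp$cohort == "weak"])
  expect_gt(sp$auc[sp$cohort == "weak"], sp$auc[sp$cohort == "null"] - 0.05)
  expect_lt(abs(sp$auc[sp$cohort == "null"] - 0.5), 0.2)
})

test_that("transfer mode trains once on the reference cohort", {
  sim <- simulate_cohort(n_case = 30, n_control = 60, n_features = 20,
                         n_planted = 2, planted_log2fc = c(-3, -3), seed = 75)
  cohorts <- list(ref = list(X = log2(sim$counts + 1), y = sim$samples$group))
  sp <- specificity_panel(cohorts, sim$truth$planted_features,
                          mode = "transfer", reference = "ref",
                          spec = spec_single(), seed = 6)
  expect_gt(sp$auc, 0.9)  # in-sample transfer on a strong panel
  expect_error(specificity_panel(cohorts, sim$truth$planted_features,
                                 mode = "transfer"), "reference")
})

test_that("hypergeometric enrichment matches exhaustive pmf summation", {
  # worked example: N=20, K=5, n=5, overlap 3 -> (1050 + 75 + 1) / 15504
  universe <- sprintf("g%02d", 1:20)
  sets <- list(s1 = universe[1:5])
  en <- enrich_hypergeom(c(universe[1:3], universe[10:11]), sets, universe)
  expect_equal(en$p, (1050 + 75 + 1) / 15504, tolerance = 1e-10)

  pmf_sum <- function(N, K, n, x) {
    sum(sapply(x:min(K, n), function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }))
  }
  withr::with_seed(76, {
    for (i in 1:25) {
      N <- sample(5:30, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      uni <- sprintf("u%02d", 1:N)
      set <- sample(uni, K)
      query <- sample(uni, n)
      en <- enrich_hypergeom(query, list(s = set), uni)
      expect_equal(en$p, pmf_sum(N, K, n, en$overlap), tolerance = 1e-12)
    }
  })
})

test_that("degenerate overlaps give p = 1", {
  uni <- letters[1:10]
  # zero overlap: P(X >= 0) = 1
  expect_equal(enrich_hypergeom(letters[1:3],
                                list(s = letters[8:10]), uni)$p[1], 1)
  # set = universe forces overlap = query size
  expect_equal(enrich_hypergeom(letters[1:4], list(s = uni), uni)$p[1], 1)
})

test_that("enrichment padj matches the shared BH utility bit-for-bit", {
  uni <- sprintf("g%02d", 1:30)
  withr::with_seed(77, {
    sets <- lapply(1:8, function(i) sample(uni, sample(3:10, 1)))
    names(sets) <- paste0("s", 1:8)
    en <- enrich_hypergeom(sample(uni, 6), sets, uni)
  })
  expect_identical(en$padj, bh_adjust(en$p))
})

test_that("GMT round trip preserves set membership", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), tmp)
  sets <- read_gmt(tmp)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g2", "g4"))
})
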