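# Shared fixtures and independent oracles, built in code at test time.

# A small cohort that still shows planted-biomarker structure.
small_cohort <- function(seed = 3, n_case = 40, n_control = 100,
                         n_features = 300, n_planted = 3,
                         planted_log2fc = c(-3.80, -3.43, -3.33), ...) {
  simulate_cohort(n_case = n_case, n_control = n_control,
                  n_features = n_features, n_planted = n_planted,
                  planted_log2fc = planted_log2fc, seed = seed, ...)
}

normalize_cohort <- function(sim) {
  harmonize_strata(normalize_cpm(filter_features(sim$counts)), sim$features)
}

labels_of <- function(sim, norm) {
  sim$samples$group[match(colnames(norm$values), sim$samples$sample_id)]
}

# One-point grid: skips the inner tuning loop; used where tuning breadth is
# irrelevant to the property under test.
spec_single <- function() classifier_spec(C_grid = 1, gamma_grid = NA)

# Independent AUC oracle: pairwise concordance with ties counted 1/2.
auc_concordance <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  cmp <- outer(s1, s0, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent Benjamini-Hochberg oracle: brute-force step-up definition,
# padj_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# NB log-likelihood (fixed dispersion phi, size factors s) for one group.
nb_loglik_group <- function(eta, y, s, phi) {
  mu <- s * exp(eta)
  sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}
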