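#' Simulation settings for synthetic exosome-RNA cohorts
#'
#' Defaults emulate a blood-exosome RNA-seq cohort: lognormal baseline means
#' spanning the abundance-filter threshold, gamma-distributed negative-binomial
#' dispersions typical of bulk RNA-seq, multiplicative per-RNA-type batch
#' offsets, and lognormal library sizes. Planted biomarkers receive baselines
#' from a high-abundance lognormal so that, even under strong down-regulation,
#' they clear the mean-abundance screening gate the way real reported
#' biomarkers did.
#'
#' @param baseline_meanlog,baseline_sdlog lognormal parameters for per-feature
#'   baseline means (defaults `log(100)` and `1.5`).
#' @param planted_meanlog,planted_sdlog lognormal parameters for the baseline
#'   means of planted biomarkers (defaults `log(500)` and `0.5`).
#' @param dispersion_mean,dispersion_shape gamma parameters for per-feature
#'   NB dispersions (mean 0.2, shape 2).
#' @param batch_log2_offset named log2 multiplicative offset per RNA-type
#'   stratum (default `c(mRNA = 0.5, lncRNA = 0.5, circRNA = -0.5)`).
#' @param rna_type_prob probabilities of the three RNA types, mirroring the
#'   roughly 31:69 mRNA/lncRNA : circRNA split of blood-exosome catalogues.
#' @param libsize_sdlog lognormal sd of relative library sizes (default 0.3).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(baseline_meanlog = log(100), baseline_sdlog = 1.5,
                       planted_meanlog = log(500), planted_sdlog = 0.5,
                       dispersion_mean = 0.2, dispersion_shape = 2,
                       batch_log2_offset = c(mRNA = 0.5, lncRNA = 0.5, circRNA = -0.5),
                       rna_type_prob = c(mRNA = 0.16, lncRNA = 0.15, circRNA = 0.69),
                       libsize_sdlog = 0.3) {
  stopifnot(baseline_sdlog >= 0, planted_sdlog >= 0,
            dispersion_mean > 0, dispersion_shape > 0, libsize_sdlog >= 0)
  stopifnot(setequal(names(batch_log2_offset), c("mRNA", "lncRNA", "circRNA")))
  structure(list(baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 planted_meanlog = planted_meanlog,
                 planted_sdlog = planted_sdlog,
                 dispersion_mean = dispersion_mean,
                 dispersion_shape = dispersion_shape,
                 batch_log2_offset = batch_log2_offset,
                 rna_type_prob = rna_type_prob,
                 libsize_sdlog = libsize_sdlog),
            class = "sim_config")
}

#' Simulate a synthetic exosome-RNA cohort with planted biomarkers
#'
#' Counts are drawn feature-wise from a negative binomial with
#' `mean = baseline * 2^log2fc[case] * 2^batch_offset * (lib_j / mean(lib))`,
#' where `log2fc` is nonzero only for planted biomarkers in case samples.
#' Defaults mirror the imbalanced cohort the method targets: 111 cases vs 362
#' controls and three planted, strongly down-regulated biomarkers
#' (log2FC -3.80, -3.43, -3.33).
#'
#' @param n_case,n_control cohort sizes (positive integers).
#' @param n_features number of RNA features.
#' @param n_planted number of planted differentially expressed biomarkers.
#' @param planted_log2fc numeric vector of length `n_planted`; effect applied
#'   to case samples only (negative = down-regulated in cases).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param config a [sim_config()].
#' @param cohort cohort label recorded in the sample metadata.
#' @return list with elements `counts` (features x samples integer matrix),
#'   `samples` (data.frame: sample_id, group, cohort), `features` (data.frame:
#'   feature_id, rna_type) and `truth` (generative parameters, class
#'   `sim_truth`).
#' @export
simulate_cohort <- function(n_case = 111, n_control = 362, n_features = 2000,
                            n_planted = 3,
                            planted_log2fc = c(-3.80, -3.43, -3.33),
                            seed = 1, config = sim_config(),
                            cohort = "SCLC") {
  if (n_case < 1 || n_control < 1) stop("cohort sizes must be positive")
  if (n_features < 1) stop("need at least one feature")
  if (n_planted > n_features) stop("n_planted exceeds n_features")
  if (length(planted_log2fc) != n_planted) {
    stop("planted_log2fc must have length n_planted")
  }
  n <- n_case + n_control
  feature_ids <- sprintf("RNA_%05d", seq_len(n_features))
  sample_ids <- sprintf("S%04d", seq_len(n))
  group <- c(rep("case", n_case), rep("control", n_control))

  withr::with_seed(seed, {
    rna_type <- sample(names(config$rna_type_prob), n_features,
                       replace = TRUE, prob = config$rna_type_prob)
    planted_idx <- if (n_planted > 0) sort(sample.int(n_features, n_planted)) else integer(0)
    baseline <- stats::rlnorm(n_features, config$baseline_meanlog, config$baseline_sdlog)
    if (n_planted > 0) {
      baseline[planted_idx] <- stats::rlnorm(n_planted, config$planted_meanlog,
                                             config$planted_sdlog)
    }
    dispersion <- stats::rgamma(n_features, shape = config$dispersion_shape,
                                rate = config$dispersion_shape / config$dispersion_mean)
    dispersion <- pmax(dispersion, 1e-4)
    libsize <- stats::rlnorm(n, 0, config$libsize_sdlog)

    lfc <- numeric(n_features)
    lfc[planted_idx] <- planted_log2fc
    batch <- config$batch_log2_offset[rna_type]
    # features x samples matrix of NB means
    mu <- (baseline * 2^batch) %o% (libsize / mean(libsize))
    if (n_case > 0 && n_planted > 0) {
      mu[planted_idx, group == "case"] <-
        mu[planted_idx, group == "case"] * 2^planted_log2fc
    }
    counts <- matrix(stats::rnbinom(n_features * n, mu = mu,
                                    size = rep(1 / dispersion, n)),
                     nrow = n_features,
                     dimnames = list(feature_ids, sample_ids))
    storage.mode(counts) <- "integer"
  })

  truth <- structure(list(planted_features = feature_ids[planted_idx],
                          planted_log2fc = planted_log2fc,
                          baseline_mean = stats::setNames(baseline, feature_ids),
                          dispersion = stats::setNames(dispersion, feature_ids),
                          batch_offset = config$batch_log2_offset,
                          library_size = stats::setNames(libsize, sample_ids),
                          seed = seed),
                     class = "sim_truth")
  list(counts = counts,
       samples = data.frame(sample_id = sample_ids, group = group,
                            cohort = ifelse(group == "case", cohort, "normal"),
                            stringsAsFactors = FALSE),
       features = data.frame(feature_id = feature_ids, rna_type = rna_type,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Randomly permute case/control labels
#'
#' Used as a negative control: a pipeline without information leakage must
#' perform at chance level on label-permuted data. Group counts are preserved.
#'
#' @param samples sample metadata data.frame with a `group` column.
#' @param seed integer seed.
#' @return the metadata with `group` permuted across samples.
#' @export
permute_labels <- function(samples, seed) {
  if (length(unique(samples$group)) < 2) {
    stop("permute_labels needs both groups present")
  }
  withr::with_seed(seed, samples$group <- sample(samples$group))
  samples
}
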