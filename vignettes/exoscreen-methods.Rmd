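---
title: "Methods: stability-selected exosome RNA biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected exosome RNA biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(exoscreen)
```

`exoscreen` turns a blood-exosome RNA count matrix with heavy class
imbalance into a small consensus biomarker panel with leakage-safe
performance and calibration estimates. This vignette records the model, its
assumptions, the package's numerical conventions, and the design decisions
taken where the procedure was genuinely open — in enough detail that a
reader can audit any number the package produces.

## 1. The data model

The raw input is a nonnegative feature-by-sample count matrix (mRNA, lncRNA
and circRNA features; the `rna_type` column of the feature metadata defines
the batch stratum), sample labels in `{case, control}`, and optionally a
cohort label per sample. Counts are modelled per feature as negative
binomial: for sample $j$ with size factor $s_j$ and feature dispersion
$\phi$,

$$ y_{j} \sim \mathrm{NB}(\mu_j, \phi), \qquad
   \mu_j = s_j\,e^{\eta_{g(j)}}, \qquad
   \mathrm{Var}(y_j) = \mu_j + \phi \mu_j^2, $$

with one log-mean $\eta_g$ per group. The case/control log2 fold change is
$(\eta_{case} - \eta_{ctrl})/\log 2$.

## 2. Preprocessing

* **Filtering** (`filter_features`): keep features non-zero in at least 80%
  of samples *and* with counts ≥ 5 in at least 10% of samples. Both
  fractions and the count threshold are arguments; the defaults are the
  standard dual prevalence/reliability gate for exosome RNA-seq. Filtering
  precedes normalization, and library sizes are computed on the filtered
  matrix.
* **Normalization** (`normalize_cpm`): $\log_2(\mathrm{CPM}+1)$ with the
  column total as effective library size. A `trimmed-mean` option rescales
  totals by TMM factors (edgeR, 30% M-value / 5% A-value trims); the
  total-count default keeps the transform fully deterministic and
  assumption-free. Zero counts map to exactly 0.
* **Stratum harmonization** (`harmonize_strata`): RNA types enter public
  exosome matrices through different quantification routes and show
  multiplicative offsets. Batch here is a *feature-level* stratum — every
  sample shares a feature's stratum — so sample-batch tools (e.g. ComBat)
  do not apply directly. Instead, within each stratum the values are
  standardized against stratum location/scale estimates shrunk toward the
  grand estimates with weight $n_s/(n_s + n_0)$ ($n_s$ = features in the
  stratum, prior $n_0 = 10$ features), then re-expressed on the common
  scale. With hundreds of features per stratum the shrinkage is mild and
  the map is idempotent to well under the data scale; a single stratum is
  provably a no-op, and strata of fewer than 2 features pass through with a
  warning. Harmonized values are no longer guaranteed nonnegative; they are
  an analysis scale, not CPMs.

## 3. Differential expression

Size factors are median-of-ratios (computed over features positive in all
samples, falling back to positive-count medians with a warning) and
rescaled to unit geometric mean so that factors are comparable across runs.
Dispersions are per-feature method-of-moments estimates on size-factor
normalized counts, pooled across the two groups and floored at $10^{-8}$ —
transparent and directly testable against a likelihood oracle, at the cost
of no information sharing across features. Each group's $\eta_g$ is fitted
by Fisher scoring (score $\sum_j (y_j-\mu_j)/(1+\phi\mu_j)$, information
$\sum_j \mu_j/(1+\phi\mu_j)$), vectorized over all features; fold changes
are estimated in natural log and reported in log2. The Wald statistic
divides the contrast by $\sqrt{1/I_{case} + 1/I_{ctrl}}$ with a two-sided
normal p-value; Benjamini–Hochberg adjustment uses `stats::p.adjust`.
A group with an all-zero total receives the continuity total 0.5 and is
flagged; features all-zero in both groups get $p=1$, log2FC $=0$.

The candidate gate applies the strict inequalities *padj < 0.05*,
*|log2FC| > 1.2*, *base mean > 50* (base mean = mean of size-factor
normalized counts over all samples). When fewer than two features pass
(e.g. null data), the screen falls back to the top features by adjusted p
so downstream stages remain defined; when more than `max_candidates`
(default 200) pass, the best by adjusted p are carried forward.

DE runs on the filtered counts with the group contrast only. Encoding the
RNA-type stratum as a covariate of a per-feature model is impossible (it is
constant within a feature), so harmonization is a separate preceding step
on the normalized matrix; this is the one place the package's structure
deliberately re-interprets the motivating procedure, and it is flagged
rather than hidden.

## 4. Ensemble stability selection

Three selectors run on the candidate-restricted normalized matrix:

* **L1-logistic** — `glmnet` with penalty grid $10^{2}\dots10^{-4}$ (50
  log-spaced values), penalty chosen by 5-fold cross-validated deviance;
  selected = non-zero coefficients.
* **Random forest** — 500 trees; selected = top `top_k` (default 20)
  features by mean decrease in Gini impurity.
* **SVM-RFE** — linear SVM (cost 1) on standardized features; repeatedly
  drop the lowest 10% of remaining features by squared weight until `top_k`
  remain; the full elimination order is recorded.

*Stability scores* repeat each selector on `n_iterations = 20` stratified
80% subsamples drawn without replacement; the score is the exact selection
fraction. Whether the original 20 iterations perturbed the data or only the
RNG is not specified anywhere; resampling is this package's documented
choice, because a stability score without data perturbation degenerates to
a determinism check for the deterministic selectors. A feature is
*consensus* when its stability is ≥ 0.5 under **each** selector
(intersection reading of "selected across all algorithms").

*Consistency scores* (x/10) run the three selectors once per outer-fold
training partition and count the folds in which a feature lands in the
three-way intersection. The *consensus panel* orders consensus features by
consistency (desc), mean stability (desc), then adjusted p (asc) and takes
the first `size` (default 3).

## 5. Nested cross-validation

`run_nested` draws stratified outer folds (default 10; per-fold class
counts differ by at most one sample). Within each outer training partition
(90% of samples) and only there:

* when no fixed panel is given, features are screened to the top
  `n_screen = 50` by Welch-t p-value and then passed to the selector
  ensemble; the fold panel is the three-way consensus (falling back to the
  top 3 screened features if the consensus is smaller than 2);
* SMOTE balances classes — synthetic minority points
  $x + u(\mathrm{nn}_k(x) - x)$, $u\sim U(0,1)$, $k = 5$ neighbors —
  inside each inner training split and for the final refit, never touching
  validation or test data;
* an RBF-SVM grid search ($C \in \{0.1, 1, 10, 100\}$,
  $\gamma \in \{10^{-3}, 10^{-2}, 10^{-1}, 1/d\}$) maximizes mean
  inner-fold (default 5) AUC; a single-point grid skips the inner loop;
* a Platt-style sigmoid mapping margins to probabilities is fitted by
  logistic regression on the original training samples, and the
  sensitivity/specificity operating point is the Youden-optimal threshold
  on the *training* probabilities, applied unchanged to the held-out 10%.
  Nothing in the motivating procedure states its threshold rule; Youden on
  training is this package's convention because any test-set rule would
  leak.

The ROC sweep moves tied scores together; the trapezoidal AUC therefore
equals the pairwise concordance probability with ties counted ½ (asserted
exactly in the tests). Fold AUCs are summarized as
$\bar a \pm t_{n-1,0.975}\,s/\sqrt n$ clipped to $[0,1]$. The panel-size
sweep (2–10) scores each size by the unweighted mean of AUC, sensitivity
and specificity — the "comprehensive score"; the motivating work plots such
a score without a formula, so the mean is the documented, configurable
choice.

## 6. Calibration

On pooled out-of-fold probabilities: Brier score (mean squared error),
calibration slope/intercept (logistic regression of outcomes on logit
probabilities, clipped to $[10^{-6}, 1-10^{-6}]$; separation is flagged),
and the Hosmer–Lemeshow test with equal-frequency risk deciles (boundary
ties to the lower bin), bins of expected event count < 1 merged into a
neighbor, statistic $\sum (O-E)^2 / (E(1-E/n_b))$, and df = bins − 2 — the
in-sample convention the test was derived for; `df = "external"` (df =
bins) is available for probabilities not fitted on the scored data. Fewer
than 3 usable bins is an error in `hosmer_lemeshow` and an NA-with-warning
in `calibration_report`: on fully separated probability distributions the
test is undefined, which the default synthetic conditions do reach.

## 7. External validation, specificity, enrichment

`external_validate` scores a fixed panel on an independent cohort with
linear models only (linear SVM, logistic regression, LDA) under stratified
k-fold CV, capping folds so every fold keeps both classes — chosen for
validation cohorts as small as 79 vs 7, where a flexible model would
overfit and a fixed 5-fold split would strand the control arm. Panel
members missing from the validation platform are dropped with an explicit
warning and the reduced panel is recorded, mirroring the common
two-of-three-marker situation. `specificity_panel` evaluates a fixed panel
across cohorts, retraining per cohort by default; whether a cross-cancer
comparison should transfer the original model or retrain is genuinely
ambiguous, so a `transfer` mode (train once on a named reference cohort)
is also provided. `enrich_hypergeom` is the upper-tail hypergeometric test
$P(X \ge x)$ against a user-supplied GMT collection restricted to a
configurable universe (default: all features surviving preprocessing),
with BH correction across sets.

## 8. The synthetic cohort generator

`simulate_cohort` emulates the structure the pipeline must survive:

| aspect | default | rationale |
|---|---|---|
| cohort | 111 cases / 362 controls | the imbalance regime the method targets |
| features | 2,000 | enough for realistic multiplicity at desk scale |
| baselines | lognormal(log 100, 1.5) | spans the abundance gate (>50) from both sides |
| planted baselines | lognormal(log 500, 0.5) | reported biomarkers passed the abundance gate despite ~12-fold down-regulation, so planted features must be abundant; drawing them from the global pool would flunk them on the gate ~1/3 of the time by construction |
| planted log2FC | −3.80, −3.43, −3.33 | the reported panel's effect sizes, case-only, down-regulated |
| dispersion | gamma, mean 0.2, shape 2 | typical bulk overdispersion; makes Poisson approximations visibly fail |
| batch | mRNA/lncRNA $2^{+0.5}$, circRNA $2^{-0.5}$ | a stratum structure harmonization can provably remove |
| library sizes | lognormal, sdlog 0.3 | realistic depth variation |
| RNA-type mix | 0.16 / 0.15 / 0.69 | the ~31:69 mRNA+lncRNA : circRNA split of blood-exosome catalogues |

Counts are integer NB draws; public "normalized count" matrices do not
document whether they are integral, so the generator emits integers (the
assumption the NB Wald stage needs) and says so here. A single integer seed
makes the cohort bit-reproducible; every stochastic function in the package
takes an explicit seed and derives stage-specific sub-seeds from it.

What the generator does **not** emulate: read-level data, circRNA
back-splice structure, exosome isolation noise, feature-feature
correlation beyond the shared library factor, outlier samples, or
biological heterogeneity within the case group. Passing tests on this
surface demonstrates algorithmic correctness and leakage-safety — not that
real cohorts reach any particular AUC. Indeed, at the planted effect sizes
the synthetic classes separate completely (AUC 1.0), a cleaner regime than
any real cohort; the leakage guard (permuted labels must score ≈ 0.5) is
the meaningful negative control.

## 9. Problem sizes, budgets and determinism

The shipped tests exercise the full default cohort (111/362 × 2,000
features) for generator, DE and screening properties, with 20-replicate
batteries for planted-panel recovery, the permuted-label leakage guard and
DE null behaviour; classifier-heavy properties (panel sweeps, SMOTE
contracts, manifest determinism) run on reduced cohorts (25–40 cases,
60–120 controls, 80–500 features) with 4–5 outer folds, sizes chosen so
the whole suite runs in minutes on one CPU while every property is still
tested at a scale where it can fail. The leakage and determinism batteries
use a single-point SVM grid: tuning breadth affects neither null AUC nor
reproducibility, only compute.

`run_pipeline` executes the stages in order, persists every artifact with
atomic write-then-rename semantics, and emits a manifest with the
configuration snapshot and MD5 checksums; identical configuration and seed
reproduce identical checksums. A configuration without a seed is rejected
before execution.

## 10. Known limitations

* Per-feature method-of-moments dispersions are noisier than shrinkage
  estimators; at small n the Wald test is correspondingly approximate
  (no Cook's-distance outlier handling, no fold-change shrinkage).
* Candidate gating for the consistency score happens once on the full
  cohort (as in the motivating workflow) before the fold-wise re-selection;
  the fully fold-internal path (`run_nested` with automatic selection) is
  the one the leakage guard certifies.
* The Hosmer–Lemeshow test is undefined under complete separation and
  reported as NA there.
* SMOTE interpolates in the normalized expression space; with very small
  minority classes (< 2 samples) it refuses to run.
* Consistency and stability scores are exact rational counts, but the
  selectors themselves are stochastic; scores are reproducible only under
  the recorded seeds.
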