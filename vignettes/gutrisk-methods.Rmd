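---
title: "Methods: latent-variable depression risk estimation from gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-variable depression risk estimation from gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutrisk)
```

## The problem and the modelling chain

Depression is associated with alterations of the gut microbial community
(dysbiosis), but single-taxon markers are weak and unstable. `gutrisk`
implements a sex-stratified modelling chain that aggregates several weakly
informative genera into one or two latent "dysbiosis axes" and scores new
samples against them:

1. **Cohort screening** — exclusion rules (nationality, pregnancy/lactation,
   enema stool, recent antibiotics, questionnaire non-response, applied in
   that order with first-match attribution), then group assignment: cases
   are self-reported physician-diagnosed depression; controls have no
   current illness and a CES-D score strictly below 16 (scores of 16 or
   more flag suspicion of depression, so such participants are neither
   case nor control).
2. **Coverage-based rarefaction** — each sample is subsampled to the
   smallest depth at which the expected rarefaction slope (new genera per
   additional read) drops to `0.002259329`, the conventional coverage
   criterion; samples that never reach it are excluded and logged.
3. **Dirichlet Monte-Carlo CLR** — counts are not proportions; per sample
   we draw `n_instances` compositions from `Dirichlet(counts + 0.5)` and
   centre their logs (CLR), so downstream statistics propagate counting
   uncertainty instead of trusting a single pseudo-count transform.
4. **Effect-size screening** — for every genus, a standardized effect size:
   the median between-group CLR difference over random case-control
   pairings divided by the larger within-group dispersion, medianed over
   Monte-Carlo instances. Genera with effect strictly above `0.2` (below
   `-0.2`) are labelled more (less) abundant in the case group. Expected
   Wilcoxon rank-sum p-values with Benjamini-Hochberg correction across
   genera are reported alongside, but selection is effect-size based —
   deliberately independent of sample size.
5. **Structural equation model** — more-abundant taxa load on latent `lv1`
   (expected positive path to depression), less-abundant taxa on `lv2`
   (expected negative path). The outcome is a probit-thresholded latent
   response. The model is estimated by diagonally weighted least squares
   (DWLS) on a mixed correlation matrix (Pearson among CLR variables,
   polyserial against the binary outcome) and pruned by greedy backward
   elimination until fit is acceptable (GFI ≥ 0.90, RMSEA ≤ 0.08) and the
   largest absolute structural path is maximal. A latent left with a
   single indicator is demoted to a direct observed predictor.
6. **Blinded factor scores** — only the measurement part of the fitted SEM
   (loadings, residual variances, standardization constants) is retained;
   empirical-Bayes posterior means give each sample's latent score with no
   outcome information. Scores are bit-identical whether or not an outcome
   column is present.
7. **Risk model** — logistic regression of case status on the latent
   score(s) (and any direct-predictor z-scores), trained with SMOTE
   balancing of the minority class, evaluated by stratified 10-fold
   cross-validation with held-out predictions pooled into a single ROC.

## Estimation details

**Moments and weights.** With standardized indicators, the model-implied
correlations are `corr(x_i, x_j) = λ_i λ_j ψ_kl` (latent variances fixed
at 1, latent correlations `ψ` free), `corr(x_j, y*) = λ_j (Ψγ + Φβ)_k`,
and free covariances between latents and direct predictors. The DWLS
discrepancy is `F(θ) = Σ_k (s_k − σ_k(θ))² / w_k`, where `w_k` is the
delta-method asymptotic variance of the root-n-scaled sample moment:
`(1 − r²)²` for Pearson entries and `n·var(ρ̂)` for polyserial entries.
Then `χ² = (n − 1) F_min` is a conventional test statistic,
`GFI = 1 − F_min/F_0` with `F_0 = Σ s_k²/w_k`,
`AGFI = 1 − (m/df)(1 − GFI)`, and
`RMSEA = sqrt(max(χ² − df, 0) / (df (n − 1)))`.

**Polyserial correlation.** Two-step: the threshold is fixed at its
univariate probit estimate `τ = Φ⁻¹(1 − prevalence)`, and
`ρ = r·sqrt(p(1−p))/φ(τ)`, clipped to (−0.999, 0.999). This is standard
two-step categorical-SEM practice; jointly estimating the threshold
changes little at these prevalences and costs stability.

**Optimization.** BFGS from a spectral start (first eigenvector of each
latent's indicator correlation block). Soft penalties keep the solution
admissible: `|λ| ≤ 1`, latent/direct correlation matrix positive
semi-definite, and explained variance of the standardized latent response
at most 1 (structural residual variance non-negative). Sign indeterminacy
is resolved by making each latent's largest-|λ| loading positive. Note
that individual standardized paths can still exceed 1 in magnitude when
two correlated latents act as mutual suppressors — the admissibility
constraint bounds their joint explained variance, not each coefficient.

**Degenerate models.** A model reduced to a single direct predictor is
saturated (`df = 0`); the pruner permits it (it is the legitimate endpoint
of the demotion rule) and reports `GFI = 1`, `RMSEA = 0`. Everywhere else
`df ≥ 1` is enforced.

**Greedy search.** Exhaustive subset search is exponential; greedy
backward elimination tries every single-indicator removal (plus demotions)
per step and keeps the best feasible move. The full trace is returned so
the path can be audited. The pipeline feeds the search the
`max_candidates = 6` strongest taxa per direction — the search cost grows
quadratically with candidates and weak candidates are removed first
anyway.

**SMOTE scoping.** Synthetic minority samples are generated inside each
training partition only. Augmenting before the fold split would place
interpolants of held-out samples in the training set and bias the CV AUC
upward; the leakage-free scoping is the defensible default.

**Logistic fit.** Iteratively reweighted least squares with a tiny ridge
(`1e-6`) on the slopes, so separable data (easy to produce after SMOTE on
a strong latent score) still give finite coefficients with the correct
score ordering.

## The synthetic cohort generator

The study data are private, so the package ships a generator that
reproduces the *statistical structure* the analysis assumes, and the test
suite runs against it:

* **Design.** Two sex strata with case:control 33:246 (male) and 35:384
  (female); read depths uniform on 2,283–34,368; age, BMI and CES-D drawn
  from truncated normals whose means and SDs mirror a typical demographic
  table for such a cohort (cases CES-D ≈ 25 ± 13; controls truncated
  strictly below 16).
* **Counts.** A deterministic log-normal quantile base profile
  (`sdlog = 2`; `genus_001` is the most abundant of 150 genera, so planted
  taxa map to known abundance ranks), Dirichlet-multinomial closure with
  concentration 200 — moderate biological overdispersion producing
  realistic zero fractions (~50–60 % at genus level).
* **Planted signal.** Case samples receive additive log-abundance shifts
  before closure. Closure makes the realized CLR effect smaller than the
  planted shift, so realized effects are always measured with the
  effect-size estimator, never assumed. The default planted strength
  (±0.4 on abundant ranks) realizes effects around |0.4–1.0|: strong
  enough that the ≥ 4/5 recovery property holds across seeds despite the
  estimator's intrinsic null spread (~0.15 SD with 35 cases — a property
  of medians of 35 values, not of the generator).

What the generator does **not** emulate: phylogenetic correlation between
genera, within-group covariance structure beyond the shared composition
(taxa co-vary only through case status and closure), longitudinal or
batch effects, and covariate-microbiome dependence. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under the assumed model, not clinical performance on real cohorts.

## Numerical choices and problem sizes

* Rarefaction slope uses log-gamma arithmetic; the coverage depth is found
  by binary search (the slope is non-increasing in depth). The slope is
  the discrete forward difference of expected richness; an analytic
  derivative differs by `O(1/N)`, inside the enumeration oracle's
  tolerance.
* Dirichlet prior mass 0.5 per taxon; 128 Monte-Carlo instances by
  default (64 in the heavier integration tests).
* PERMANOVA/PERMDISP use the add-one permutation estimator
  `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, which never returns 0; PERMDISP
  measures distances to group *centroids* in the principal-coordinate
  embedding (a closed-form test surface; the common alternative default is
  spatial medians).
* NMDS: 20 random starts plus a metric start, isotonic regression, best
  Kruskal stress-1 returned.
* Test problem sizes were chosen to estimate each property with
  comfortable margins at small cost: 200+ null simulations for
  permutation-test calibration, 50 for classifier null calibration,
  20 seeds × n = 2000 for SEM parameter recovery, and a 35:350 single
  stratum for the end-to-end integration run.

## Known limitations

* The structural path from a latent to the probit outcome is mildly
  attenuated (≈ factor `1/sqrt(1 + γ²)`) relative to a generator that
  leaves the latent response unstandardized; recovery experiments bound
  the bias well inside ±0.1 for paths near 0.5.
* DWLS here uses a diagonal weight matrix; full-weight WLS and robust
  mean-and-variance-adjusted χ² variants are out of scope, as are
  standard errors on loadings.
* The greedy pruner is not guaranteed to find the global optimum of the
  path-maximization criterion; the trace makes its decisions auditable.
* With heavily imbalanced strata and ~150 genera, some null taxa will
  always cross the |0.2| effect threshold (the estimator's null spread at
  33–35 cases); the SEM pruning stage is what ultimately discards them.
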