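---
title: "Methods: sex- and severity-stratified steroid panel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex- and severity-stratified steroid panel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidpanel)
library(dplyr)
```

steroidpanel implements a complete statistical pipeline for a nine-analyte
plasma steroid hormone panel (cortisone, cortisol, corticosterone,
11-deoxycortisol, aldosterone, androstenedione, testosterone,
17α-hydroxyprogesterone, progesterone; all ng/mL) measured in cohorts
stratified by sex and by ME/CFS disease severity — healthy controls (HC),
mild/moderate patients (ME/CFSmm) and severely affected patients (ME/CFSsa).
This vignette explains the models and procedures, the tunable parameters and
their defaults, the synthetic cohort generator the test-suite rests on, the
numerical choices, and the limits of what the tests demonstrate.

## The synthetic cohort generator

Per-subject steroid data of this kind are typically not deposited, so the
package ships a generator whose draws have the statistical structure the
analysis stages assume. Each (sex, group) block is simulated independently:

1. **Marginals.** Cohort summaries report median and IQR per analyte. We fit
   a log-normal to each triple: `mu_log = log(median)` and
   `sigma_log = log(q75/q25) / (2 qnorm(0.75))`. Concentrations are strictly
   positive and right-skewed (progesterone IQRs span more than a decade in
   some groups), which makes the log-normal the natural two-parameter
   choice. The fit reproduces the median and the quartile *ratio* exactly;
   the individual quartiles are reproduced exactly only when the printed IQR
   is geometrically symmetric around the median (`q25 * q75 = median^2`).
   Several reference rows are asymmetric, so the generator's quartiles sit
   at the geometric symmetrization `median * (q25/q75)^(±1/2)` — a
   deliberate property of the two-parameter family, not a sampling error.
2. **Dependence.** A Gaussian copula: a latent multivariate normal with
   correlation `r = 2 sin(pi rho_s / 6)` applied elementwise to the target
   Spearman matrix, each coordinate then pushed through its log-normal
   quantile. For a jointly feasible target this recovers the Spearman
   matrix to simulation accuracy. The default targets carry the published
   per-group significant coefficients with zeros elsewhere; those matrices
   are *not* jointly positive semi-definite (minimum eigenvalues down to
   about −0.38), so the copula matrix is repaired by eigenvalue clipping at
   `1e-8` and re-normalization to unit diagonal. The repair shrinks the
   largest entries of infeasible targets noticeably (a 0.89 pair can land
   near 0.73); realized correlations of the default cohort are therefore the
   repaired ones. Feasible targets round-trip within ±0.02 at n = 10⁵.
3. **Missingness.** Aldosterone is the one analyte with missing data in the
   motivating study; the amount and mechanism are unreported. We default to
   MCAR at rate 0.2 per subject, configurable per analyte.
4. **Seeding.** One integer seed; each block derives a deterministic
   substream from a hash of `(sex, group)`, so adding or removing a block
   never perturbs the others, and the whole cohort is bitwise reproducible.

Default group sizes are the study's: female 12/20/24 and male 17/8/6 for
HC/ME/CFSmm/ME/CFSsa. What the generator does **not** emulate: assay noise
and limits of quantification, batch effects, covariates (age, BMI,
menstrual-cycle phase), and informative missingness. Tests passing on this
generator show the *statistical machinery* is correct and calibrated; they
cannot certify conclusions about real cohorts.

## Univariate stage

For each analyte within a sex stratum, the three severity groups are
compared with one-way ANOVA when every group passes a Shapiro–Wilk
normality check at α = 0.05, and with the Kruskal–Wallis rank test
otherwise. The criterion behind "ANOVA when normal" had to be fixed by us:
Shapiro–Wilk per group at 0.05 is the conventional reading, and the gate is
deterministic. Kruskal–Wallis uses mid-ranks with tie correction; when all
values are identical the tie-correction denominator vanishes and we return
H = 0, p = 1 with a warning.

The nine three-group p values per stratum are adjusted by both
Benjamini–Hochberg (BH) and Benjamini–Yekutieli (BY) step-up procedures at
the 5% FDR level (`stats::p.adjust`); BY multiplies by the harmonic factor
`c(m)` and is valid under arbitrary dependence, so `p ≤ BH ≤ BY` always.
Pairwise two-group comparisons use the two-sided Mann–Whitney test (exact
enumeration when both groups have ≤ 8 tie-free values, tie-corrected normal
approximation with continuity correction otherwise). The adjustment family
for the pairwise tests is a genuine modelling choice: the default is the
within-stratum family of 27 tests (9 analytes × 3 pairs), with
`pairwise_family = "per_pair"` providing the alternative 9-test families.
Strata are adjusted separately by default, matching the per-sex presentation
of such analyses.

## Correlation stage

Per-group association is summarized by mid-rank Spearman matrices on
pairwise-complete observations, annotated with the conventional strength
taxonomy (very high ≥ 0.9 > high ≥ 0.7 > moderate ≥ 0.5 > low ≥ 0.3 >
little-or-none; boundaries belong to the upper bin, sign reported
separately).

Equality of two correlation matrices is tested with Jennrich's statistic:
with pooled `Rbar = (n1 R1 + n2 R2)/(n1 + n2)`, `c = n1 n2/(n1 + n2)`,
`Z = sqrt(c) Rbar⁻¹ (R1 − R2)` and `S_ij = δ_ij + rbar_ij rbar^ij`,

```
J = tr(Z²)/2 − diag(Z)' S⁻¹ diag(Z),   df = p(p−1)/2.
```

The asymptotic χ² null is derived for Pearson matrices under multivariate
normality; applied to Spearman matrices it is only a diagnostic, so the
test is wrapped in a permutation null: subjects are shuffled between the
two groups holding group sizes fixed, both Spearman matrices and J are
recomputed B times (default B = 1000), and
`p = (1 + #{J_perm ≥ J_obs})/(B + 1)`. This estimator is never 0 and is
exact under exchangeability. Raw subject rows are permuted — the plain
reading of permuting "the original data set". The upper-tail direction is
the conventional one for an equality test (an extreme observed J is
evidence against equality). Design details: the scalar n entering the
statistic is the group's subject count (per-pair complete counts vary under
missingness; the permutation null absorbs the approximation); near-singular
pooled matrices get a `1e-8` diagonal ridge; a permutation that still fails
is redrawn, and more than 10% redraws aborts. The aldosterone-excluded
variant (df 28 instead of 36) never touches any aldosterone value.

Calibration, verified in the test-suite: under a common 4-variate normal at
n = 200/group the statistic's mean is ≈ df = 6 and the χ²₆ 0.95-quantile
rejection rate ≈ 5% (2,000 replicates); the permutation test holds its size
on same-copula groups at the study's own group sizes (n = 28/24, B = 199,
500 replicates) and has power ≥ 0.8 against a 0.8-block versus independent
structure at n = 50/group (200 replicates).

## Classification stage

Disease status (HC versus pooled ME/CFS) is predicted from the nine
analytes with four classifiers: LDA, a bootstrap forest, and PLS-DA with
one and two latent components (more components overfit at these sample
sizes). Per-subject probabilities are estimated honestly:

- **LDA / PLS-DA**: leave-one-out — the model *and* the preprocessing
  (log-transform then autoscale; the panel spans three orders of magnitude)
  are re-estimated inside every fold. Subjects with any missing predictor
  are dropped (count reported); no imputation.
- **Forest**: out-of-bag — each subject's probability is the ME/CFS vote
  fraction among trees whose bootstrap sample excluded it. Default 10,000
  trees, `sqrt(p)` candidate features per split, unlimited depth, raw
  concentrations (trees are scale-invariant). "Bootstrap probability" could
  also mean full-ensemble voting on the training data, but that is
  degenerate (resubstitution); OOB is the only honest reading.
- **PLS-DA internals**: NIPALS on autoscaled predictors against a ±1 class
  code — the first weight vector is proportional to `X'y`, scores are
  orthogonal across components. How latent scores become probabilities is
  unstated in this family of analyses; we calibrate with a logistic
  regression of the class on the training-fold scores, which is monotone,
  bounded, and entirely fold-contained.

Probabilities feed a ROC curve (thresholds at every distinct probability;
trapezoid AUC = tie-adjusted Mann–Whitney concordance, an identity the
tests check to 1e-12). The operating point is the curve point closest to
(0, 1) in the (1 − Sp, Se) plane; exact ties are broken toward higher
sensitivity, then higher specificity. Accuracy is reported through the
identity `accuracy · n = Se · n_cases + Sp · n_controls`, which then holds
exactly. Under permuted labels every classifier's mean AUC is ≈ 0.5 on a
balanced 50-per-class design (leakage control, 200 replicates in the
test-suite, forest run at 500 trees — AUC centering does not depend on
ensemble size, and this keeps the suite fast; user-facing defaults keep
10,000 trees). One subtlety worth knowing: honest LOO/OOB null AUC sits
systematically *below* 0.5 — each fold trains with one subject of the
held-out subject's class removed, a pessimism of order 1/n that grows with
class imbalance (at the study's own 11-control stratum it reaches ≈ 0.06).
That bias is conservative and must not be mistaken for miscalibration;
leakage would push the null AUC above 0.55, and the suite checks both
directions, including at the study's own imbalanced sizes.

## Unsupervised stage

PCA operates on the log-transformed, autoscaled complete-case panel by
default (components ordered by decreasing variance; sign fixed so each
loading vector's largest-magnitude entry is positive; equals the SVD of the
preprocessed matrix). Unscaled covariance PCA is available too: on raw
ng/mL data cortisol dominates the variance and the first components capture
almost everything — the two modes answer different questions and both are
reported by the acceptance script. Hierarchical clustering uses Euclidean
distance with complete linkage by default (average and Ward available) on
the same per-analyte z-scores of logged concentrations that standard
metabolomics heatmaps use; subject and analyte trees are built, the subject
tree can be cut into a requested number of groups, and the
dendrogram-ordered matrix exports deterministically to CSV (plus a PNG
heatmap when pheatmap is installed, and Newick text for the trees).

## Numerical and testing choices

- Simulation sizes in the test-suite are chosen to keep the full run in a
  few minutes while leaving comfortable Monte-Carlo margins: 10,000-draw
  marginal round-trips (2% tolerance), 2,000-replicate χ² calibration,
  500 × B = 199 permutation size check, 200-replicate power and leakage
  nulls, 500-instance exact identities.
- All stochastic stages take explicit integer seeds and restore the
  caller's RNG state; two runs of the full pipeline with the same
  configuration produce byte-identical output bundles.
- Degenerate inputs have defined behaviour: zero-spread marginals are point
  masses; constant groups fail the normality gate; all-tied rank tests
  return p = 1 with a warning; zero-variance predictors are dropped per
  fold with a warning; correlation pairs with fewer than 4 complete
  observations are flagged unusable and refuse to enter the Jennrich
  statistic.

## Known limitations

- The default dependence targets are infeasible as a joint matrix (see
  above); realized correlations are the PSD-repaired ones.
- The permutation test's exchangeability null assumes the two groups differ
  only in dependence structure; strong marginal differences between groups
  are not what it tests.
- MCAR aldosterone missingness is an assumption; the analysis stages drop
  incomplete subjects rather than impute.
- With 6-subject groups (male ME/CFSsa) Spearman matrices are extremely
  noisy; the machinery runs, but no amount of FDR control rescues that
  sample size.

```{r session}
sessionInfo()
```
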