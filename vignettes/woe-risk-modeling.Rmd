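---
title: "Weight-of-Evidence risk modeling for post-concussion MSK injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-of-Evidence risk modeling for post-concussion MSK injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mskrisk)
```

## The modeling problem

Cohorts of concussed athletes tracked for a subsequent musculoskeletal
(MSK) injury are small by machine-learning standards (a few hundred
subjects), wide (a hundred or more variables spanning demographics,
injury characteristics and repeated clinical batteries at the
Baseline, Acute, Asymptomatic and Return-to-Participation timepoints),
heavily incomplete (a third of all entries can be missing), and mix
continuous scores with categorical and binary codings whose
relationships with risk are often threshold-shaped rather than linear.
`mskrisk` addresses this with a scorecard-style pipeline: supervised
discretization with Weight-of-Evidence (WoE) coding, sparse variable
selection on the coded features, a ridge-stabilized final fit, and
closed-form attribution.

## The model

Write $Y \in \{0, 1\}$ for the injury outcome and $x_1, \dots, x_P$
for the predictors.  Each variable is partitioned into bins; bin $b$
of variable $i$ receives the smoothed Weight of Evidence

$$\mathrm{WoE}_{ib} = \ln\frac{(e_{ib} + s) / (E + sB_i)}
{(\bar e_{ib} + s) / (\bar E + sB_i)},$$

where $e_{ib}$ and $\bar e_{ib}$ are the bin's event and non-event
counts, $E$ and $\bar E$ the training totals, $B_i$ the number of bins
and $s$ a pseudo-count.  Positive values are evidence for injury.  The
variable's Information Value is
$\mathrm{IV}_i = \sum_b (p_{ib} - \bar p_{ib})\,\mathrm{WoE}_{ib}$
with the same smoothed proportions; it is non-negative and measures
discriminatory power after binning.  The risk model is linear on the
coded scale:

$$\log\frac{P(Y=1\mid x)}{P(Y=0\mid x)}
 \approx w_0 + \sum_{i=1}^{P} w_i\,\mathrm{WoE}_i(x_i).$$

If every variable contributed independent evidence, setting $w_i = 1$
and $w_0$ to the log prior odds would recover the naive Bayes
posterior log-odds on the binned data; the fitted weights temper that
independence assumption, and the test suite checks the naive-Bayes
limit exactly.  Missing values map to a dedicated bin per variable, so
prediction never requires imputation and missingness can itself be
informative.

## Fitting procedure

1. **Binning** (`fit_binning`, `fit_all_binnings`).  Continuous
   variables are pre-binned at training quantiles (default 20 cells);
   contiguous cells are then merged by exact dynamic programming to
   the partition maximizing total IV, for each candidate bin count up
   to the maximum; categorical levels are first ordered by event rate
   (ties alphabetically) and merged with the same machinery.  Fitting
   sees training data only.
2. **Selection** (`l1_path`).  The WoE-coded design enters an
   L1-penalized logistic regression over 100 log-spaced penalties from
   the analytic all-zero threshold $\lambda_{\max} = \max_j |x_j^\top
   (y - \bar y)|/n$ down to $10^{-4}\lambda_{\max}$ (glmnet, no
   re-standardization: WoE features already live on the log-odds
   scale).  Coefficients below $10^{-8}$ snap to exactly zero.
3. **Model choice** (`select_and_refit`).  Each path point is scored
   by $\mathrm{AICc} = 2\,\mathrm{NLL} + 2k + 2k(k+1)/(n-k-1)$ with
   $k$ = nonzero coefficients + 1, the NLL taken from the penalized
   fit itself; ties break toward fewer variables, then the larger
   penalty.  The winning support is refit by L2-penalized logistic
   regression (exact BFGS on the penalized likelihood).
4. **Explanation** (`shap_values`, `rank_variables`).  For a linear
   model the SHAP contribution is closed-form,
   $\phi_i(x) = w_i(\mathrm{WoE}_i(x_i) - \overline{\mathrm{WoE}_i})$,
   with the mean taken over a reference sample (the training set, by
   convention); contributions sum to the log-odds deviation from the
   reference mean to within $10^{-9}$, and variables are ranked by
   mean absolute contribution.

## Tunable parameters

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `min_bin_fraction` | 0.05 | fraction of non-missing training rows | bins below ~5% carry unstable rates |
| `max_bins` | 10 | count | scorecard practice; DP cost is negligible |
| `pre_bins` | 20 | count | edge resolution of ~5% quantile steps |
| `smoothing` | 0.5 | pseudo-count per class per bin | keeps WoE finite in one-class bins |
| `complexity_penalty` | `NULL` (auto) | $\chi^2_1$ quantile | see below |
| `l2_strength` | 1.0 | absolute ridge on $\tfrac12\|w\|^2$ | WoE features are log-odds-scaled, so unit ridge is mild |
| `lambda_min_ratio` | $10^{-4}$ | relative to $\lambda_{\max}$ | standard path practice |
| benchmark `ridge` | $10^{-2}$ | absolute | numerical stability only |

**The bin-count complexity charge.**  Raw IV never decreases under
further splitting, so maximizing IV alone always exhausts `max_bins`,
and an outcome-independent variable would keep spurious structure.  A
chance split contributes on the order of a one-degree chi-square times
$(1/E + 1/\bar E)$ to IV, and the optimizer takes the best of roughly
$m$ candidate boundaries per extra bin ($m$ = number of pre-bin
cells), so the default charge per extra bin is the Bonferroni-corrected
quantile $\chi^2_1(1 - 0.05/(m-1)) \cdot (1/E + 1/\bar E)$.  Under
permuted labels this collapses variables to one or two bins while
genuine threshold effects (whose IV increments are an order of
magnitude larger at the package's working sample sizes) keep their
edges; both behaviors are asserted in the test suite.  Setting
`complexity_penalty = 0` recovers the unpenalized IV maximum, which
the tests compare against exhaustive enumeration of all contiguous
partitions.

## The synthetic cohort generator

`generate_cohort` emulates the features of real post-concussion
cohorts the pipeline is designed around: five informative continuous
markers with piecewise-constant log-odds effects (cutpoints 9 and 12
on a days-like N(10, 3) scale; monotone steps of ±0.45 or U-shaped
profiles of ±0.4 — the U-shape mirrors the clinical observation that
unusually short recovery times carry elevated risk), 40 noise measures
grouped into blocks sharing a latent factor across the four timepoints
(correlation 0.5), four inert categoricals, and a Sport variable whose
level shifts reproduce the per-sport event rates of a published
collegiate cohort composition (`study_injury_counts`), sampled with
that cohort's sport weights.  The overall event rate lands near the
composition's 0.62.  Effect sizes were fixed once, by a design
calculation, at the largest values for which the ground-truth score
remains recoverable to within a few hundredths of AUC at the package's
working sample size; they are deliberately moderate clinical effects,
not separable signals.

Missingness (default 35%, never applied to Sport) comes in two modes.
Under the default MCAR mode the mask is drawn first and masked entries
contribute nothing to the latent score, so the returned
`latent_score` is the generating log-odds of the *observable* process
and `bayes_auc` is an attainable ceiling — this is what makes the
parameter-recovery tests a measure of the method rather than of
information destroyed by masking.  Under `missing_mode = "outcome"`
the score uses complete values and the mask is drawn given the
outcome, so the missing bin itself becomes predictive, exercising the
WoE treatment of informative missingness.  Which mode matches any
particular real cohort is unknowable from the package's side; both are
provided.

What the generator does **not** emulate: realistic marginal
distributions of specific clinical instruments (balance error counts,
symptom checklists and reaction times are all generic Gaussians),
cross-measure correlation beyond the within-measure blocks,
informative dropout over timepoints, or measurement drift.  Passing
the recovery tests therefore shows the pipeline recovers known
structure under realistic dimensionality, missingness and effect
sizes — not that it attains any particular performance on real
clinical data.

## Numerical and design choices

- **Rounding of stratified test counts** is half-up per outcome class,
  which reproduces the 96/59/24/15 partition of a 120/74 cohort at
  test fraction 0.2.  Split draws that would put a category level only
  in the test set are rejected and redrawn (bound: 1000, then an error
  naming the offending level).
- **Bins are half-open** $[lo, hi)$ with outer bins extended to
  $\pm\infty$; unseen categories and missing values without a fitted
  missing bin transform to 0 (neutral evidence), so predictions are
  total functions.
- **Degenerate columns**: an all-missing column yields a missing-bin-
  only scheme; a constant column a single bin.  A variable whose fit
  fails is excluded with a logged reason rather than aborting the
  cohort fit.
- **Categorical grouping is restricted to event-rate order**, making
  the optimum exact and reproducible; unordered exhaustive grouping is
  exponential in the number of levels and was rejected.
- **AICc uses the penalized fit's own likelihood** with
  $k$ = support size + 1.  Using the refit likelihood instead is a
  recognized alternative; the penalized-fit convention was kept as the
  standard lasso-information-criterion practice.
- **Optimizer tolerances**: glmnet convergence threshold $10^{-10}$;
  the exact ridge refit runs BFGS with analytic gradients to relative
  tolerance $10^{-14}$, initialized from the selected path point.  The
  refit's unpenalized intercept makes the mean predicted probability
  match the training event rate (calibration in the large), which the
  acceptance script reports.
- **Group contrast test**: the distributions of held-out risk scores
  for injured vs uninjured athletes are compared with a two-sided
  Mann-Whitney U test by default — a rank test matches the
  quartile-style presentation such scores usually get and needs no
  normality assumption; Welch's t is available via `method`.
- **Split-experiment seeding**: run $r$ uses seed $r$; rejected draws
  advance an inner counter only, so runs are independent and the whole
  experiment is bit-reproducible.  The sport-ablation arm removes any
  variable whose name matches `"sport"` case-insensitively.
- **Serialization** (schemes and fitted models) writes JSON with 17
  significant digits, which round-trips doubles bit-exactly; reloaded
  models predict identically to the originals.

## Problem sizes used by the tests

The suite works at deliberately modest scales chosen to make the
statistical assertions sharp: unit fixtures of 40–300 subjects,
parameter recovery at 2000 training / 2000 test subjects × 50
variables over 10 generator seeds, null (permuted-label) checks at
1000 subjects, and a 5-run split-stability experiment at 500–2000
subjects.  A `generator_spec_paper_scale` preset (194 subjects × 135
variables) mirrors the shape of the motivating study for exploratory
use; at that scale individual held-out AUCs are noisy (39-subject test
sets) and should only be interpreted across many splits.

## Known limitations

- IV-optimal bins can be clinically awkward; there is no facility yet
  for imposing pre-specified bin edges when interpretability demands
  them.
- No interaction (multi-variable) binning, no monotonicity constraints
  on WoE across bins, and no cross-validated penalty selection (model
  choice is committed to AICc).
- AICc with $k$ = support + 1 undercounts the effective degrees of
  freedom that supervised binning consumes, so some overfit noise
  variables survive selection at small $n$; the repeated-split
  experiment's selection frequencies are the intended diagnostic.
- The generator's ground-truth ceiling is only attainable under its
  MCAR mode; under outcome-dependent missingness the ceiling is not
  defined by `bayes_auc` alone (the mask carries extra evidence).
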