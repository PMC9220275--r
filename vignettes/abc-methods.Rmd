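---
title: "Reject-option sex classification with per-sex posterior thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reject-option sex classification with per-sex posterior thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Osteometric sex estimation predicts biological sex from skeletal
measurements. Long-bone dimensions are sexually dimorphic but their male and
female distributions overlap, so a conventional binary classifier that calls
every specimen at the 0.5 posterior sectioning point carries an error rate
fixed by that overlap — typically 10–20% for single femoral measurements.
Forensic casework often requires a stated, low error rate instead; the
admissibility of the conclusion depends on it.

The adjusted binary classification (ABC) procedure implemented here trades
coverage for a guaranteed error rate. Let $p(x)$ be a model's posterior
probability that a specimen is male. ABC selects two cutoffs, $c_m$ for the
male side (on the $p$ scale) and $c_f$ for the female side (on the $1-p$
scale), and classifies

* male if $p(x) \ge c_m$,
* female if $1 - p(x) \ge c_f$,
* otherwise *indeterminate*.

The cutoffs are chosen on held-out (cross-validated) posteriors so that, on
the classified subset, accuracy, positive predictive value and negative
predictive value all reach a target level $\tau$ (default 0.95), while
classifying as many specimens as possible. Male is the positive class
throughout.

## The threshold search

`abc_search()` scans candidate cutoffs taken from the *observed* posterior
values above 0.5 on each side, in ascending order: the smallest $c_m$ whose
classified-male set attains PPV $\ge \tau$, and the smallest $c_f$ whose
classified-female set attains NPV $\ge \tau$. Overall accuracy on the union
is then verified; on a violation the side with the lower predictive value
advances to its next admissible candidate and the check repeats. If the
candidates are exhausted the result is flagged infeasible (both cutoffs 1,
nothing classified) — a reportable state, not an error, since downstream
stages must continue.

Choices worth recording:

* **Candidate grid.** Observed posterior values, not a fixed lattice: the
  reported cutoff is always attained by at least one specimen and the search
  is exact over the data. The 0.5 boundary is kept only as a last-resort
  candidate when no observed value satisfies a side's constraint; this keeps
  the two classification regions disjoint and means a reported cutoff is an
  observed value whenever one works.
* **No monotonicity assumption.** PPV and NPV are not monotone in their
  cutoff, so every candidate is evaluated directly.
* **Ties classify.** A posterior exactly at a cutoff is classified (the
  $\ge$ convention), consistent with `classify_at()`.
* **Search order.** The per-side-then-verify order is a deterministic
  approximation to the joint search over cutoff pairs. The test suite
  compares it with an exhaustive pair-scan oracle on small instances and it
  attains the optimal classified count on the large majority of them; the
  guarantee itself (accuracy/PPV/NPV $\ge \tau$ whenever feasibility is
  reported) is asserted with zero tolerance.

Applied to new data (`abc_apply()`), fixed cutoffs carry no guarantee; the
result records whether the target was attained rather than failing.

## The four classifiers

All four produce a posterior through a linear logit on the raw measurement
scale, $p(x) = \mathrm{plogis}(\alpha + \beta^\top x)$, which makes fitted
models portable JSON artifacts and the ABC stage model-agnostic.

* **Logistic regression** — binomial GLM by IRLS, no tuning. Quasi-complete
  separation (small samples, many predictors) drives coefficients toward
  infinity; the fit is then flagged `separated` and standardized
  coefficients are capped at 15, which keeps the posteriors
  finite-precision-safe while preserving near-0/1 values. The cap value is
  deliberately large: it repairs the numerics, not the overfitting.
* **Linear discriminant analysis** — two-class Gaussian model with pooled
  covariance and equal priors (cohorts are balanced by construction). The
  Bayes posterior of that model is exactly a linear logit, computed here in
  closed form; the tests pin it to the closed-form univariate posterior at
  1e-10 and to an independent implementation.
* **Componentwise boosted GLM** — gradient boosting of a linear logit in
  the AdaBoost half-log-odds parameterization standard for boosted binomial
  models (loss $\log(1+e^{-2yf})$, $y \in \{-1,1\}$): at each of `mstop`
  iterations every single predictor (plus intercept) is fit by least
  squares to the current negative gradient and only the best-fitting
  component is updated, by $\nu = 0.1$ times its fit. Early stopping
  shrinks coefficients toward zero; as `mstop` grows the single-predictor
  fit converges to the logistic MLE (a test oracle). `mstop` is selected
  from \{50, 100, 150\} by internal 70/30 Monte-Carlo validation accuracy
  (25 iterations by default, ties to the smaller value).
* **Linear SVM** — soft-margin SVM (kernlab) with the cost fixed at
  $C = 1$. Posteriors come from a two-parameter sigmoid fit by regularized
  maximum likelihood (ridge $10^{-6}$, smoothed targets
  $(N_+ + 1)/(N_+ + 2)$ and $1/(N_- + 2)$) on decision values cross-fitted
  over 3 stratified folds, so the calibration never sees its own training
  decisions. The calibrated posterior is monotone in the decision value.

GLMB and SVM standardize predictors internally (both are scale-sensitive);
the constants are stored in the model and folded back into $(\alpha,
\beta)$, so prediction always happens on the raw scale. LR and LDA fit raw
for interpretable coefficients. Hyperparameters beyond those named stay at
their defaults deliberately — the protocol under study treats the
classifiers as commodity components.

## Resampling, ranking and selection

* **Monte-Carlo (leave-group-out) cross-validation** — repeated stratified
  70/30 calibration/validation splits (50 iterations by default). Metrics
  are averaged across iterations; an iteration whose metric is undefined
  (zero denominator) is excluded from that metric's average and counted.
  All validation-fold posteriors are pooled, because the ABC search needs
  specimen-level posteriors; the averaged metrics and the pooled set are
  returned together.
* **Univariate ranking** — per-variable trapezoidal ROC AUC of the raw
  measurement, folded as $\max(a, 1-a)$ so importance ignores direction
  (the raw orientation is retained). The trapezoidal area equals the
  Mann–Whitney statistic; the suite asserts agreement with the pair-counting
  c-index at 1e-12 and with an independent AUC implementation. The top five
  variables feed the univariate models.
* **Recursive feature elimination** — backward elimination judged by
  cross-validated accuracy at threshold 0.5 (selection happens before any
  ABC adjustment): at each step the variable whose removal least degrades
  accuracy is dropped, every candidate removal being evaluated on the same
  fixed set of resampling splits; all subset sizes are profiled and the
  best-accuracy subset wins, ties toward fewer variables. RFE is run per
  classifier — different classifiers legitimately select different subsets.
* **c-index** — midrank Mann–Whitney concordance of the male–female pairs,
  identical to pair counting with ties at 1/2.

## The synthetic cohort generator

The reference dataset (13 femoral measurements, 150 males and 150 females
from a modern Turkish CT sample) is not deposited, so the package ships a
generator instead of data. `femur_dimorphism_spec()` holds the published
per-sex means, SDs and observed ranges for all 13 variables;
`generate_cohort()` draws per-sex multivariate Gaussians with those
marginals and a shared between-variable correlation.

Only the marginals are published. The correlation structure is a modeling
choice: the default is a common pairwise correlation of 0.6, reflecting the
strong positive correlation of long-bone measurements, and is configurable
(including a full positive-definite matrix). Range truncation by rejection
sampling is available but off by default, since truncation perturbs the
target moments.

What the generator emulates: balanced two-group Gaussian structure with the
published effect sizes, which is what t-tests, LDA and the ABC machinery
presume. What it does not emulate: heterogeneous (block) correlation among
measurement families, non-Gaussian tails, measurement error, age and
population structure, and any train/test distribution shift. Consequences
for interpretation are discussed under limitations below.

## Numerical and protocol choices

* Pooled-variance t-test with $df = n_m + n_f - 2$ (with equal group sizes
  it coincides with the Welch statistic); `t_from_summary()` recomputes t
  from printed summaries, which is how the published t values are verified.
* Kernel-density overlap: Gaussian kernel, Silverman bandwidth per sample,
  both densities evaluated on one 1024-point grid spanning the pooled range
  plus three bandwidths; the index is the integrated minimum of the two
  densities (the intersection convention — the union convention would halve
  large overlaps), recorded in the result as `silverman:intersection`.
  Published overlap percentages depend on an unspecified bandwidth rule and
  are treated as non-reproducible; only the ordering across variables is
  checked.
* Stratified splitting uses round-half-to-even per-sex training counts; the
  published 80/20 of 150/150 is unambiguous, smaller cohorts need the rule.
  Sweep sizes are rounded to the nearest even count to keep sexes balanced.
* Posteriors are clamped to $[10^{-12}, 1-10^{-12}]$; confidently wrong and
  confidently right predictions can therefore tie at the clamp, which is
  the realistic behavior of any saturated-precision implementation and is
  what makes a separated LR either fully usable or fully infeasible under
  ABC.
* Derived seeds: every resampling consumer (CV iteration, calibration fold,
  sweep cell) receives a seed derived deterministically from the master
  seed, so any run replays bit-identically from its config.
* The sample-size sweep re-runs subset selection, CV, the ABC search and
  the test-set application per cell; a failed cell (degenerate small-sample
  fit) is recorded with its error message, not raised, because small-n
  failures are themselves findings. The single-draw protocol corresponds to
  `replicates = 1`; replicated draws are available because one subsample
  per size confounds size with sampling noise.

## Problem sizes used by the test suite

The full protocol at its default depth (50 CV iterations everywhere,
RFE over 13 variables for four classifiers) is more computation than a test
suite should carry, so the suite's end-to-end checks run five independent
reference cohorts (n = 300, correlation 0.6) with the RFE search at 10
resampling iterations, model evaluation at 25, sweep cells at 10, and
GLMB's internal `mstop` selection at 5–10 inner iterations inside search
loops (25 elsewhere). The acceptance script uses the same sizes. Unit
oracles (closed-form posteriors, pair enumeration, exhaustive cutoff
search) run at full precision.

## Limitations

* The ABC guarantee is a property of the posterior set it was searched on.
  On new data the attained accuracy can fall below the target — the test-set
  application therefore reports attainment as a flag.
* The generator's common-correlation Gaussian cohorts are a stand-in, not a
  claim about the real data. Two published qualitative findings depend on
  real-data features the generator deliberately omits: the near-equality of
  the four classifiers' multivariate accuracies, and the fragility of LR
  relative to GLMB at very small training sizes. Under equicorrelation the
  optimal discriminant loads heavily on between-variable contrasts, which a
  componentwise-boosted model capped at 150 iterations reaches only partly
  and which pushes a 13-predictor LR into quasi-complete separation; and
  with train and test drawn from one clean distribution, a separated LR
  that survives the ABC search generalizes better than it would under real
  covariate shift. Passing the remaining checks therefore shows the
  machinery is correct, not that every published contrast re-emerges under
  Gaussian equicorrelation.
* The per-side-then-verify threshold search can return a slightly smaller
  classified set than the exhaustive pair search on adversarial posterior
  configurations; the guarantee constraints are never relaxed.
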