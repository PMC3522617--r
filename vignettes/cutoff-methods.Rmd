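---
title: "Cutoff determination methods in markercut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff determination methods in markercut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markercut)
```

## The problem

Gene and protein expression are measured on metric or ordinal scales, but a
clinical decision is binary: treat or do not treat. Translating a continuous
biomarker into such a decision requires a cutoff that stratifies patients
into two groups. No single optimization criterion is right for every marker
and every clinical question, so `markercut` implements five families of
methods and, just as importantly, the diagnostics that show how stable the
chosen cutoff is.

Throughout, the marker values themselves are the candidate cutoffs, the
split is `low = {x < c}` vs `high = {x >= c}` (a value equal to the cutoff is
"high"), and the high group is the reference in every effect size. Observed
values keep reported cutoffs interpretable on the marker's own scale;
midpoints between order statistics would select the same partitions but
report values no patient actually has.

## Method 1: mixture-model density crossing

When the marker is bimodal — the typical shape for a marker that is "on" in
one biological subgroup and "off" in another — the distribution itself
suggests the cutoff. `fit_mixture()` fits

$$f(x) = \pi_1\,\varphi(x;\mu_1,\sigma_1) + \pi_2\,\varphi(x;\mu_2,\sigma_2)$$

by maximum-likelihood EM on the raw values, and `mixture_cutoff()` returns
the point where the two weighted component densities coincide,
$\pi_1 \varphi(x;\mu_1,\sigma_1) = \pi_2 \varphi(x;\mu_2,\sigma_2)$: the
value at which a patient is equally likely to come from either component.
This method needs no outcome data at all.

Numerical choices, all of which matter in degenerate corners:

* **Initialization and restarts.** EM converges to a local optimum. The
  first start splits the sample at its median; `n_starts - 1` further starts
  (default 9) draw random component means from the data under a caller seed,
  and the best final log-likelihood wins. The seed makes the whole fit
  reproducible.
* **Variance floor.** Each component SD is clamped to
  `1e-4 * sd(x)`, preventing the classical likelihood degeneracy where one
  component collapses onto a single observation.
* **Convergence.** Relative log-likelihood change below `1e-8`, at most 500
  iterations. On genuinely unimodal data EM creeps along a flat ridge and
  can hit the iteration cap; the fit is then returned flagged
  (`converged = FALSE`) and `mixture_cutoff()` refuses it rather than
  reporting a crossing of an unconverged model.
* **Root selection.** With unequal variances the crossing equation is a
  quadratic with up to two real roots. The root inside $(\mu_1, \mu_2)$ is
  the decision boundary; if none lies there (heavily overlapping
  components), the nearest root is returned with a warning. With equal
  variances the closed form
  $x = \tfrac{\mu_1+\mu_2}{2} + \sigma^2 \tfrac{\log(\pi_1/\pi_2)}{\mu_2-\mu_1}$
  applies; the tests pin the implementation to it.

```{r mixture}
x <- gen_bimodal_marker(400, mu = c(5, 10), seed = 1)
fit <- fit_mixture(x, seed = 1)
mixture_cutoff(fit)
```

## Methods 2–4: optimizing against a binary outcome

`binary_scan()` evaluates every candidate cutoff against a binary outcome:
the 2x2 confusion table, the odds ratio with a Wald CI (the cross-product
ratio, identical to the logistic-regression MLE for a single binary
predictor; Haldane–Anscombe +0.5 on zero cells, flagged), the two-sided
Fisher exact p, and sensitivity/specificity with **Wilson score** intervals
— Wilson because Wald intervals for proportions misbehave exactly where
diagnostic tests live, near 0 and 1.

Three optimizers consume the scan:

* `optimize_binary_significance()` — the minimal-p approach: the cutoff
  whose split is most significant by Fisher's exact test.
* `optimize_roc()` — the candidate closest to the top-left corner of the
  ROC diagram, by Euclidean distance or by Manhattan distance; the latter
  is equivalent to maximizing Youden's $J = \text{sens} + \text{spec} - 1$.
* `constrained_cutoff()` — the cutoff guaranteeing sensitivity (or
  specificity) strictly above a user threshold while maximizing the
  complementary measure. "Strictly above, maximizing the complement" is the
  stringent reading of a minimum-performance requirement: among all cutoffs
  that meet the guarantee, take the one that gives the best of the other
  measure.

All ties break toward the lowest cutoff — an arbitrary but deterministic and
documented rule.

The marker direction is detected automatically (`orientation = "auto"`):
whichever direction gives empirical AUC ≥ 0.5 is used, overridable when the
science says otherwise.

### The equivocal zone

Running the constrained optimizer twice — once for sensitivity, once for
specificity — yields a three-way test: positive at or above the specificity
cutoff, negative below the sensitivity cutoff, *equivocal* in between.
`equivocal_zone()` packages this and re-estimates sensitivity and
specificity on the non-equivocal samples. Two caveats the function is honest
about: excluding the zone can only lower the sensitivity relative to the
full-sample guarantee (the zone removes true positives from the numerator),
so the re-estimated measures exceed the threshold only when the constraints
are met with some slack; and on a very good marker the two constraints can
*invert* (the sensitivity cutoff lies above the specificity cutoff), in
which case the zone is empty, every sample is reliable, and a warning is
raised.

## Method 5: optimizing against survival

`survival_scan()` evaluates each candidate split with the standard
survival-analysis toolkit: the two-group **log-rank test** drives the
selection (`optimize_survival_significance()` takes the minimal p), while
the effect size is the **Cox** hazard ratio of high vs low with a Wald CI
(Efron tie handling by default, Breslow switchable). Both are reported per
candidate because they answer different questions — significance of the
split vs strength of the stratification.

The scan also carries the difference in **restricted mean survival time**:
the area under each arm's Kaplan-Meier curve up to a uniform horizon
$\tau$ = the largest observed time in the *full* cohort. A per-arm horizon
would make the two areas incomparable; the uniform horizon means one arm's
curve is usually extended flat beyond its own last observation, which is
deliberate. The CI uses the Greenwood-type asymptotic variance of the RMST
integral on each arm, combined as independent arms; the tests check it
against a nonparametric bootstrap.

When all events fall into one group the Cox partial likelihood is monotone
and the estimate diverges; such candidates are flagged (`boundary`) and get
an unbounded CI rather than a fabricated finite one.

## The minimal-p caveat

Scanning all cutoffs and reporting the best p-value is a multiple-testing
problem: under the null the selected p is far below its nominal level. The
package does not correct the p-value (corrections for maximally selected
statistics exist in the literature but are out of scope); instead it makes
the instability visible. The overview plots show the OR/HR with CIs across
*all* cutoffs, and `proportion_significant()` reports the fraction of
candidates significant at `alpha` (default 0.05) — a dichotomization whose
significance survives across most of the marker's range is less likely to
be an artifact of selection. The acceptance tests demonstrate the
anti-conservatism directly: with a marker independent of the outcome, the
selected p is below 0.05 in far more than 5% of simulated cohorts.

A related edge effect: with `min_group = 1` the log-rank statistic at an
extreme cutoff can be enormous when a single-patient group happens to have
an extreme event time. This is a real property of maximally selected
statistics, not a bug; `min_group` (exposed on every entry point) trims the
grid to splits with enough patients on both sides, and is the recommended
guard for survival scans.

## The synthetic cohort

`simulate_marker_dataset()` generates the structure every method assumes,
and is what the tests and the acceptance script run on:

* **Marker**: two-Gaussian mixture, default means 5 and 10, unit SDs, equal
  weights — a log2-expression-like bimodal marker, at the default cohort
  size n = 286 of a typical retrospective breast-cancer series.
* **Outcome**: logistic link $P(\text{pos}) = \text{expit}(a + b x)$,
  default $a = -15, b = 2$ (strong concordance, crossing 50% at the
  mixture midpoint 7.5), or a step link with symmetric label noise.
* **Survival**: exponential event times (baseline rate 0.1) with the hazard
  multiplied by a true HR of 0.5 for `marker >= 7.5`, plus independent
  exponential censoring whose rate is solved numerically to hit a 30%
  censoring fraction. Exponential baselines are the simplest
  proportional-hazards-consistent choice; the PH assumption therefore holds
  by construction, which the tests verify via a Schoenfeld residual trend
  test.

What the generator does **not** emulate: probe-level microarray noise,
batch effects, non-proportional hazards, informative censoring, or ordinal
markers with few levels. Passing tests on this cohort show the estimators
and optimizers are correct under their own assumptions — not that any
particular clinical marker satisfies those assumptions.

Problem sizes used in the test suite were chosen to give stable statistical
assertions at interactive runtimes: 50 random instances of n ≤ 60 for the
optimizer-vs-exhaustive-scan equivalences, 100 cohorts of n = 500 for
mixture-crossing recovery, 100 cohorts of n = 300 for survival changepoint
recovery, and 200 null cohorts of n = 40 for the anti-conservatism
demonstration.

## Known limitations

* The mixture model is exactly two Gaussian components; no model selection
  over the number of components, and coarse ordinal markers (e.g. an
  immunoreactive score with a dozen levels) can starve the EM.
* Selected p-values are uncorrected for cutoff multiplicity (by design, see
  above); treat them as descriptive, and validate any optimized cutoff on
  independent data.
* Effect sizes are univariate: no multivariate adjustment in either the
  logistic or the Cox direction.
* One cutoff only: three-group stratification is supported only via the
  two-run equivocal-zone recipe, not by simultaneous two-cutoff
  optimization.
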