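---
title: "Modelling old-item variance in recognition memory with uvsdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling old-item variance in recognition memory with uvsdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvsdr)
```

## The scientific problem

Confidence-rating ROCs from recognition memory are, after probit
transformation, approximately linear with slopes below 1. Under a Gaussian
signal detection account this forces the old-item strength distribution to
be wider than the new-item distribution: the unequal-variance signal
detection (UVSD) model. Two explanations of that *old-item variance
effect* compete. The *encoding-variability* account says studied items
receive a Gaussian increment of strength, `O = B + A`, so variance is
added at study. The *strength-scaling* account says the old-item SD simply
grows with the old-new mean separation `d`, approximately linearly. This
package implements the full modelling pipeline needed to pit these
accounts against each other on rating data: model fitting, design
emulation under either generative account, stimulus construction, and the
inferential battery.

## The standard model

New-item strength is N(0, 1); old-item strength is N(d, sigma_o^2). Five
strictly ordered criteria split the axis into six rating categories, and
category probabilities are Gaussian interval masses. The data for one
participant and condition are two 6-vectors of counts (old, new), and the
log-likelihood is the product-multinomial kernel; `fit_uvsd()` maximises
it. Numerical choices:

* **Parameterisation.** The optimiser works on
  `(d, log sigma_o, C1, log diff(C))`. Log-increments make criterion
  ordering unconditional; log sigma keeps the SD positive and matches the
  convention of analysing sigma_o on the log scale (it is a ratio against
  the fixed new-item SD).
* **Probability floor.** Category probabilities are floored at
  `eps = 1e-10` inside the log so that empty cells with zero predicted
  mass stay finite. The floor is an argument, not a constant.
* **Multi-start.** Ten starts by default: the first from the z-ROC
  heuristic (slope and intercept of the half-count-corrected probit points
  give starting `d` and `sigma_o`; false-alarm rates give starting
  criteria), the rest jittered with seeded noise. The fit is deterministic
  given `seed`. Non-convergence of every start is a warning plus a flag,
  never silent.
* **Identifiability.** Fits are refused with an explanatory error when all
  responses share one rating category, or when each item type occupies a
  single (different) category — perfect separation, where `d` and
  `sigma_o` diverge.
* **No continuity correction for fitting.** The half-count correction
  (replacing cumulative counts of 0 and N by 0.5 and N − 0.5) is applied
  only when forming descriptive z-ROC points, never in the likelihood.

The z-ROC identity is exact in population mode: `z(H) = d/sigma_o +
z(FA)/sigma_o`, so `zroc_slope()` on population points returns
`1/sigma_o` to machine precision (the points are computed in closed form
rather than via a `pnorm`/`qnorm` round trip, which loses precision in the
tails). We commit to slope = sigma_n/sigma_o: a slope of 0.8 means
sigma_o = 1.25. The occasionally seen phrasing "the slope is the ratio
sigma_o/sigma_n" is inconsistent with sub-unit slopes co-occurring with
sigma_o > sigma_n and is not adopted.

## The mixed-list (four-distribution) extension

When one study/test block mixes high- and low-variability sub-lists, each
of the four conditions (old/new x high/low) gets its own Gaussian, the
new-low distribution is the fixed N(0, 1) reference, and — because every
item is judged in the same test phase — a single criterion set is shared.
That gives 11 free parameters: three means, three SDs (fitted on the log
scale), five criteria. `extended_log_likelihood()` is the sum of four
multinomial terms; collapsing the high conditions onto the low ones
recovers the standard model's likelihood on pooled counts exactly (a unit
test asserts this). Discriminability splits into `d_high = mu_oh - mu_nh`
and `d_low = mu_ol` (the new-low mean is 0).

The joint construction is validated by recovery simulation rather than by
appeal to any external reference: at 20,000 trials per condition all six
free means and log-SDs are recovered within 0.05; at the realistic 60-120
trials per condition the new-high log-SD is recovered without detectable
bias (60 replicates, one-sample *t*), which is the property the analysis
pipeline's null test on sigma_nh relies on.

## What the generators emulate — and what they do not

`simulate_experiment()` produces long-format trial tables for two designs:

* **2x2 factorial** (strength high/low x item-characteristic variability
  high/low), four study/test blocks of 60 old + 60 new trials each.
* **Mixed-list single block**: 120 studied words, 240 test trials, with
  high/low variability sub-lists intermixed.

Calibration choices (made once, stated here because no single source pins
them all down):

* Condition means of `d` default to 1.46 (high strength) and 0.92 (low),
  the scale typical of a strong distraction manipulation at these design
  sizes. Old-item SDs follow a linear scaling law by default; the default
  law (intercept 1.0, slope 0.3) is chosen so that *condition-mean*
  sigma_o lands in the 1.25-1.45 range typical of rating studies at these
  `d` values. Note that published *across-participant* scaling fits tend
  to report much smaller intercepts (0.02-0.09) with slopes ~0.2; a line
  through the participant cloud and a line through condition means need
  not coincide, and the two targets cannot both be matched by one law.
  The curve-fitting checks therefore pass their law explicitly (e.g.
  `scaling_law(0.09, 0.18)`) where the participant-level relation is the
  object of study.
* Between-participant heterogeneity: `d` has SD 0.7 with 70% of its
  variance shared across conditions (a stable memory-ability trait);
  residual log-sigma noise around the scaling law has SD 0.15. For the
  mixed-list design, participant parameters are drawn around the
  population values in `exp3_population()`; 85% of the between-participant
  variance in the old-condition means and log-SDs is carried by a common
  ability (respectively variance) trait, the two traits correlating 0.55.
  The 0.85 share is derived from the magnitude of published paired
  comparisons between the two old-condition SDs relative to their
  between-participant spreads; the trait correlation induces the
  participant-level d-sigma association the within-condition regressions
  detect.
* **Item effects.** Each simulated word carries synthetic frequency,
  concreteness, age-of-acquisition, and length values
  (`generate_lexicon()`), and a standardised weighted index of these
  characteristics contributes a configurable share of the latent strength
  variance (default 5% in high-variability conditions, 0.5% in low). With
  60-trial cells and four predictors this puts mean manipulation-check
  R-squared near .11 in high and .06 in low conditions (the latter mostly
  the small-sample positive bias of R-squared), i.e. a 4-8 point
  difference. Because the index enters inside the total strength variance,
  the marginal strength distributions remain exactly Gaussian and the UVSD
  model stays well-specified.
* All randomness flows from a single seed; sub-seeds are derived
  deterministically per participant/condition, so results do not depend on
  execution order.

What the generators deliberately do **not** emulate: the distraction task
itself (only its effect on `d`), criterion drift within a test phase,
sequential dependencies between trials, non-Gaussian strength mixtures
(the discrete-mixture account is out of scope), and real word norms —
the synthetic lexicons match means, SDs, and correlation structure of
typical norms, not their marginal shapes or semantic content. Passing
tests therefore show the pipeline is correct and well-calibrated under the
model's own assumptions, not that real data satisfy those assumptions.

## Stimulus construction

The materials algorithms mirror how such experiments build word lists:

* **High-variability lists** (`sample_variability_lists()`, gaussian
  mode): rejection sampling of 60-word subsets until each list has the
  target attribute means (tolerance 0.15), the prescribed strong
  inter-correlations (r(frequency, concreteness) < -.77,
  r(frequency, aoa) < -.61, r(concreteness, aoa) > .26, applied one-sided
  exactly as stated), and passes a composite Anderson-Darling normality
  check (p > .05) per attribute. Attempts are capped; on failure the
  binding constraint is named. Sampling is without replacement across
  lists.
* **Wider, non-Gaussian lists** (nongaussian mode): words are scored by a
  weighted index of standardised attributes (weights configurable; equal
  magnitudes by default, frequency sign-flipped), grouped into bands by
  the index's SD-distance from its mean (default six bands of width 0.75
  SD, outer bands open), and sampled in equal numbers per band. Equal band
  weights overweight the tails, yielding roughly symmetric, flatter
  distributions whose attribute SDs run ~25% above gaussian-mode lists
  from the same lexicon. Band count and width are knobs because no
  external source fixes them.
* **Low-variability pool** (`select_low_variability_pool()`): candidates
  (fixed length 7 by default) are scored by the summed absolute deviation
  of their characteristics from the pool means; the 240 lowest-scoring
  words form the pool. Characteristics are standardised before summing —
  otherwise age-of-acquisition, measured in years, would dominate the
  1-5-scale norms. Ties break deterministically by word id.

## The inferential battery

* `rm_anova()` implements the within-subject decomposition directly. For
  2x2 designs each effect is the squared paired-t of its contrast on
  (1, n-1) df — an exact identity asserted in the tests. For one-way
  designs the Greenhouse-Geisser epsilon is computed from the
  double-centred sample covariance of the conditions,
  `eps = tr(S)^2 / ((k-1) sum(S^2))`, and multiplies both df; epsilon is
  exactly 1 at k = 2. Cross-checked against `stats::aov` with an Error
  stratum.
* `sequential_scaling_fit()` fits the linear, +quadratic, +cubic scaling
  models and compares them pairwise by extra-sum-of-squares F tests (each
  added term against the larger model's residual mean square). The
  selected model is the most complex with a significant added term at
  alpha = .05 (a configurable default; the selection threshold is not
  externally fixed). Improvements at numerical-noise level — e.g. when the
  linear model already fits perfectly — are never declared significant.
* Exclusions (`apply_exclusions()`): "predominantly extreme" responding is
  operationalised as >= 90% of ratings in categories {1, 6} (the threshold
  is configurable because "predominantly" is not a number), and outlying
  estimates as any d or log-sigma above the full-sample mean + 3 SD,
  one-sided, computed once without iteration. The log records which rule
  fired for whom.
* Condition means of sigma are always computed on the log scale and
  exponentiated, matching the convention of treating sigma_o as a ratio.
* `min_detectable_dz()` inverts the exact noncentral-t power function of
  the two-sided paired t test (via `stats::power.t.test`); 72 pairs at 80%
  power and alpha = .05 give d_z = 0.33.
* Bayes-factor columns are intentionally absent: scaled-JZS Bayes factors
  belong to external tooling and are out of scope here.

## Problem sizes used by the test suite

The suite validates large-sample recovery at 1e5 trials per item type
(standard model, tolerance 0.03) and 2e4 per condition (extended model,
tolerance 0.05); realistic-scale recovery with 200 simulated participants
of 60 + 60 trials (d correlation > 0.8); null calibration of each test at
2,000 replicates (acceptance band 3-7% at alpha = .05); and equal-variance
experiment calibration over 20 simulated experiments of 12 participants at
50 trials per item type. These sizes were chosen so the whole suite runs
in about a minute on a single core while keeping Monte-Carlo error well
inside every asserted tolerance.

## Known limitations

* The optimiser is a quasi-Newton local search with multi-start, not a
  global method; with 6-category data and the ordered-criteria
  parameterisation we have not observed multimodality, but pathological
  count patterns near the identifiability boundary can produce flagged
  (non-converged) fits.
* Extreme criteria combined with very large N can place entire categories
  below the probability floor; the floor then dominates those cells'
  contribution. The floor is visible and adjustable.
* The exclusion rule's outlier screen uses the one-sided mean + 3 SD
  bound on the full sample; with very small samples (< ~10 participants)
  the SD itself is noisy and the rule is conservative.
* `rm_anova()` requires complete cases; there is no imputation by design.
* The package fits no dual-process, mixture, or variable-criterion
  models; those accounts are out of scope.
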