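---
title: "Measuring numerosity–size interference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring numerosity-size interference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numerbias)
```

## Overview

`numerbias` is a pipeline for two-alternative forced-choice comparison
experiments on dot arrays, where the attended dimension is either
numerosity or mean item size and the unattended dimension may bias the
judgment.  The package covers five stages: (1) constrained stimulus
construction and factorial design enumeration, (2) a parametric synthetic
observer, (3) psychometric fitting with grid-Bayes posteriors, (4)
interference statistics (congruency effects, signed/unsigned biases,
bimodality), and (5) correlation utilities linking interference to
external ability scores.  This vignette records the models, the default
parameter values and the numerical choices, including the places where a
genuine design decision had to be made.

## Stimulus geometry and design

A stimulus is a set of dots inside a virtual circle of 7.6° or 5.8° of
visual angle.  Constraints: every dot lies entirely inside the circle;
edge-to-edge gaps are at least 0.25°; no dot overlaps a central fixation
exclusion disk; dots are half black and half white on a mid-gray
background (so luminance is not a numerosity cue); and density stays
under a cap (default 0.76 dots/deg²) that keeps arrays in the sparse
"number regime" where items are individually segregable — the densest
design cell, 20 dots in the 5.8° field, reaches 0.757 dots/deg².

Decisions the published constraints leave open, and how we resolved them:

* **"At least 0.25° apart"** is read as an *edge-to-edge* gap.  A
  center-to-center reading would force physical overlap for 0.5° dots,
  which the displays clearly did not have.
* **Containment** requires the whole dot inside the circle, not just its
  center — the conservative reading of "fall within a virtual circle".
* **Fixation exclusion** has no published radius; the default is a 0.3°
  disk, configurable in `design_config()`.
* **Placement** is uniform rejection sampling, largest dots first, with a
  10,000-attempt budget and whole-array restarts; exceeding the budget
  raises an explicit infeasibility error.  Identical RNG seeds give
  identical arrays.

Individual dot diameters come from a symmetric interval around the
nominal mean, linearly subdivided into as many bins as there are dots;
`sample_dot_diameters()` returns the *bin centers*, which guarantees the
arithmetic mean equals the nominal mean exactly.  The interval half-width
scales with the mean diameter (±0.09° at 0.25° up to ±0.19° at 0.5°); the
tabulated value for the 0.30° mean is taken as ±0.12° (the printed source
value "±12" is an evident typo for 0.12).  The 0.35° reference mean is
not in the table; its half-width (±0.135°) is linearly interpolated so
the size-spread scaling is preserved.

`enumerate_design()` crosses 6 attended ratios × 2 unattended magnitudes
× 2 field areas × 2 positions × 3 repetitions × 3 sessions = 432 trials
per task, each ratio appearing 72 times.  Congruency is defined by the
sign rule (congruent when both dimensions deviate from the reference in
the same direction), and ratios are binned far/medium/close by pairing
the symmetric values.  For the size task the attended axis is mean item
**area** (`2·log` diameter ratio), so the printed area sequence 0.05,
0.06, 0.07, 0.13, 0.17, 0.2 deg² corresponds to approximately the same
ratio ladder as the numerosities; the package stores exact areas computed
from diameters and treats the printed rounded values as display values.

## The synthetic observer

No human data ship with the package; a generative observer replaces them.
On each trial the decision variable is

$$ d = \log r_\text{att} + \beta \, \log r_\text{unatt} - \mu_0, $$

and the observer chooses the test with probability
$\lambda/2 + (1-\lambda)\,\Phi(d/\sigma)$.  All ratios are natural-log
test/reference ratios, with the size dimension always on the area scale.
The additive-in-log interference term is a *modeling choice*: the
phenomena it must emulate are described at the level of psychometric
shifts, and additivity is the minimal mechanism whose induced PSE shift
is analytically $-\beta\,\log r_\text{unatt}$ — with unattended levels at
ratios 0.5 and 2 the signed bias (PSE small − big) is exactly
$2\beta\log 2$, which the recovery tests exploit as a closed form.  The
direction and mechanism of the size-on-number bias is genuinely
unresolved in the literature; the mixture parametrization below is one
admissible stand-in, not a mechanistic claim.

Cohort defaults (`cohort_spec()`), chosen once to match the population
the pipeline emulates:

| parameter | control | dyscalculic | rationale |
|---|---|---|---|
| `sigma_num` | N(0.24, 0.04) | N(0.30, 0.05) | Weber fractions `0.675·σ` ≈ 0.16 / 0.20, the adult range for these tasks |
| `sigma_size` | N(0.24, 0.04) | N(0.24, 0.04) | size acuity comparable across groups |
| `beta_num` | N(0, 0.03) | ±0.35 mixture, sd 0.08 | controls nearly immune; dyscalculics strongly biased with subject-specific sign |
| `beta_size` | N(0.2, 0.06) | same | both groups overestimate size with more dots; induced bias ≈ 0.28 log units |
| `lapse` | N(0.02, 0.015), clipped to [0, 0.1] | same | small symmetric lapse |

Mixture membership in the dyscalculic cohort is **stratified**:
`round(n·w)` subjects take the positive component (shuffled), rather than
i.i.d. Bernoulli draws.  With i.i.d. assignment a 10-subject cohort falls
to a 7/3 split or worse about a third of the time, and a 3-of-10 minor
mode cannot be detected by a dip test at n = 10 regardless of how
separated the modes are; stratification reflects the empirical situation
being emulated — a small cohort in which both bias directions are
clearly populated.

What the generator does *not* emulate: sequential-presentation memory
effects, eccentricity and attention effects, reaction times (ability
scores enter as external inputs), and any trial-order learning or
fatigue.  A green test suite therefore establishes that the *analysis
machinery* is correct and calibrated for this generative family — not
that human data follow the additive model.

## Psychometric fitting

`fit_psychometric()` models the proportion of "test greater" choices as a
cumulative Gaussian with symmetric lapse on the log-ratio axis and
evaluates the Bernoulli likelihood on a fixed grid with uniform priors:
PSE on 121 points over [−0.6, 0.6] (step 0.01 log units), σ on 61
log-spaced points over [0.02, 1], lapse on 0, 0.01, …, 0.1.  The reported
fit is the maximum a posteriori grid point; the PSE marginal is kept for
interval arithmetic.  A grid posterior rather than MCMC keeps every fit
deterministic, fast (compiled likelihood kernel, ~10 ms) and exactly
reproducible.

Conventions decided here:

* **Log base**: natural log.  On this axis the fitted Weber fractions of
  typical adult observers land at 0.15–0.23, consistent with the values
  the pipeline is meant to reproduce.
* **Weber fraction**: reported as the JND in natural-log units,
  `w = σ·Φ⁻¹(0.75)`.  The alternative convention `exp(JND) − 1` differs
  by under 10% at these acuities and is available via
  `weber_fraction(fit, "proportional")`.
* **Size axis**: log mean-item-*area* (2× log diameter), so number- and
  size-task JNDs are directly comparable.
* **Lapse**: bounded at 0.1 and symmetric; fitting without a lapse is a
  one-line grid change (`grid_config(lapse = 0)`).
* **Degenerate inputs**: a single stimulus level with identical responses
  is unidentifiable and raises an explicit error rather than returning a
  boundary fit.  For perfect step data the likelihood is flat over the
  interval between the innermost levels; the MAP is then only determined
  up to that interval (the posterior mean pins zero), and σ sits at the
  grid floor — tests assert exactly this.

`split_fit_by_unattended()` refits on the 216-trial subsets defined by
the unattended magnitude, and `pse_difference()` convolves the two PSE
marginals (discrete convolution on the shared grid) into the posterior of
the difference.  From it: a 95% equal-tailed credible interval
(tie-broken toward wider coverage; half-grid-step discretization), and
`p = 2·min(P(D≤0), P(D≥0))`, the complement of the largest coverage whose
interval still excludes zero.  A subject's bias is "reliable" when
`p < 0.05`.  Equal-tailed intervals (not HPD) match the convolution
arithmetic and are symmetric-friendly.

## Interference statistics

* `congruency_table()` — errors (choices inconsistent with the true sign
  of the attended log-ratio) by ratio bin × congruency, plus the
  incongruent-minus-congruent effect.  The design guarantees the attended
  ratio never equals 1; the function guards it anyway.
* `cohort_bias_summary()` — one-sample t of signed biases against zero,
  count of individually reliable subjects, and an explicit `degenerate`
  flag when the biases have zero variance (t is then 0 or ±Inf rather
  than silently NaN).
* `dip_test()` — Hartigan's dip with a Monte-Carlo uniform null (default
  2000 replicates, the uniform being the least-favourable unimodal null).
  Only the Monte-Carlo p-value is provided; no quantile table ships.
* `group_contrast_unsigned()` — the task × group difference-of-differences
  on unsigned biases with a subject-level label-permutation p-value
  (default 10,000 permutations).  The factorial repeated-measures ANOVA
  this replaces is routine machinery; the targeted contrast is the
  quantity that actually carries the headline claim, and the permutation
  null makes no sphericity assumptions at these sample sizes.

### The dip statistic

The dip is the smallest sup-norm distance between the empirical CDF and
any unimodal CDF (convex below its mode, concave above; the optimal
unimodal fit may jump at the mode).  No implementation exists in the
environment, so the package computes it from first principles: bisection
on the band half-width `d`, with feasibility decided by scanning the
greatest convex minorant of the upper band and the least concave majorant
of the lower band, plus an exact junction check at candidate mode points
(a lower-bound propagation for the minimal end value of a convex chain).
Bisection runs to 1e-9; the statistic lives in `[1/(2n), 0.25]`.

Correctness is established by an *independent* oracle in the test suite:
a linear-programming formulation (via `boot::simplex`) that minimises `d`
over unimodal chains with the mode at each data point in turn, plus exact
hand-derived values — `dip = 0.25` for any two distinct points,
`1/(2n)` for equally spaced samples, `min(a,b)/(2n)` for two tight
clusters of sizes a and b, `1/6` for three equal clusters, and
`(1/2 − t)/(2(1 − t))` for the four-point family `(0, t, 1−t, 1)`.  The
implementation agrees with the LP oracle on hundreds of random samples to
1e-7.

## Correlations and ability scores

`ie_score()` implements the inverse-efficiency composite (mean RT divided
by proportion correct); RT generation is deliberately outside the
simulator, so IE inputs are plain numeric inputs.  `pearson_r()` and
`partial_r()` provide product-moment and residual-based partial
correlations (p on n − k − 2 df); with an empty covariate set the partial
reduces exactly to the Pearson.  `run_experiment()` can attach a
*synthetic* calculation-ability score — generated as a monotone function
of the subject's true number-task interference weight plus Gaussian noise
(600 + 900·|β_num| + N(0, 60) ms) — so the correlation stage is
exercisable end to end; it is labelled synthetic and carries no empirical
content.

## Reproducibility

Every stage draws from the R RNG; cohort and pipeline functions take a
master seed from which per-subject, per-task seeds are derived
arithmetically (subject-level reproducibility survives cohort resizing,
and derived seeds stay below 2^31).  `run_experiment()` reruns
byte-identically for a fixed seed, which the tests assert.

## Known limitations

* The additive-in-log observer is a stand-in; real interference may be
  nonlinear, asymmetric or attention-dependent.
* The grid posterior truncates the PSE axis at ±0.6 log units; observers
  with larger true shifts (|β| ≳ 0.43 at unattended ratio 2) would
  saturate, and σ is floored at 0.02.
* The dip's Monte-Carlo null is exchangeable but discrete: p-values are
  multiples of 1/replicates.
* Rendering (`render_stimulus()`) is a verification fixture, not display
  code: no anti-aliasing, luminance calibration or timing.
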