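# numerbias

Design, simulation and analysis tools for two-alternative forced-choice
experiments in which observers compare either the **numerosity** or the
**mean item size** of heterogeneous dot arrays, and the unattended
dimension interferes with the attended one.

## The problem

When people judge which of two dot clouds is more numerous, the size of
the dots should be irrelevant — yet it often is not, and vice versa: the
number of dots biases judgments of their average size.  Measuring this
reciprocal interference cleanly requires (i) stimuli in which numerosity
and mean size vary orthogonally under tight geometric constraints, (ii)
psychometric fits that separate *precision* (Weber fraction) from *bias*
(shift of the point of subjective equality), and (iii) statistics that can
tell a genuinely absent bias from strong biases of opposite sign that
cancel across observers — the signature reported for adults with
developmental dyscalculia judging numerosity.

`numerbias` implements that full pipeline, with a synthetic observer in
place of human participants so that every stage is testable: parameter
recovery, bias-detection calibration, and bimodality detection.

## The model

Each trial presents a test array against a fixed reference (10 dots of
0.35° mean diameter) inside a virtual circle of 7.6° or 5.8°, dots at
least 0.25° apart, half black and half white.  On the log-ratio axis
`x = log(test/reference)` (mean item **area** for the size task), the
probability of choosing the test is a cumulative Gaussian with lapses:

    P(choose test) = λ/2 + (1 − λ) Φ((x_att + β·x_unatt − μ₀)/σ)

* `σ` — internal noise; the just-noticeable difference is
  `JND = σ·Φ⁻¹(0.75)`, reported as the Weber fraction in log units.
* `β` — additive interference weight of the unattended dimension.  With
  unattended levels at ratios 0.5 and 2, the induced signed bias
  (PSE_small − PSE_big) is exactly `2·β·log 2`.
* Fitting is by a grid posterior over (PSE, σ, λ); the posterior
  marginals of the two split fits (unattended small vs big) are
  **convolved** to get the bias posterior, its 95% credible interval and a
  per-subject reliability flag.
* Bimodality of signed biases is tested with **Hartigan's dip statistic**
  (implemented in compiled code, validated against a linear-programming
  oracle) with a 2000-replicate Monte-Carlo uniform null.

## Worked example

```r
library(numerbias)

des  <- enumerate_design("size")          # 432-trial factorial design
obs  <- observer_params(sigma_size = 0.2, beta_size = 0.25, lapse = 0.02)
resp <- simulate_responses(des, obs, seed = 42)

fit_psychometric(resp)
#> <psychometric_fit> 432 trials, 6 stimulus levels
#>   PSE = -0.0500  sigma = 0.2383  lapse = 0.010  (MAP)
#>   JND = 0.1607 log units (Weber fraction, log convention)

bias_estimate(resp)
#> <bias_estimate>
#>   signed bias (small - big) = +0.4200 log units
#>   95% CI [0.2200, 0.5000]  p = 0.0001  reliable: TRUE
```

The fitted Weber fraction (0.16) tracks the generating noise
(`σ = 0.2`, i.e. `JND = 0.2 × 0.674 = 0.135`) within the sampling error
of a single 432-trial session, and the signed bias recovers the
closed-form prediction `2·β·log 2 = 0.347` within its credible interval:
this observer overestimates mean size when shown many dots.

A full simulated experiment — a control-like cohort (interference on size
judgments only) and a dyscalculic-like cohort (strong, sign-mixed
interference on number judgments) — runs with:

```r
report <- run_experiment(n_control = 14, n_dyscalculic = 10, seed = 1)
report$group_summaries   # per group x task: signed/unsigned bias, t vs 0
report$dip_tests         # bimodality of the signed biases
report$interaction       # task x group contrast on unsigned bias
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — design enumeration, cohort simulation, psychometric fits, bias
estimates, dip tests and the group contrast — at the published scale
(14 + 10 subjects, 432 trials per task) and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
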