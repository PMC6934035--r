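---
title: "Methods: state-trace analysis of sentence ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-trace analysis of sentence ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Sentence-rating experiments can elicit two kinds of judgment from the same
participant: an *acceptability* rating ("how natural does this sound?") and
a *grammaticality* rating ("does this follow the rules?"). Do the two tap
distinct mental factors, or a single underlying well-formedness dimension
filtered through different response styles? `statrace` implements the
frequentist state-trace approach to this question, together with the
simulation, exclusion, and summary machinery needed to run it end to end
on trial-level rating tables.

A *state trace* plots one dependent variable against the other across
conditions (here, sentence types). If one latent factor drives both
ratings, the per-condition means must fall on a single monotone curve —
whatever its shape — because both outcomes are then monotone functions of
the same latent quantity. Two factors are free to break the common rank
order. The test therefore asks: are the observed rank orders of the two
rating types consistent, beyond what sampling noise can explain?

## The one-dimensional model and its lack of fit

Let `x_i` and `y_i` be the mean acceptability and grammaticality ratings of
unit `i`, with weights `wx_i`, `wy_i` (cell counts by default). The
one-dimensional model says some order `pi` of the units makes both vectors
nondecreasing. Its lack of fit is

```
fit_1d = min over pi [ iso(x[pi], wx[pi]) + iso(y[pi], wy[pi]) ]
```

where `iso(v, w)` is the weighted isotonic-regression SSE: the minimum of
`sum w (v - f)^2` over nondecreasing `f`, computed exactly by weighted
pool-adjacent-violators (`isotonic()`). The two-dimensional alternative
lets each variable choose its own order; with no a-priori constraints its
lack of fit is exactly 0, so the test statistic reduces to `fit_1d`. The
constraint set of a restricted alternative is rarely available for rating
studies, so the unconstrained default is used throughout; `fit_2d()`
accepts an explicit partial order (solved by quadratic programming after a
cycle check) when a trace factor exists.

Monotonicity is weak (ties allowed) in both variables, and both rating
scales point the same way (higher = better), so both fits are
nondecreasing along the common order.

### Minimisation over orders

Minimising over all `n!` orders is exact and affordable for `n <= 9`
(`coupled_fit_exact()`, enumeration in compiled code with ties broken
toward the lexicographically smallest permutation). Above that,
`coupled_fit_heuristic()` runs a multi-start local search: deterministic
starts from the order by x, by y, and by the average of the two rank
vectors, plus 20 random restarts; moves are adjacent transpositions
(swept first-improvement) and single-element insertions. The heuristic
can only overestimate `fit_1d`; the test suite pins it to the enumeration
optimum on instances with `n` in 4–8, and enumeration itself is checked
against a plain-R brute-force oracle and the isotonic core against a
quadratic-programming projection. The numeric tolerance for accepting an
improving move is `1e-12` on the SSE scale; a fit of 0 (`< 1e-15`) stops
the search, since it is a global optimum.

## The bootstrap test

`sta_test()` computes the observed statistic on the full-data cell means
and compares it with a bootstrap population. Each iteration resamples
ratings, recomputes cell means, and refits; the p value is the proportion
of bootstrap statistics at least as large as the observed one
(`comparison = "non_strict"`). A strict "greater than" comparison is
selectable, but it makes perfectly monotone noiseless data — observed
statistic 0 and every bootstrap statistic 0 — yield p = 0, a pathological
rejection of data that fit the null perfectly; non-strict gives p = 1
there, which is why it is the default.

Three resampling schemes:

* `"data_informed"` (default): residuals around each cell's observed mean
  are resampled with replacement and recentred on the one-dimensional
  model's *fitted* cell means, so bootstrap data are generated under the
  null hypothesis. This is the variant the frequentist state-trace
  literature uses, and the package follows it.
* `"cells"`: plain within-cell resampling around observed means, sizes
  preserved. Because the observed rank-order violations are baked into
  every resample, this scheme is markedly conservative (bootstrap
  statistics stochastically dominate the observed one); it is kept for
  comparison.
* `"participants"`: whole participants resampled with replacement, for
  designs where the participant is the natural exchangeable unit.

Even the data-informed scheme is somewhat conservative near the null:
the fitted monotone means absorb part of the noise, so bootstrap data
carry slightly more order-violation than the observed data did. In the
calibration study below the type-I error at nominal 0.05 comes out near
0.01–0.05 rather than at 0.05; the test errs on the side of failing to
reject one-dimensionality.

Cells with fewer than `min_cell = 8` ratings are flagged (not dropped):
below roughly that size, resampling a cell degenerates to reshuffling a
handful of values and the bootstrap distribution becomes lumpy.

## The synthetic-data generator

The generator emulates the rating-experiment structure the analysis
expects, so every stage is testable without access to a real (unpublished)
dataset:

* Each of `n_units = 15` sentence-type conditions carries two latent
  consensus means. The acceptability latent `u1` is uniform on the rating
  scale `[0, 5]`; the grammaticality latent is `u2 = u1 + e` with Gaussian
  `e` whose standard deviation is solved analytically from the target
  correlation: `sd(e) = sqrt(Var(u1) (1/rho^2 - 1))`, `Var(u1) = 25/12`.
  At `rho = 1` the two latents coincide (a true one-factor world). `u2`
  is deliberately not clipped to the scale: clipping would distort the
  additive noise model that defines `rho`.
* Ratings are the latent mean plus Gaussian noise with `noise_sd = 1`,
  `n_per_cell = 13` per unit and condition — the cell sizes a
  crowd-sourced study of this shape typically achieves. Ratings are left
  continuous by default; `discretize = TRUE` clips to `[0, 5]` and rounds,
  for realistic Likert fixtures.
* `generate_experiment()` adds the participant layer: two 30-item blocks
  (one per instruction condition), item draws without replacement within
  participant and uniform over sentence type, and two fixed attention-check
  items appended to the grammaticality block. The item pool holds 6 items
  per sentence type (90 total, at least two blocks' worth); with the
  default 39 participants each item collects about 13 ratings per
  condition. Response times are a constant 7.7 s and total participation
  10 min — the generator does not model response-time or bias processes,
  so response-time summaries on synthetic data are placeholders, exercised
  by fixtures that perturb them explicitly.

What passing tests on synthetic data do *not* show: real rating data have
participant-level response styles, item heterogeneity within sentence
types, and scale-use artifacts (endpoint attraction) that the generator
deliberately omits. Results on synthetic data validate the machinery and
the test's operating characteristics under its own assumptions, not the
substantive conclusion for any real dataset.

Latents are assigned per sentence type by default (`latent_unit =
"sentence_type"`), matching a design where the sentence type is the unit
of analysis; `"item"` draws an independent pair per item for analyses
that treat each stimulus as a point on the trace. The analysis unit in
`aggregate_cells()` and `sta_test()` mirrors the same choice, defaulting
to sentence type × variant.

## Exclusions

`apply_exclusions()` applies the standard crowd-sourcing screen: reported
non-native speakers, incomplete sessions, total participation under 4
minutes (240 s, configurable), and attention-check failures — the
known-bad item must get one of the two lowest options and the known-good
item one of the two highest. A missing check record counts as incomplete,
not as an attention failure. The report carries each criterion's marginal
count, the number of participants triggering two or more criteria, unique
exclusions, and the retention percentage rounded half away from zero to a
whole percent.

## Descriptive summaries

`contrast_table()` tests the acceptability–grammaticality difference per
sentence type at the response level with Welch's unequal-variance t test
(the conservative default when the variance structure is unknown;
pooled-variance is available), with normal-approximation 95% intervals
(mean ± 1.96 SE). `extremity_proportions()` reports the percentage of
responses at the scale endpoints {0, 5} per condition.
`rt_contrast()` z-scores response times within participant before
comparing conditions, so between-participant speed differences cancel;
participants with zero spread contribute zeros with a warning.
`difference_distributions()` gives per-item acceptability-minus-
grammaticality differences with group spread statistics. No
multiple-comparison correction is applied, matching common practice for
descriptive contrast tables of this kind.

## Numerical and design choices

* Sample variance uses the n−1 denominator, defined as 0 for n = 1.
* Cell weights default to the cell count `n`; inverse squared standard
  error is available but interacts badly with zero-variance cells (it
  falls back to `n` there).
* Bootstrap p values are plain proportions `count / n_boot`, so they live
  on the grid `{0, 1/n_boot, ..., 1}`; comparisons use a `1e-12` tolerance
  so exact ties of a zero statistic are counted as "at least as large".
* All randomness flows through explicit `seed` arguments (applied via
  `withr::local_seed`, so callers' RNG state is untouched); the same seed
  reproduces results byte-for-byte, including CSV output.
* Degenerate inputs: a unit observed in only one condition is dropped from
  the trace with a warning; both-constant groups with equal means return
  t = 0, p = 1 rather than 0/0; empty tables aggregate to empty summaries.

## Study sizes used in the checks

The packaged checks run the calibration study at 200 simulated
experiments (15 units, 13 ratings/cell, noise sd 1, 300 bootstrap
iterations) and the power sweep at 35 repetitions per correlation in
{0.8, 0.9, 0.977} with the same bootstrap size — sizes at which the
binomial noise on a rejection rate (about ±0.08 at 35 reps) still leaves
the qualitative ordering stable. The expected pattern, reproduced by
`power_curve()`, is majority rejection at correlation 0.8 and frequent
failure to reject at 0.977, with type-I error at or below nominal under
the null.

## Known limitations

* The heuristic carries no optimality certificate above `n = 9`; its
  agreement with enumeration is verified only on small instances.
* The bootstrap test is conservative near the null (see above); a
  borderline p value slightly above 0.05 may understate the evidence
  against one-dimensionality.
* With no a-priori partial order, the two-dimensional model fits
  perfectly, so the test statistic is a pure lack-of-fit of the
  one-dimensional model; supplying a trace factor would sharpen the test
  but requires design knowledge the package cannot infer.
* Response-level Welch tests treat ratings within a condition as
  exchangeable across participants and items; no mixed-effects structure
  is modelled.
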