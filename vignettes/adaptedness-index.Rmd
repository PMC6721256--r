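---
title: "Scoring physiological adaptedness: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring physiological adaptedness: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptindex)
```

## The model

`adaptindex` scores how well an organism withstands an acute provoking load
`Q` (exercise, hypoxia, a pharmacological challenge), possibly after a
chronic conditioning influence `P` (training, pre-treatment). Four states
are recognised: the intact baseline `F°`, the pre-load state `F′` (after
`P`), the post-load state `F″`, and the state `F‴` after a rest interval.
For unconditioned subjects `F°` and `F′` coincide and may alias the same
measurements.

Each measured parameter is declared by the analyst as **homeostatic** (the
load deflects it directly: lactate, glycogen, body temperature),
**adaptive/allostatic** (compensatory machinery that activates to oppose
the deflection: heart rate, corticosteroids), or **indifferent**. This
classification is a physiological judgement; the package never infers it,
because the boundary genuinely depends on the stressor and its timing.

Two dimensionless fractions per parameter feed the score. The *response
fraction* `|K″ − K′| / K′` measures the relative load shift; direction is
discarded so that parameters moving up or down are comparable. The
*recovery fraction* `|K‴ − K′| / |K‴ − K″|` is small when the parameter has
returned close to its pre-load value after covering much ground during
rest. A subject's index is the signed sum

$$a \;=\; \sum_{j=1}^{m} S_j\!\left(-\frac{|K_j''-K_j'|}{K_j'}
  -\frac{|K_j'''-K_j'|}{|K_j'''-K_j''|}\right)
  \;+\; \sum_{h=1}^{d} S_h\!\left(+\frac{|K_h''-K_h'|}{K_h'}
  -\frac{|K_h'''-K_h'|}{|K_h'''-K_h''|}\right),$$

over homeostatic parameters $j$ and adaptive parameters $h$: homeostatic
deflection and sluggish recovery count against adaptedness, adaptive
activation counts for it. The weight $S = 1 - \mathrm{SD}/\mathrm{mean}$,
one minus the coefficient of variation of the parameter in an intact
baseline cohort, expresses that deviations of ultrastable constants are
physiologically costlier — and hence more diagnostic — than deviations of
labile variables. With all $S = 1$ the weighted index reduces exactly to
the unweighted sum, and both modes are first-class
(`index_options(weighting =)`).

The index has *no absolute meaning*. Only comparisons between units scored
under an identical panel, states and options are meaningful, which is why
every result carries an options fingerprint and `validate_inputs()` refuses
comparisons whose homeostatic count $m$, adaptive count $d$, parameter
identities or recovery availability differ.

### Assumptions

* Parameters are approximately Gaussian in the intact population; the
  stability weighting is meaningless for `SD >= mean` (Poisson-like or
  skewed variables), which is rejected outright, and coefficients below
  0.5 are flagged as unreliable but allowed — published analyses themselves
  use values as low as 0.42.
* The organisms are regulators, not conformers: a species that does not
  defend its internal milieu has no homeostatic deflection to score.
* Responses are compared at matched rest intervals. The recovery fraction
  blows up when the rest interval is so short that `K‴ ≈ K″`; such designs
  should be avoided. Fractions above 1 are flagged; the degenerate
  `K‴ = K″ ≠ K′` case errors unless the caller supplies a finite cap
  (`index_options(recovery_cap =)`), mirroring the fallback of dividing by
  a fixed constant, which is off by default because it puts the capped
  parameter on an unequal footing.

## Study designs

**Case I** compares two subjects measured repeatedly
(`compare_subjects()`). **Case II** (`group_index_repeated()`) scores each
subject of each group and reports the group mean `A`, the sample SD of the
individual `a` values, and a normal-approximation confidence interval
(default level 0.95). The between-group test is Welch's two-sample t on the
individual `a` values by default, with a seeded permutation alternative for
small groups; the method itself names no test, so this is a package
choice. Pairwise p-values are reported raw, without multiplicity
correction, and printed as such.

**Case III** (`group_index_destructive()`) handles destructive sampling:
different animals are measured at each state, so the group mean of every
cell substitutes for the individual value and each group is scored as one
pseudo-profile. The dispersion of such an index is an open problem in the
original method. The package offers a parametric bootstrap as a clearly
labelled beyond-source extension: each cell mean is resampled from
`Normal(mean, sd/sqrt(n))`, the index recomputed per replicate, and the
empirical SD and percentile interval reported. The bootstrap was preferred
over a delta-method linearisation for transparency — the recovery fraction
is a ratio whose denominator can approach zero, where a first-order
approximation is exactly wrong.

Ranks are assigned by descending `A` (rank 1 = most adaptive); ties share a
dense rank and trigger a warning rather than being broken arbitrarily.

### Zeroing non-significant changes

Changes that do not reach significance — in particular "paradoxical" shifts
running against the direction seen in a compared group — can be treated as
zero response via `zero_insignificant()`, either from a user-supplied mask
or from a Welch test computed on the (mean, SD, n) summaries. This is **off
by default** everywhere: the published worked examples do not apply it, and
silently zeroing terms would break table reproduction. When enabled, every
zeroing action is logged.

## Stability coefficients

`S` may be supplied fixed (as when reproducing a published table) or
estimated from baseline data with `compute_stability()`, with three source
policies: the pooled baseline of designated groups, per-group baselines, or
the mean of per-group coefficients. The sample SD (n − 1) is used
throughout — the convention for small animal cohorts. The bundled rat
fixture supplies the published S values, derived from the control untrained
rest cohort; a test recomputes all five from the transcribed baseline
summaries and agrees within 0.001. In the horse fixture the published
per-group S values match each group's own baseline (not the mean of the two
baselines the accompanying text describes); since that study's index is
aggregated unweighted, the discrepancy does not touch any reported value,
and both policies remain available.

## The synthetic-cohort generator

`simulate_study()` exists so that every design path is testable against a
known ground truth. Each group carries a latent adaptedness level
`theta` in `[0, 1]`; per subject and parameter,

* `K′ ~ Normal(mu, sigma)` — between-subject baseline variation;
* homeostatic: `K″ = K′ (1 + delta (1 − theta) + e)` — a fully adapted
  group shows no homeostatic deflection;
* adaptive: `K″ = K′ (1 + gamma theta + e)` — activation scales with
  adaptedness;
* `K‴ = K″ + rho(theta)(K′ − K″) + K′ e` with `rho(theta) = rho0 +
  rho1 theta` — recovery covers a larger fraction of the ground the more
  adapted the group;

with `e ~ Normal(0, noise_sd)` drawn independently at the load and recovery
stages. All effects are multiplicative because the index itself is built on
relative fractions, which keeps `theta`'s effect scale-free across
parameters. Values are clipped below at 1% of the baseline mean (counted
and reported) rather than resampled, so that a fixed seed always consumes
the same random numbers.

The default panel and effect sizes are calibrated to the magnitudes the
bundled real studies show: three homeostatic parameters with `delta` =
1.7 (lactate; the untrained rats' relative lactate shift is 1.72), 0.9
(glycogen) and 1.0 (ammonia); two adaptive parameters with `gamma` = 2.0
(the horses' heart-rate rise is 2.05, rat corticosteroid rises span
1.3–2.7); `rho0 = 0.3`, `rho1 = 0.6`, so recovery fractions of
well-adapted groups sit well below 1 as in the robust horses; and stage
noise `noise_sd = 0.03`, a typical assay-level analytic CV. Under these
conditions the noise-free index is strictly increasing in `theta`, and
across 200 seeded replicates of a 4-group study (`theta` = 0.2/0.4/0.6/0.8,
n = 25 per group, unweighted mode) the recovered group ordering matched the
true ordering in every replicate — the test suite requires at least 95%.

What the generator does **not** emulate: supercompensation (post-recovery
overshoot), nonlinear or exponential recovery kinetics, correlated
biomarkers, non-Gaussian baselines, or measurement dropout. Passing the
parameter-recovery test therefore shows that the index orders groups
correctly when its own assumptions hold; it says nothing about robustness
to skewed biomarkers or overshooting recovery, which the method explicitly
excludes.

## Numerical conventions

* **Recovery 0/0**: a parameter back at its pre-load value scores recovery
  fraction 0 — the numerator-zero convention wins, including the 0/0 case
  (full recovery); published "−0" cells are consistent with this.
* **`K′ ≤ 0`** is rejected: the relative fractions presuppose positive
  physiological magnitudes.
* Full precision is kept internally; reports render at 3 decimals to mirror
  the published tables, and the JSON report twin round-trips at full
  precision.
* Reproduction checks compare per-term values at ±0.01, except single cells
  documented as carrying larger published rounding slop (the untrained
  adaptogen group's hexokinase term, printed from a rounded intermediate,
  checked at ±0.06); full-pipeline group indices at ±0.06 (rats, where the
  published terms were rounded before summation) and ±0.01 (horses); ranks
  exactly.
* Indifferent parameters are retained as zero rows in breakdowns so the
  `m`/`d` bookkeeping stays visible.
* No rest-interval duration enters the formulas: with matched intervals
  between compared units there is no need for it, and no normalised variant
  is defined.

## Limitations

The index is a sum, so it is only as balanced as the panel: panels should
include several adaptive functions spanning a range of stability
coefficients. The Case III bootstrap quantifies only sampling noise of the
cell means, not model error. The fidelity of the two bundled fixtures is
limited by the printed precision of their sources (one published hexokinase
fraction, 0.600, differs from its own cell means, which give 0.613; the
transcription keeps the cell means and documents the mismatch via the wider
tolerance above).
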