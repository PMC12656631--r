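---
title: "Terrain-weighted pacing features and in-race finish-time prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terrain-weighted pacing features and in-race finish-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailpace)
```

## The problem

Finish-time prediction in trail running is hard because effort is dominated
by terrain: a 5.5 km section climbing 1430 m takes several times longer than
a flat 5.5 km, and raw split times correlate only moderately with the final
result. `trailpace` implements a modelling chain built entirely from in-race
data for races timed over sections of alternating net slope: terrain
difficulty scoring of each section, difficulty-weighted split times, pacing
variability across comparable terrain, pooled checkpoint ranks, and per-
segment regression models of total time whose ascent forms collapse to
closed-form predictors evaluable mid-race.

The package is programmatic: the exported functions, the test suite and
`scripts/acceptance.R` are the interface.

## Difficulty factors and relative coefficients

A track of distance $d$ km with accumulated ascent $S^+$ and descent $S^-$
(m) has uphill and downhill difficulty factors
$\mathrm{IDF}^{+} = d + S^{+}/100$ and $\mathrm{IDF}^{-} = d + S^{-}/100$;
the same formula applied to a section's own distance and net-slope elevation
gives the section factor, and the ratio of section to race factor of the
same slope sign is the section's relative difficulty coefficient
$\mathrm{IRDC}_n \in (0, 1]$ — its share of the race's slope-matched
difficulty. The ratio is invariant to rescaling the whole course, and both
factors are strictly increasing in distance and elevation; both properties
are asserted in the test suite.

Two conventions matter and are fixed deliberately:

- **Signed elevation.** Config files store descent as a non-negative
  magnitude and carry an explicit `net_slope` flag per section instead of
  re-deriving it, so published section tables can be reproduced exactly.
- **Printed-value overrides.** The built-in fixtures for the two Trail
  Valle de Tena modalities store the officially published section factors
  where those differ from the raw distance/slope arithmetic (sections 1, 4
  and 5: published 20.5, 11.0, 9.0 versus recomputed 19.8, 10.8, 8.7), and
  the published 8K downhill race factor 148 (raw totals give 147.5). The
  published values are treated as authoritative because the 2-decimal
  coefficient table and the closed-form predictors are built on them;
  recomputation from raw inputs stays available via
  `use_override = FALSE`.

All arithmetic is at full floating precision by default. The
`rounding = "paper"` mode rounds coefficients to 2 decimals — the precision
at which the published closed forms embed them (0.27, 0.16, 0.14, 0.08).
Mixing modes across model provenance is refused: published coefficients are
only evaluated over 2-decimal coefficients, freshly fitted ones only over
full precision, because a coefficient estimated on one predictor scale is
biased on the other.

## Per-runner features

For runner $i$ with section time $T_n$ (hours, from successive differences
of elapsed checkpoint passage times; a missed checkpoint voids both adjacent
sections):

- weighted time $\mathrm{WT}_n = T_n / \mathrm{IRDC}_n$, the section effort
  extrapolated to whole-race scale;
- weighted-time variability
  $\mathrm{WTV}_{n,n+2} = \mathrm{WT}_{n+2}/\mathrm{WT}_n - 1$ between two
  sections of the same slope type consecutive in terrain order — pairs
  (1,3), (2,4), (3,5) on the five-section fixtures — positive when the
  runner slows on comparable terrain;
- checkpoint percentile rank $\mathrm{CPR}_n$, the ascending rank fraction
  of the passage time in the field pooled across modalities (the checkpoints
  lie on the shared course portion). The fastest of $n$ runners gets $1/n$,
  the slowest 1, and ties share the mean rank. The direction (fastest =
  smallest) is chosen so that a positive rank coefficient in the finish-time
  model means slower-ranked runners finish later.

Quartile grouping splits the field at rank $\lceil n/4 \rceil$ *inclusive*:
with 947 ranked runners the boundary rank 237 (237/947 = 0.2503) belongs to
the fast quartile Q1, giving the 237/710 split used in group comparisons.
Missing data are excluded pairwise per feature, never listwise.

## Group statistics

Race split times are heavy-tailed, so significance is assessed by bootstrap:
the test statistic (paired t on differences; Welch t between groups, robust
to field imbalances like 76 vs 871) is recomputed on 1000 resamples drawn
under a null enforced by mean-centring (differences, or each group), and the
two-sided p-value is the fraction of $|t^\ast| \ge |t_{obs}|$ with the +1
finite-sample correction. The analytic t-test p is reported alongside; the
two converge on Gaussian data, which the tests check at tolerance 0.02. An
explicit seed is mandatory for every stochastic routine and makes results
bit-reproducible.

Effect sizes are Cohen's d — mean difference over SD of differences
(paired) or over the pooled SD (independent) — with the conventional
trivial/small/medium/large bands at 0.2/0.5/0.8. The paired denominator
uses the SD of differences; with strongly correlated pairs this is the more
conservative-looking convention (larger |d|) and is stated here because the
choice is not inferable from the statistic's name. Post hoc power comes
from the noncentral-t distribution (t-tests) or the Fisher-z approximation
(correlations); at zero effect it equals $\alpha$ by construction and it was
verified against a $10^5$-replicate Monte-Carlo oracle. Normality screening
reports both a Lilliefors-corrected Kolmogorov–Smirnov test and Shapiro–
Wilk.

## Segment regression and diagnostics

Each terrain segment — ascent 1 (sections 1 and 3, rank at cp1), descent
(2 and 4, cp2), ascent 2 (3 and 5, cp3) — gets an OLS model of finish time
on its predictor triple $(\mathrm{WT}_n, \mathrm{WTV}_{n,n+2},
\mathrm{CPR}_n)$ with all three entered simultaneously ("enter" method).
Stepwise entry/removal thresholds are deliberately not applied: the model is
a fixed specification, and all three predictors are always retained. The
percentile rank enters as a fraction in $(0,1]$; coefficient magnitudes
depend on that convention.

Diagnostics follow standard definitions: Durbin–Watson
$\sum(e_i - e_{i-1})^2 / \sum e_i^2$ (1–3 acceptable), variance inflation
$1/(1 - R_j^2)$ (above 10 flags collinearity), Cook's distance with the
$D > 1$ influence rule, standardized residuals beyond ±3 SD as outliers.
Case screening is a **single pass** — flag, remove, refit once — not
iterated to convergence; iterating can cascade on heavy-tailed race data
and makes the excluded set order-dependent. When a fit is exact to machine
precision the influence measures are ratios of floating-point noise and
screening is skipped. Coefficient intervals are analytic t-based ones;
standardized betas are $B_j \,\mathrm{sd}(x_j)/\mathrm{sd}(y)$, invariant to
affine predictor rescaling. Agreement between predicted and actual times is
summarised Bland–Altman style: bias, ±1.96 SD limits, fraction outside
(about 5% for Gaussian differences), and a normality screen of the
differences.

Every diagnostic is tested against an independent brute-force oracle —
normal equations for the coefficients, auxiliary regressions for VIF,
leave-one-out refits for Cook's distance, and the `lmtest`/`car`
implementations as cross-checks — at tolerance 1e-10.

## Prediction and closed forms

`predict_tt()` evaluates a model for one runner from raw section times and
the live rank; `expand_closed_form()` substitutes the feature definitions
symbolically, producing

$$\mathrm{TT} = B_1 \frac{T_a}{i_a}
  + B_2\!\left(\frac{T_b/i_b}{T_a/i_a} - 1\right)
  + B_3\,\frac{\mathrm{rank}}{n} + B_0$$

with $i_a, i_b$ the segment's two same-slope coefficients. The two paths
are algebraically identical and tested to agree to 1e-10. The field size
$n$ at prediction time is supplied by the caller: mid-race the final
finisher count is unknown, so the live-timing field stands in — a
documented divergence from the retrospective setting, where $n$ is the
pooled finisher count.

## The synthetic generator

`simulate_field()` draws, per runner, a latent ability $A$ (hours, on the
weighted-time scale) from a lognormal, and sets section times
$T_n = \mathrm{IRDC}_n \cdot A \cdot f_n \cdot (1 + \varepsilon_n)$, where
$f_n$ is a cumulative same-slope fatigue drift and $\varepsilon_n$ is
Gaussian noise. Defining ability on the weighted-time scale makes
difficulty-proportional pacing — the premise the features encode — hold
exactly in the noiseless limit: every $\mathrm{WT}_n = A$ and every WTV is
0, which the tests assert. The finish time adds a single ability-
proportional lump for the untimed course remainder, since no structure is
assumed beyond the last shared checkpoint.

Defaults are fixed once to the study conditions the pipeline targets and
are not tuning knobs: fields of 764 + 183 runners (male fraction 871/947);
ability matched to first-ascent weighted times of 7.30 ± 1.02 h and
16.85 ± 2.75 h; drift targets 0.31, 0.15 and −0.02 for the three same-slope
transitions (the observed slowing on early ascents and descents and the
late-race stabilisation); per-section noise SD 0.08, which places the
paired first-vs-second-ascent effect size near −2; remainder fractions
0.373 and 0.577 solved so mean finish times land at 9.98 h and 18.35 h.
With these defaults the generated field reproduces the qualitative
structure the analysis assumes — weighted times correlating above 0.9 with
finish time and out-correlating raw times, a strongly negative paired
effect on the first ascent, a 237-runner fast quartile — and generator
parameters are recoverable from the output within Monte-Carlo error (the
mean of a noisy WT ratio carries the second-order $1 + \sigma^2$ inflation,
which the recovery tests account for).

What the generator does **not** emulate: withdrawals and missing passages,
weather and course-condition shocks shared across runners, rank-dependent
pacing tactics, repeat participation across editions, and any sex
difference beyond field composition (none was observed in the cohort the
defaults mirror). Passing tests therefore validate the pipeline's
arithmetic and statistical behaviour under the assumed structure, not its
fit to any particular real cohort.

`simulate_linear_tt()` overwrites the finish time with a known linear
combination of one segment's features plus Gaussian noise (clamped, with a
warning, to stay after the last checkpoint) and is the parameter-recovery
harness: at noise SD 0.3 h on a 900-runner pooled field the refitted
coefficients land within 3 SE of truth with adjusted $R^2 > 0.95$, and at
zero noise recovery is exact to 1e-8.

## Numerical choices and problem sizes

- Ties at checkpoints take the mean rank; the quartile boundary is
  inclusive (both documented above).
- 2-decimal rounding uses R's `round()`; no published coefficient sits on
  a representation tie.
- Degenerate inputs (zero-variance differences, constant samples, perfect
  collinearity, all-zero residuals) return flagged results or errors rather
  than silent numbers.
- Test problem sizes: full 947-runner fields for structure checks; 100–900
  runners for recovery; 2000 simulated null datasets (1000 resamples each,
  25 per group) for type-I calibration of the bootstrap test, whose
  rejection rate at $\alpha = 0.05$ must lie in [0.03, 0.07]; $10^5$
  Monte-Carlo replicates for the power oracle. The bootstrap internals are
  vectorised so the whole suite runs in well under a minute.

## Known limitations

The regression models are purely observational and race-specific: the
closed-form coefficients transfer to other events only insofar as terrain
difficulty scales the same way. Percentile ranks computed mid-race on a
partial field differ from retrospective pooled ranks. The difficulty factor
ignores altitude, technicality and surface. And since the original cohort's
split table is not redistributable, cohort-level coefficient tables are
validated structurally (via the generator) rather than reproduced
numerically.
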