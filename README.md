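# trailpace

Terrain-weighted pacing analysis and real-time finish-time prediction for
mountain trail races.

Trail-running performance models usually need laboratory testing or pre-race
athlete data, which makes them impractical on race day. `trailpace`
implements an alternative built entirely from in-race quantities — checkpoint
split times and live rankings — for races timed over sections of alternating
net slope. It is aimed at sports scientists and coaches analysing official
split tables, and at anyone who wants a tested reference implementation of
the underlying feature definitions and regression methodology.

## The model

A race with total distance *d* (km), accumulated ascent *S⁺* and descent
*S⁻* (m) has uphill and downhill **difficulty factors**

&nbsp;&nbsp;&nbsp;&nbsp;IDF⁺ = d + S⁺/100,&nbsp;&nbsp;&nbsp;IDF⁻ = d + S⁻/100,

and each timed section *n* (between two checkpoints) has the analogous
section-level factor IDF±ₙ computed from its own distance and net-slope
elevation. The section's **relative difficulty coefficient**

&nbsp;&nbsp;&nbsp;&nbsp;IRDCₙ = IDF±ₙ / IDF±

is its share of the race's total difficulty of the same slope sign. Three
per-runner features follow:

- **Weighted time** WTₙ = Tₙ / IRDCₙ — the raw section time Tₙ (hours)
  extrapolated to whole-race scale; under perfectly even effort every WTₙ
  equals the finish time.
- **Weighted-time variability** WTVₙ,ₙ₊₂ = WTₙ₊₂/WTₙ − 1 — the relative
  change between two *same-slope* sections consecutive in terrain order
  (skipping the opposite-slope section between them); positive values mean
  slowing on comparable terrain.
- **Checkpoint percentile rank** CPRₙ — the runner's ascending-rank fraction
  (rank/field, fastest = 1/n) in the pooled field at checkpoint *n*.

Finish time TT is modelled per terrain segment by ordinary least squares
with all three predictors entered simultaneously,

&nbsp;&nbsp;&nbsp;&nbsp;TT = B₀ + B₁·WTₙ + B₂·WTVₙ,ₙ₊₂ + B₃·CPRₙ + ε,

with a full diagnostic battery (Durbin–Watson, VIF, Cook's-distance and
±3 SD case screening, Bland–Altman agreement). Substituting the feature
definitions into a fitted ascent model yields a closed-form predictor in raw
split times that can be evaluated mid-race at the segment's closing
checkpoint.

Group comparisons (race modality, sex, performance quartile) use paired and
independent t-tests with bootstrap p-values (1000 centred resamples),
Cohen's d effect sizes and post hoc power.

Because official split tables are rarely redistributable, the package ships
a synthetic race generator (`simulate_field()`, `simulate_linear_tt()`) that
reproduces the statistical structure the analysis assumes — difficulty-
proportional section times, same-slope fatigue drift, pooled two-modality
fields — so every pipeline stage runs and is tested without external data.

## Worked example

```r
library(trailpace)

summarize_course(course_4k(), rounding = "paper")
#> <difficulty_summary> 4K (IDF+ 77.0, IDF- 82.0, paper precision)
#>   index start_cp end_cp net_slope idf_section  irdc
#> 1     1 cp0      cp1    positive         20.5  0.27
#> 2     2 cp1      cp2    negative         17    0.21
#> 3     3 cp2      cp3    positive         12    0.16
#> 4     4 cp3      cp4    negative         11    0.13
#> 5     5 cp4      cp5    positive          9    0.12
```

The five shared sections of the built-in 42 km course carry 27%, 21%, 16%,
13% and 12% of the race's slope-matched difficulty. Simulate a two-modality
field, build features, and fit the first-ascent segment model:

```r
cfg      <- synthetic_config(seed = 2017)        # 764 + 183 runners
splits   <- simulate_field(cfg)
features <- build_feature_table(splits, quiet = TRUE)
fit_segment_model(features, segment = "ascent1")
#> <segment_fit> ascent1: n = 932, R2 = 0.9748 (adj 0.9747), SEE = 0.585 h
#>   Durbin-Watson = 2.078; VIF: WT_1 1.60, WTV_13 1.11, CPR_1 1.74
#>   excluded 15 influential/outlier case(s)
#>   term         B      SE     t         p    ll    ul   beta
#> 1 constant 1.69  0.0719   23.5 5.40e- 96 1.55  1.83  NA
#> 2 WT_1     0.874 0.00623 140.  0         0.862 0.886  0.926
#> 3 WTV_13   3.57  0.138    25.9 5.14e-112 3.30  3.84   0.143
#> 4 CPR_1    1.48  0.0882   16.8 2.48e- 55 1.31  1.65   0.115
```

The weighted time dominates (standardized β ≈ 0.93), pacing variability and
rank add smaller positive contributions, and the diagnostics are clean
(DW ≈ 2, all VIF < 10). A mid-race prediction for a 42 km runner who climbed
section 1 in 2 h, section 3 in 1.6 h and passed the first checkpoint ranked
100th of 764, using the published segment coefficients:

```r
predict_tt(paper_model("ascent1"), course_4k(),
           t_first = 2.0, t_second = 1.6, rank = 100, field_size = 764)
#> [1] 9.649067   # hours, i.e. about 9:39
```

`expand_closed_form()` turns any ascent model into the equivalent explicit
formula over raw split times:

```r
expand_closed_form(paper_model("ascent1"), course_8k())
#> <closed_form> 8K / ascent1 (paper coefficients, paper-precision IRDC)
#>   TT = 0.914 * T1/0.14 + 4.993 * ((T3/0.08)/(T1/0.14) - 1) + 1.468 * rank/n + 0.939
```

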