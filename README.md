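# heteropower

Sampling designs and statistical power for heterogeneous wearable
heart-rate cohorts.

## The problem

Nightly sleeping heart rate (HR) from wearables has small night-to-night
variability within a person (SD of roughly 1–3 bpm) but large differences
between people (normal resting HR spans roughly 50–90 bpm). A naive
cross-sectional comparison — pool everyone's weekend nights against
everyone's weekday nights — buries a bpm-scale weekly effect under the
between-person spread, and on top of that the *direction* of the weekend
effect differs across people, so opposing responders partially cancel.

`heteropower` quantifies what each level of experimental control buys. Its
central statistic is the **significance onset**: stream weekend/weekday HR
pairs one at a time, test cumulatively after each pair with a two-sided
nonparametric test, and record the first sample size `k` at which
`p < α`, together with Cliff's delta

```
δ = [ #{(i,j): x_i > y_j } − #{(i,j): x_i < y_j } ] / (|x|·|y|)
```

computed on everything up to and including that pair. Four cohort-wide
designs (random, temporal, person-matched, temporal person-matched — the
unpaired ones tested with the Mann–Whitney U, the matched ones with the
Wilcoxon signed-rank) and three within-individual designs (pooled,
temporal, sequential; always signed-rank, one pair per valid week) are run
over many replicated datasets, and the onset and δ distributions are
compared across designs. A Monte-Carlo power analysis over a grid of
Cliff's δ and target power puts the empirical ratios in closed-form
context (Noether's approximation
`n ≈ (z_{1−α/2} + z_β)² / (6 (p − ½)²)` with `p = (δ+1)/2` for the
unpaired test).

Because raw wearable datasets of this kind are not generally
redistributable, the package ships a calibrated synthetic-cohort generator
(`generate_cohort()`) that reproduces the statistical structure the
analysis depends on: between-individual baseline spread, small
within-individual nightly noise, a seasonal decline, heterogeneous
quartile-structured weekend effects, rolling enrollment and per-night
missingness — with the full per-participant ground truth attached for
parameter-recovery testing.

It is aimed at researchers designing longitudinal wearable studies who
need to know how many participants — or how many weeks of one participant —
a within-subject contrast requires.

## Worked example

```r
library(heteropower)

# a calibrated cohort at reduced scale: 300 individuals, 41 weeks
cohort <- generate_cohort(generator_params(n_individuals = 300, seed = 42))
#> <night_cohort> 41174 nights, 300 participants, window 2020-01-06 .. 2020-10-18

# heterogeneous weekend effects: quartiles of mean weekend − weekday HR
quartile_stratify(cohort)$quartile_summary
#>   quartile     n median      q1     q3
#> 1        1    75 -0.730 -1.23   -0.447
#> 2        2    75  0.297  0.0777  0.515
#> 3        3    75  1.28   1.00    1.56
#> 4        4    75  3.15   2.84    3.67
```

The quartile medians recover the generator's calibration (−0.50, +0.38,
+1.25, +3.19 bpm): a quarter of the cohort has *higher* weekday HR.

```r
cm <- run_cohort_methods(cohort, n_runs = 20, alpha = 0.01, seed = 42)
cm$summary[, c("method", "median_onset", "median_delta", "n_censored")]
#>   method                  median_onset median_delta n_censored
#> 1 random                         113         0.200          17
#> 2 temporal                       133         0.205          16
#> 3 person_matched                  64.5       0.0831          0
#> 4 temporal_person_matched         80         0.0732          0
```

With only 300 pairs available, 17 of 20 random-sampling runs exhaust the
whole cohort without ever reaching `p < .01` (they are censored; the
median shown is over the lucky runs). Person-matching reaches
significance in every run.

```r
sw <- run_within_cohort(cohort, n_runs = 100, alpha = 0.01, seed = 42)
aggregate_within(sw)
#> <within_aggregate> 225 of 300 individuals kept (significant under all modes)
#>   mode       n_individuals median_onset onset_q1 onset_q3 median_delta
#> 1 pooled               225           12      9.5       16        0.534
#> 2 temporal             225           12      9         16        0.503
#> 3 sequential           225           12      9         18        0.530
```

Within a single individual, a median of **12** weekend/weekday pairs
suffices, at a median effect size of δ ≈ 0.5 — several times the
cohort-wide δ of ≈ 0.1 — because the test no longer fights
between-person baseline spread or cross-person effect cancellation.

```r
required_pairs("unpaired", delta = 0.10, power = 0.80, alpha = 0.01,
               reps = 1000, seed = 42)
#> <power_cell> unpaired test, delta = 0.10, power = 0.80, alpha = 0.01: n = 768
required_pairs("unpaired", delta = 0.50, power = 0.80, alpha = 0.01,
               reps = 1000, seed = 43)
#> <power_cell> unpaired test, delta = 0.50, power = 0.80, alpha = 0.01: n = 30
```

The simulated power analysis says the same thing prospectively: detecting
δ = 0.10 needs ~26× more pairs than δ = 0.50 at the same power.

`run_all(run_config(...))` chains every stage (generation, filters,
variability descriptives, both sampling families at α = .01 and .05,
method comparisons, the power grid) into one deterministic, seeded report
bundle written as JSON + tidy CSVs.

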