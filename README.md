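# richtrend

Differential richness inference for 16S rRNA (OTU/ASV) surveys with an
explicit control for the abundance-dependent accumulation of spurious taxa.

## The problem

In marker-gene surveys, error-derived read clusters ("false taxa")
accumulate at a rate that increases with the recovered abundance of their
true source. Observed richness — and asymptotic estimates built on it
(Chao1, ACE) — therefore rises with read counts for purely technical
reasons, and between-group richness comparisons are confounded by
between-group *differential abundance*. `richtrend` is for microbiome
researchers who want richness contrasts that are not artifacts of
composition or depth shifts.

## The method

1. **Technical trend.** On detected within-genus cells, log observed
   richness is modeled as

   `z_gj = κ + f_R(log y_gj) + f_G(g) + ε`,

   with `f_R` a penalized cubic smoothing spline in log recovered
   abundance (smoothing parameter by GCV) and sum-to-zero genus effects
   kept only if they survive Benjamini–Hochberg correction. The fitted
   control is `f̂_t(g, log y) = κ̂ + f̂_R(log y) + f̂_G(g)`. A pooled loess
   alternative is included.

2. **Differential richness.** The control enters count GLMs as a
   covariate/offset:
   - genus level (Poisson):
     `log E[n_gj] = X_jᵀ μ_g + ν_g f̂_t(g, log y_gj)` (ν_g = 1 by default);
   - sample-wide (negative binomial):
     `log E[n_+j] = X_jᵀ ζ + γ log Σ_{g detected} exp(f̂_t(g, log y_gj))`;
   - arbitrary genus collections, which reduce exactly to the sample-wide
     model when the collection is everything.

   Bootstrap-t intervals (trend refit per resample) are available for
   sample-wide and collection contrasts.

3. **Baselines and diagnostics.** Chao1/ACE with standard errors,
   inverse-variance weighted meta-regression of log asymptotic estimates,
   confounding reports (richness-LFC vs abundance-LFC correlation),
   McFadden pseudo-R²/AIC model comparisons, sub-genus replicability
   summaries, and a synthetic-survey generator with known ground truth.

## Worked example

```r
library(richtrend)
library(dplyr)

sv    <- null_richness_confounding_scenario(n_per_group = 15, G = 30,
                                            depth = 2e4, seed = 7)
agg   <- survey_aggregate(sv)     # per-(genus, sample) richness n and abundance y
X     <- survey_design(sv)        # intercept + groupB
trend <- fit_trend(agg)
trend
#> <trend_fit> spline | n = 900 | lambda = 1.664 | edf = 34.56 | sigma2 = 0.02175
#>   genus effects: 30 tested, 0 retained (BH <= 0.05)

dr <- genus_differential(agg, trend, X) |> filter(term == "groupB")
da <- differential_abundance(agg, X)    |> filter(term == "groupB")
confounding_diagnostic(dr, da)
#>       r conf.low conf.high p.value n_pairs n_dropped method
#>  0.0580   -0.309     0.410   0.761      30         0 pearson
```

This survey was generated with *no* true richness differences but strong
per-genus abundance fold changes; the trend-controlled richness contrasts
are uncorrelated with the abundance contrasts (r ≈ 0.06). Running the same
diagnostic with per-genus Chao1 estimates through the weighted-regression
route gives r ≈ 0.9: the classical route mistakes abundance shifts for
diversity shifts. The sample-wide contrast is likewise null:

```r
samplewide_differential_richness(agg, trend, X) |> tidy()
#>   term        estimate     se statistic p.value conf.low conf.high
#> 1 (Intercept)  107.    55.2        1.94   0.052    -1.04   216.
#> 2 groupB        -0.616  0.323     -1.90   0.057    -1.25     0.018
#> 3 trend        -16.0    8.77      -1.83   0.068   -33.2      1.17
```

(`estimate` for `groupB` is the natural-log fold change of sample-wide
observed richness; here it is not distinguishable from zero.) Estimators:

```r
chao1(c(1, 1, 2, 3, 5))
#>  estimator estimate    se variant undefined
#>  chao1            7  3.74 classic FALSE
```

A thin command-line front-end (`inst/cli/richtrend`) exposes `simulate`,
`fit-trend`, `dr-genus`, `dr-sample`, `dr-collection`, `richness`,
`diagnose`, and `run` subcommands over the same functions.

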