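---
title: "Differential richness inference with an abundance-dependent technical control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential richness inference with an abundance-dependent technical control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richtrend)
library(dplyr)
```

## The problem

Marker-gene (16S rRNA) surveys report community richness as the number of
distinct OTUs/ASVs detected. A substantial fraction of sub-genus read
clusters are spurious — artifacts of amplification and sequencing error —
and, critically, they do not appear at a fixed rate: the more reads a true
source sequence recovers, the more distinct error-derived clusters it
spawns. Observed richness therefore grows with recovered abundance for
purely technical reasons. Any between-group comparison of richness
(observed, or asymptotic via Chao1/ACE) is then confounded by between-group
*differential abundance*: a taxon that merely becomes more abundant in one
group appears to become more "diverse" there.

`richtrend` addresses this by (i) estimating the within-genus
taxa-accumulation trend as a function of log recovered abundance, and (ii)
using the fitted trend as a covariate in count regressions for differential
richness, at genus, collection, and whole-sample level.

## The accumulation model

For genus $g$ in sample $j$ let $n_{gj}$ be the number of detected member
taxa and $y_{gj}$ the genus's total read count. On detected cells
($n_{gj}\ge 1$) the log richness $z_{gj}=\log n_{gj}$ is modeled
semi-parametrically:

$$ z_{gj} = \kappa + f_R(\log y_{gj}) + f_G(g) + \varepsilon_{gj},
\qquad \varepsilon_{gj}\sim N(0,\sigma^2), $$

where $f_R$ is a cubic B-spline penalized by its integrated squared second
derivative and $f_G$ are unpenalized genus effects under a sum-to-zero
constraint. The penalized least-squares problem is solved over a 40-point
log-spaced grid of smoothing parameters spanning $10^{-4}$–$10^{4}$ times a
scale heuristic, with $\lambda$ chosen by generalized cross-validation and
ties broken toward the smoother fit. Genus effects are Wald-tested against
zero (treating $\lambda$ as fixed) and only effects surviving
Benjamini–Hochberg correction at $\alpha_G = 0.05$ are retained in the
evaluated control

$$ \hat f_t(g, \log y) = \hat\kappa + \hat f_R(\log y) + \hat f_G(g). $$

A pooled loess smooth (span 0.75, no genus effects) is available as an
alternative; the two agree closely when genus effects are null. Evaluation
outside the observed abundance range clamps to the boundary (constant
extrapolation), since the spline has no information there. Interaction
terms between genus and abundance can be added for diagnostics but never
enter $\hat f_t$: the control deliberately uses the additive form.

Cells with $n_{gj}=0$ are excluded (the response is a log count of detected
taxa; no pseudo-count is added). Knots sit at quantiles of the observed
log abundances, capped at 30 interior knots. All logarithms are natural.

## Differential richness models

With $X_j$ the design row for sample $j$:

* **Genus-specific** (Poisson, log link, samples where the genus is
  detected): $\log E[n_{gj}] = X_j^T\mu_g + \nu_g\,\hat f_t(g,\log y_{gj})$.
* **Sample-wide** (negative binomial, ML dispersion):
  $\log E[n_{+j}] = X_j^T\zeta + \gamma\,\log\sum_{g:\,y_{gj}>0}
  e^{\hat f_t(g,\log y_{gj})}$.
* **Collections**: as sample-wide but with response and covariate restricted
  to a genus set $G_k$; with the full set this reduces *exactly* to the
  sample-wide model, and with a singleton set the covariate equals the genus
  trend value.

Fitting uses R's IRLS (`glm`, `MASS::glm.nb`); the NB fit falls back to
Poisson when the profiled dispersion is numerically zero (below $10^{-8}$).
Wald tests and intervals are reported per coefficient; across genera,
p-values are BH-adjusted within each coefficient family.

### Why $\nu_g$ defaults to 1

The genus-level trend coefficient $\nu_g$ can be estimated freely, and on
data with a wide within-genus abundance spread it is recovered near 1. But
the group-contrast error of the free-$\nu$ fit is approximately
$-(\hat\nu_g-1)\,\Delta\hat f_{t,g}$, where $\Delta\hat f_{t,g}$ is the
between-group difference in the trend covariate — itself proportional to
the genus's abundance fold change. When the within-genus abundance spread
is small (similar library sizes, stable compositions), $\hat\nu_g$ is
weakly identified, and its sampling error re-introduces exactly the
abundance-aligned artifact the control exists to remove: in our null
simulations the correlation between genus richness and abundance fold
changes stays below 0.2 in only ~74% of replicates with free $\nu$, versus
essentially always with $\nu$ pinned. Since applications typically find
$\nu_g\approx 1$, the genus model uses the trend as an offset by default;
`offset_trend = FALSE` frees the coefficient (useful as a diagnostic that
$\hat\nu_g \approx 1$ holds on your data). The sample-wide $\gamma$ is well
identified (its covariate varies across all samples) and remains free.

### What the models estimate

The group coefficients are log fold changes of *expected observed richness
given the technical control*. When spurious taxa are a non-trivial additive
share of observed counts, a fold change $\rho$ in true richness appears on
the observed scale as $(\rho T + F)/(T+F)$, attenuated toward 1. Inference
about true-richness fold changes is therefore most faithful for well
expressed, well sampled genera where the spurious share is modest — the
same regime in which observed and asymptotic richness track each other.

## Classical estimators and the comparison route

`chao1()` implements the classic estimator $S_{obs} + f_1^2/(2f_2)$ with
its classical variance, switching to the bias-corrected form
$S_{obs}+f_1(f_1-1)/(2(f_2+1))$ when no doubletons exist; the variant is
recorded because the standard errors feed the inverse-variance weighted
regression (`weighted_meta_regression()`), which analyzes log estimates
with delta-method SEs so its coefficients share the GLMs' fold-change
scale. The weighted regression uses fixed-effect weights $1/SE^2$ and
covariance $(X^TWX)^{-1}$; cells with zero or undefined estimates or SEs
are dropped and counted. `ace()` implements the abundance-based coverage
estimator with rare/abundant cutoff 10 (configurable); when every rare
taxon is a singleton the coverage is zero and the cell is flagged undefined
rather than imputed.

## Bootstrap-t intervals

For sample-wide and collection models, `bootstrap_t_ci()` resamples samples
with replacement within design cells, refits the trend on each resample
(holding the knots and the GCV-selected $\lambda$ fixed — $\lambda$ is
treated as a tuning constant, which keeps the procedure stable and fast),
refits the GLM, and forms the percentile-$t$ interval from the studentized
pivots. Runs are reproducible bit-for-bit given `seed`; more than 10%
resample failures abort with a tally.

## The synthetic-survey generator

`simulate_survey()` embodies the hypothesized mechanism with known truth:

1. true-taxon counts are a single multinomial of size $\tau_j$ over all
   true taxa (genus composition × within-genus profile, group-adjusted);
2. false-taxon *counts* per genus follow
   $F_{gj}\sim\text{Poisson}(\alpha\,y_{gj}^\beta)$ — abundance-dependent,
   not depth-dependent;
3. false-taxon *identities* are drawn without replacement from a per-genus
   pool of size $M_g$, so a larger pool means less replicable artifacts;
4. each false taxon receives $1+\text{Binomial}(3, 0.1)$ reads moved from
   the genus's true taxa (total capped at $y_{gj}/2$; infeasible demand is
   truncated with a warning), so genus totals and sample depths are
   conserved exactly. A read-creation mode exists for sensitivity analysis.

Defaults describe the study conditions used throughout the tests: 60
genera, 30 samples per group, depth $5\times10^4$, $\alpha=0.01$,
$\beta=1$. Quantities the mechanism does not pin down were fixed once at
values realistic for 16S genus structure: per-genus true richness uniform
on 10–40, geometric within-genus profiles (ratio 0.6) over a log-normal
genus composition (SD 1 on the log scale), and an identity pool of
$M_g=1000$ (large enough that the pool never binds the Poisson mean, as the
configuration contract requires). `null_richness_confounding_scenario()`
wraps the null-richness case with heterogeneous
($N(0,\log 4/2)$), asymmetric (exponential with mean $\ln 2$), or absent
abundance fold changes.

The generator emulates abundance-dependent spurious accumulation, partial
detection, and compositional closure. It does not emulate chimera
formation, per-nucleotide error chains, taxonomic misannotation, or
real-data features like batch effects — so passing tests demonstrate
control of the modeled mechanism, not of every artifact in real surveys.

## Verification scale and numerical choices

The test suite runs the full pipeline at the study conditions above: the
confounding contrast over 50 seeded surveys; genus-level type-I error over
200 genus fits; recovery of a $\ln 2$ richness fold change over 200
model-generated replicates (and, under the raw mechanism, in a
detection-complete scenario of 40 equally abundant genera at depth 8000
with even profiles, where the estimand is observable); and bootstrap-t
coverage over 200 outer × 199 inner replicates on reduced surveys (20
genera, 12+12 samples, depth $10^4$). These sizes were chosen so the whole
suite runs on a single CPU in well under half an hour while keeping Monte
Carlo error small relative to the asserted margins.

Numerical choices: IRLS tolerance $10^{-8}$ on deviance with at most 50
iterations; spline systems solved by Cholesky with a QR fallback;
rank-deficient designs are an error naming the offending columns; genus
fits require detection in at least 5 samples, genus effects at least 3
cells; GCV ties resolve to the larger $\lambda$; "detected" means a count
strictly greater than zero, with no minimum-abundance filter (any such
filter is explicit preprocessing). Sample depths are computed from the full
input table before any filtering and frozen thereafter. Taxa without genus
annotation are pooled into one pseudo-genus per parent family
(`unassigned@<family>`) so depth conservation holds; a drop mode exists.

## Known limitations

* The additive false-taxa mechanism bounds what group coefficients can mean
  on the observed scale (attenuation at high spurious share); the package
  reports observed-scale fold changes and leaves asymptotic extrapolation
  to the estimator battery.
* The spline control assumes a shared abundance-richness shape across
  genera after additive genus effects; strongly genus-specific accumulation
  slopes are visible via the interaction diagnostic but are not controlled
  for.
* Tree-structured multiple testing across the taxonomy and joint estimation
  of the trend with the fold changes are out of scope.

## A worked example

```{r example, eval = FALSE}
sv <- null_richness_confounding_scenario(n_per_group = 15, G = 30,
                                         depth = 2e4, seed = 7)
agg <- survey_aggregate(sv)
X <- survey_design(sv)
trend <- fit_trend(agg)
autoplot(trend)

dr <- genus_differential(agg, trend, X) |> filter(term == "groupB")
da <- differential_abundance(agg, X) |> filter(term == "groupB")
confounding_diagnostic(dr, da)   # |r| should be small: richness contrasts
                                 # are not driven by abundance contrasts
samplewide_differential_richness(agg, trend, X) |> tidy()
```
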