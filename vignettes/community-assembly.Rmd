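---
title: "Inferring internal and external assembly filters from individual-level traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring internal and external assembly filters from individual-level traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitfilter)
```

## The model

The unit of observation is an individual with one or more positive,
ratio-scale trait values (body mass, wing loading, wing aspect ratio in the
motivating hawkmoth application). Individuals nest into populations (all
conspecifics within one community), populations into communities, and
communities into a regional pool. All analyses run on a long-format tibble,
one row per individual (`trait_table()`), so that every grouping level is a
grouping of the same rows.

T-statistics are variance ratios across those scales, computed per
community and per trait on natural-log traits:

* `T_IP_IC = sigma2_IP / sigma2_IC`: `sigma2_IP` is the *unweighted* mean,
  over species with at least two measured individuals, of the
  within-population sample variance; `sigma2_IC` is the sample variance of
  all the community's individuals.
* `T_IC_IR = sigma2_IC / sigma2_IR`, with `sigma2_IR` the sample variance of
  all individuals in the region.
* `T_PC_PR = sigma2_PC / sigma2_PR`, the same contrast on population means;
  a population here is a species-by-community pair, so a species occurring
  in k communities contributes k means to the regional pool of population
  means.

Conventions that the ratios depend on, and why we chose them:

* **Sample variance (n − 1) throughout.** Applied uniformly to all five
  components, so numerator and denominator share the convention and the
  ratios stay comparable across communities of different sizes.
* **Unweighted species averaging in `sigma2_IP`.** "Averaged over all
  species" is read literally; species with fewer than two measured
  individuals contribute nothing (neither a zero nor a pseudo-variance).
  Undefined components propagate as `NA`, never as 0. The abundance-weighted
  alternative would collapse `T_IP_IC` toward the dominant species' niche
  width; the unweighted mean treats the species, not the individual, as the
  unit whose niche width is in question.
* **Natural logs.** The transform removes mean–variance scaling; the base is
  immaterial because any base change rescales every variance by the same
  constant, which cancels in each ratio (a property the test suite asserts).
* **Pairwise-complete missingness.** Each trait is analyzed on the
  individuals measured for it; records with one missing trait still
  contribute their other traits and their abundance.

A single-species community has `T_IP_IC = 1` by construction; a community
where every species is internally constant has `T_IP_IC = 0`. The law of
total variance ties the components together: under the n-divisor convention
the community variance is exactly the abundance-weighted mean of
within-species variances plus the abundance-weighted variance of species
means, and the (n − 1) pipeline is checked against a brute-force oracle to
machine precision in the tests.

## Null models and standardized effect sizes

Each ratio is compared with the randomization that breaks exactly the
association it measures, leaving everything else fixed (`null_schemes()`):

| metric | randomization | conserves |
|---|---|---|
| `T_IP_IC` | shuffle species labels within each community | each community's trait multiset and per-species abundances |
| `T_IC_IR` | permute community labels over pooled individuals | community sizes, regional trait multiset |
| `T_PC_PR` | permute community labels over population means | per-community population counts, pool of means |

All three are permutations, i.e. sampling without replacement within an
iteration, so the conserved quantities are conserved exactly (asserted on
every iteration in the test suite). `tstat_ses()` computes, per community ×
trait × metric, `SES = (I_obs − mean(I_null)) / sd(I_null)` and a two-sided
95% envelope from the 2.5% and 97.5% quantiles of the null metric draws,
flagging observations outside the envelope. We default to 999 iterations;
envelope and SES come from the same null sample, and significance is
decided on the metric envelope (SES is descriptive of effect size).
Iterations on which a metric is undefined are dropped and counted; a null
distribution with zero spread yields `ses = NA` rather than an infinity.

Two numerical choices deserve note. First, RNG streams are derived
arithmetically from the master seed per (trait, scheme), so results do not
depend on which traits or metrics are requested together; communities
within one scheme share each iteration's permutation, as they must — under
the regional schemes the randomized communities partition one pool and are
not independent. Second, the individual-level regional null does not
conserve species richness, only community size: randomized communities mix
individuals of many more species than a species-poor community holds, which
biases that community slightly below the null mean even without any
filtering. The variant `regional_null = "populations"` reassigns whole
populations instead, conserving richness at the cost of letting sizes
fluctuate; the default remains the size-conserving scheme, which is the
conventional choice.

## Community-level trait metrics

* **CWM** (`cwm()`): `CWM_k = sum_i a_ik t_ik` with `a_ik` the share of
  community k's individuals belonging to species i. The local mode uses
  within-community species means (ITV included in the species means); the
  regional mode uses region-wide species means. CWM is computed on the raw
  trait scale — the log transform is a device for variance ratios, and a
  community's mean body mass is most interpretable in grams. Comparing the
  two modes' elevational slopes (`compare_slopes()`) asks whether including
  ITV changes the inferred gradient response; the z statistic uses the
  one-sided normal tail `p = pnorm(-|z|)`, the convention that reproduces
  the worked pair z = 0.43, p ≈ .33.
* **Kernel-density overlap** (`trait_kde()`, `kde_overlap()`): each
  community's trait distribution is an unweighted Gaussian KDE over its
  individuals — every individual is one kernel, so ITV enters directly and
  abundant species contribute proportionally many kernels. Bandwidth is
  Silverman's rule per community, overridable (a fixed bandwidth is also
  what makes densities of duplicated datasets exactly equal, and is
  required when a community has zero trait variance). All communities are
  evaluated on one grid: the pooled regional range extended by three pooled
  bandwidths, at ≥ 512 points, so the pairwise overlap — the trapezoidal
  integral of the pointwise minimum, a number in [0, 1] — is well defined.
  Densities are not truncated at observed trait bounds; the common-grid
  extension keeps the lost tail mass below the 1e-3 normalization
  tolerance. The decay of overlap with elevational distance
  (`overlap_decay()`) is the package's functional beta-diversity gradient
  statistic.
* **Rarefaction** (`rarefaction()`, `rarefied_richness()`): taxonomic
  curves use the analytic hypergeometric expectation (via `vegan::rarefy`,
  cross-checked against exhaustive enumeration in tests); richness entering
  regressions is rarefied to the smallest community's individual count.
  Functional curves report the mean community trait variance over
  subsamples of m individuals drawn without replacement — variance is the
  trait-space size statistic used throughout this package, making the curve
  interpretable as "how fast does occupied trait space saturate with
  sampling effort"; it is an approximation to, not a reimplementation of,
  any particular published functional-rarefaction statistic.

## Gradient analyses

`ols()` wraps `stats::lm` for the one-predictor regressions of Table-style
outputs (`metric_regressions()`): each metric × trait against elevation and
rarefied richness, two-sided t-tests on slopes, significance annotated at
p < .1 and p < .05, no multiple-testing correction (none is conventional
for these descriptive tables). `env_pca()` standardizes the four
environmental covariates (MAT, APPT, EVI, AD) and orients PC1 to correlate
positively with elevation — the sign is arbitrary in PCA, and fixing it
makes PC1 a reproducible "elevation-like" composite. Elevation itself,
not PC1, is the default gradient predictor: it is measured, comparable
across studies, and in the motivating system correlates with PC1 at
R² > 0.95, whereas a phenomenological composite is unique to each study.

## The synthetic-data generator

`sim_scenario()`/`simulate_communities()` generate trait tables with known
filter strength. The generative model is: regional species log-mean traits
drawn from a normal per trait; a community trait optimum shifting linearly
with elevation; admission of a fixed number of species per community by
weighted sampling without replacement with Gaussian kernel weights of width
`w_ext` (infinite width = uniform random subsets); deterministic greedy
thinning so admitted species means are at least `limiting_similarity_gap`
apart (the internal filter); log-series abundances scaled to the community
size target (uniform abundances available as an oracle-friendly switch);
and log-normal individuals around species means with SD `within_sd`.
Log-normal traits guarantee positive support and match the log-transform
pipeline; the Gaussian admission kernel is the standard niche-filtering
form; greedy thinning is chosen over stochastic rejection for determinism
under a seed.

The defaults emulate the motivating study's design: 13 communities from
200 to 2770 m, 80 regional species, ~254 individuals per community (~3,300
in all), three traits whose variance structure reproduces the reported
regime — regional log-trait variances near 3.7e-2, 1.0e-2 and 0.21e-2 and
mean within:community ratios near 0.22, 0.56, 0.54 (within-species SD
47–75% of community SD). Because log-series dominance shrinks the realized
abundance-weighted between-species variance inside a community, the
(`within_sd`, `between_sd`) defaults were calibrated against the *realized*
statistics of simulated regions rather than set to the naive
`T = sw²/(sw² + sb²)` split; the calibrated defaults recover the target
regime to within Monte-Carlo noise (about ±0.04 on a mean ratio across
regions). `within_sd` and `between_sd` accept per-trait vectors because no
single within-species SD can reproduce both the per-trait ratios and the
per-trait regional variances.

Two structural facts about the model matter when designing experiments
with it. An external filter is only *detectable* (via `T_IC_IR`) when the
optimum varies across communities: a filter common to all communities
narrows the realized regional pool identically and leaves communities
exchangeable with the region. And because each community admits a fixed
number of species, a very narrow kernel saturates — once the near-optimum
species are exhausted the remaining admissions are effectively uniform —
so sweeps over `w_ext` should keep the admitted fraction of the pool
modest. `parameter_sweep()` packages the simulate → T-statistics → SES
loop for calibration and power analyses.

What the generator does *not* emulate: phylogenetic correlation of species
means, spatial dispersal limitation, detection bias toward large or
flight-active individuals, trait measurement error, and within-species
trait–elevation clines (a species' mean is constant across the communities
it occupies). Passing tests on synthetic data therefore validate the
statistical machinery — calibration of the nulls, monotone response of SES
to the filters, parameter recovery — not the ecological fidelity of any
particular field dataset.

## Missing-trait imputation

Field datasets routinely contain individuals identified to species whose
traits could not be measured. `impute_missing_traits()` adds such
individuals by drawing complete trait vectors uniformly, with replacement,
from measured conspecifics in the same community — whole vectors rather
than independent per-trait draws, preserving within-individual trait
correlations. Imputed records are flagged, populations without donors are
an error, and imputation never introduces a trait value absent from the
donor population. Whether imputed individuals should enter null models or
only summary statistics is left to the analyst; the flag makes either
choice a one-line filter.

## Problem sizes and runtime

The test suite and the acceptance script run everything at sizes chosen to
finish in minutes on one CPU while keeping Monte-Carlo noise within the
asserted tolerances: null-model calibration uses 40–60 replicate regions of
4 communities × 6 species at 199 iterations (240 envelope decisions per
metric); filter-monotonicity sweeps use 6 communities × 40 species at 149
iterations and 4 replicates per grid cell; study-scale checks simulate full
~3,300-individual regions, averaging over 6–16 seeds where a mean is
asserted. The permutation engine computes grouped variances via `rowsum`
on pre-built factors, which keeps 999-iteration runs on a 3,300-individual
table around a second per community-set × trait × scheme.

## Known limitations

Single-trait analysis only: no multivariate or hypervolume T-statistics
(each trait is decomposed independently, and a species that overlaps
broadly on every single axis may still segregate in the joint trait
space). No phylogenetic correction, no abundance-weighted null models, no
spatial autocorrelation structure in either the statistics or the
generator. Regression machinery is deliberately linear — higher-order
gradient shapes (e.g. mid-elevation troughs) are visible in plots but not
fitted.
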