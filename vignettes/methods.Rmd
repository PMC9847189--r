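---
title: "Methods: neighborhood food-environment inequality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood food-environment inequality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedure the package implements, the
choices that were genuinely open when it was designed, and what the synthetic
validation does and does not establish. It is the package's methodological
reference; the README shows the user-facing workflow.

## The ecological design

The unit of analysis is the neighborhood, an aggregate of census tracts, and
the row unit of every output table is the school, which inherits all of its
neighborhood's categories. The design is purely ecological: no school-level
exposure is measured, and all inference is about the neighborhoods schools
sit in, not about students. Three inequality measures and two
food-environment flags are computed per neighborhood, and school-level
prevalences are compared across strata with Pearson chi-square tests.

## Aggregation from tracts

`aggregate_tracts()` sums population and total income, so per-capita income
is a ratio of sums. Two different pooling rules coexist deliberately:

* the Gi* input — the proportion of household heads earning 0–3 minimum
  wages — is **pooled** (sum of numerators over sum of denominators), so
  large tracts weigh more;
* the three deprivation indicators are computed per tract and **averaged
  unweighted** over the neighborhood's tracts, matching how area deprivation
  indices published for small enumeration units are usually lifted to larger
  units.

The exact weighting of the head-of-household proportion at neighborhood level
is not something the source methodology pins down; pooling is the default
here because it is the maximum-likelihood estimate of the neighborhood-level
proportion under binomial sampling.

## Income terciles

Boundaries are the empirical 33⅓ and 66⅔ percentiles of the neighborhood
per-capita-income distribution, computed with linear interpolation between
order statistics (R's default quantile type 7), unweighted by schools. A
neighborhood whose income ties a boundary goes to the **lower** tercile. With
distinct incomes and `3k` neighborhoods this yields exactly balanced
terciles; ties can unbalance them by at most the number of tied values. A
degenerate (all-equal) income distribution is an error rather than an
arbitrary assignment.

## The Gi* segregation index

`gi_star()` implements the self-inclusive Gi* statistic in its Z-score form

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
{S \sqrt{\left(n S_{1i} - W_i^2\right)/(n-1)}}$$

with binary first-order rook weights, $w_{ii} = 1$, no row standardization;
$\bar X$ and $S$ are the global mean and **population** standard deviation
(divide by $n$). Three decisions are folded into that sentence:

* **Gi\* rather than Gi** (self-inclusive): the fixed ±1.96 cut points used
  for categorization presume the standard-normal form of the self-inclusive
  statistic.
* **Binary weights**: row-standardized weights would rescale $W_i$ and
  $S_{1i}$ without changing the Z-score's null calibration, but binary rook
  is the stated matrix in the methodology this package follows, and it keeps
  the lattice tests exact.
* **Population SD**: matches the moment derivation of the statistic; at city
  scale ($n$ in the tens to hundreds) the difference from the sample SD is
  far smaller than any categorization effect, and the unit tests cover the
  convention explicitly via an independent brute-force oracle (tolerance
  1e-8 on random 6×6 lattices, 1e-10 on a fixed 3×3 case).

Categories: High for $Z \ge 1.96$, Medium for $0 \le Z < 1.96$, Low for
$Z < 0$. A constant input has no variance and is an error; a unit adjacent
to every other unit makes the denominator vanish and is likewise an error.

**Unit of analysis.** The source methodology describes tract-level weighting
but categorizes neighborhoods. The default here computes Gi* at the
neighborhood level on neighborhood adjacency, which matches the index's
definition as a neighborhood Z-score. A tract-level mode
(`city_study(..., gi_level = "tract")`) is provided: tracts of the same or
of rook-adjacent neighborhoods are treated as neighbors, each tract is
scored, and the neighborhood takes the majority tract category (ties broken
toward the more segregated category). On planted-cluster lattices both modes
recover the cluster.

## The deprivation index

The combination formula behind published area-deprivation scores is often
not printed. The package uses the mean of the three z-standardized
indicators, the approach of the Brazilian deprivation-index family; the
standardization makes the score scale-free, so the ± ½ SD categorization is
invariant to affine changes in any indicator. Thresholds are mean ± ½ SD of
the score (population SD again). If scores were exactly normal this yields
expected shares 30.9% / 38.3% / 30.9% for Low / Medium / High, which the
tests verify by simulation. An indicator that is constant across
neighborhoods carries no ranking information and is an error.

## Food-environment classification

The CAISAN taxonomy has 13 subcategories in three macro classes; activity
codes map to subcategories by **longest-prefix match**, with unmatched codes
counted as `non_food` (logged, never silently dropped). The shipped default
prefixes follow the Brazilian CNAE retail (47.x) and food-service (56.x)
groups, but registries differ in code formatting, so the map is an editable
YAML file (`inst/extdata/category_map.yaml`).

* **Deserts**: healthy density = 10,000 × (in natura + mixed) / population;
  the threshold is the city-wide 25th percentile (type-7 linear
  interpolation) and the flag is **strictly below**. Consequences: with all
  densities equal there are no deserts, and at percentile 0 nothing is
  flagged. Under a continuous density distribution the flagged share is ≈25%
  by construction.
* **Swamps**: the sum over the swamp subcategory set must **exceed four**
  (i.e. ≥ 5). The published swamp sum names "convenience stores, snack bars,
  grocery stores and candy stores"; "snack bars" are cafeterias
  (*lanchonetes*) per the methodology's own note, and "grocery stores" is
  read as mini markets — the one genuinely ambiguous term. The set is a
  field of the category map, so either reading is a one-line change.
* **mRFEI** = 100 × healthy / (healthy + ultraprocessed); a neighborhood with
  no outlets in either group is undefined (`NA`), never zero, because zero
  would mean "maximally unhealthy" rather than "no information".

## Tabulation and testing

Prevalences are reported to one decimal. Chi-square tests are **uncorrected
Pearson** on the school-level contingency tables; the choice is locked by a
regression check: on the shipped Rio de Janeiro sector × both-flags table
(224/1737 vs 156/1422) the uncorrected test gives p = 0.098 as published,
while the Yates-corrected one gives 0.110. P-values render to three decimals
with `< 0.001` below 0.0005.

Count summaries use the median and the p25–p75 interquartile range with the
**type-6 quantile convention** (the SPSS rule: on `{0,0,1,2,3}` the IQR is
(0, 2.5), where type 7 would give (0, 2)). Note the asymmetry with the
desert threshold, which uses type 7; each convention is pinned by the worked
example it has to reproduce, and both are recorded here because quantile
conventions are the classic source of irreproducible descriptive tables.

**A documented discrepancy.** On the shipped Rio counts, school-level Pearson
tests reproduce the published p-values for all desert stratifications
(p = 0.001 by sector, < 0.001 elsewhere), for both-flags (0.098 by sector,
< 0.001 elsewhere) and for swamps by sector (< 0.001). The published swamp
p-values by income tercile (0.016), deprivation (0.231) and segregation
(0.079) are **not** consistent with school-level tests on the published
counts, which give p ≪ 0.001; they are consistent in magnitude with tests
run at the neighborhood level, where n is an order of magnitude smaller.
The package reports school-level tests and flags this rather than guessing
an undocumented procedure.

## The synthetic-city generator

`generate_city()` emulates the statistical structure the pipeline needs, not
any real city's geography:

* **Lattice geometry.** Neighborhoods sit on a rectangular grid with exact
  rook adjacency; polygon input remains supported through
  `rook_from_polygons()` for real data. A lattice makes contiguity exact and
  planted spatial structure unambiguous.
* **Income.** Household-head income is lognormal (sdlog 0.8, a typical
  Brazilian income inequality scale) with the log-mean solved analytically so
  that P(income ≤ 3 × minimum wage) equals the configured proportion (0.3
  background, 0.7 in planted clusters by default; proportions are clamped to
  [0.001, 0.999] because the normal quantile diverges at 0 and 1). This
  makes planted segregation exactly controllable. The default minimum wage
  is 510, the 2010 Brazilian value, in the same currency units as incomes.
* **Deprivation coupling.** Indicator rates are affine in the tract's
  low-income proportion (e.g. illiteracy 0.01 + 0.08·p), so income clusters
  are also deprivation hot spots — the correlation real cities show.
* **Establishments.** Poisson counts per neighborhood × subcategory, the
  simplest model matching the skewed, zero-inflated count distributions such
  registries show. The default rates are free parameters (no public registry
  exists to calibrate against) chosen once so relative abundances resemble a
  dense metropolis: cafeterias and mini markets common, seafood and
  convenience stores sparse. `plant_desert_swamp()` rewrites per-cell rates:
  desert cells get healthy rates × 0, swamp cells a swamp-set rate totalling
  12 (Poisson(12) exceeds 4 with probability 0.9977).
* **Substreams.** The master seed is expanded into per-component seeds
  (population, income, deprivation, establishments, schools), so changing
  the school settings cannot perturb establishment draws — a property the
  determinism tests rely on.

What the generator does **not** emulate: real street networks or travel
distances, point coordinates (everything is neighborhood-level, as in the
ecological design), income-dependent establishment rates, and registry
noise such as misclassified or duplicated activity codes beyond unknown-code
handling. Passing the recovery tests therefore shows the pipeline's
statistics behave correctly on data with the assumed structure; it is not
evidence about any particular real city.

## Problem sizes and reproducibility

The test suite and acceptance script run at deliberately small scale, chosen
so the whole validation completes in seconds while keeping Monte-Carlo error
well inside the asserted tolerances: 5×5 and 4×4 lattices with 50-seed
recovery loops (a binomial 95% hit-rate bound at 50 trials separates cleanly
from the observed 100%), 20-seed averages for planted-proportion gaps,
200-neighborhood continuous-density draws for the 25% desert-share check,
and 10^5-replicate multinomial nulls for the chi-square comparison (absolute
tolerance 0.05, dominated by the asymptotic approximation at n = 30, not by
Monte-Carlo error). Every random quantity in the package flows from an
explicit seed; rerunning any pipeline with the same configuration writes
byte-identical output files, which the tests assert literally.

## Known limitations

* Only first-order rook contiguity is provided; queen, distance-band and
  kernel weights are out of scope, as is inference for Gi* beyond the fixed
  cut points.
* The polygon reader derives adjacency from exactly shared boundary
  vertices; polygons that abut without coincident vertices (un-noded
  boundaries) need pre-processing in a GIS.
* Currency conversion is out of scope; incomes are unitless and the minimum
  wage is a configuration value in the same units.
* The chi-square stage assumes independent school observations; schools in
  the same neighborhood share all exposures, so the ecological p-values are
  anti-conservative at school level — one reason the neighborhood-level
  reading of the published swamp tests (above) is plausible.
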