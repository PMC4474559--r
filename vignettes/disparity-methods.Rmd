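---
title: "Measuring between-country life-expectancy disparities with dispaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring between-country life-expectancy disparities with dispaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispaq)
library(dplyr)
```

## The problem

Life expectancy at birth (LE) is the workhorse summary of national health,
but a regional average hides how unevenly longevity is distributed among a
region's member countries. dispaq quantifies that unevenness for panels of
country × period × sex LE observations — the structure of the United
Nations' five-yearly demographic summaries — and tracks how it changes over
time. The motivating application is comparing sub-regions such as the
Caribbean, Central America and South America, where a region can post
respectable average gains while the spread between its best- and
worst-performing members barely narrows.

Three questions drive the design:

1. **Level**: what is a region's population-weighted LE, and how far is it
   from the world average (the *gap*) and from the best-performing
   comparator region (the *shortfall*)?
2. **Spread**: how unequal are the member countries, measured on both
   absolute (years) and relative (dimensionless) scales?
3. **Robustness**: how much do the answers depend on which countries are in
   the region, and on any single dominant member?

## Aggregation

The regional LE for a period/sex slice is the weighted mean
$\bar{x} = \sum_i p_i x_i$ with $p_i = \mathrm{pop}_i / \sum_j \mathrm{pop}_j$,
so populous countries dominate. The **gap** is the signed difference from a
supplied world series; the **shortfall** is
$\max(\text{comparators}) - \bar{x}$, a non-negative deficit whenever the
comparator set contains the region itself. The comparator set is
caller-supplied (typically the weighted LE of every world sub-region per
period); the package deliberately hard-codes no world geography.

Members missing from a slice are reported and the mean is computed over the
available members. We chose transparency over imputation: demographic
panels are either complete by construction (as UN projections are) or
missing for reasons no generic imputation should paper over.

Gender disparities are summarized as the female-minus-male difference, the
percent difference **with the female LE as denominator**, and the
female-to-male ratio. The denominator convention is not arbitrary: it is
the only one of the three candidates (female, male, midpoint) consistent
with published regional tables we use as arithmetic checks, e.g.
$100 \times 5.16 / 74.42 = 6.93$. All arithmetic is done at full precision;
rounding to two decimals happens only at the rendering stage
(`format_metric()`), which is why a difference printed as 3.62 can coexist
with inputs that, themselves rounded, would give 3.61.

## The six-metric disparity suite

Following the practice of presenting absolute and relative measures side by
side rather than committing to one definition of "disparity", the suite
computes, per region × period × sex slice:

| metric | type | formula | units |
|---|---|---|---|
| LED | absolute, simple | $\max x - \min x$ | years |
| LER | relative, simple | $\max x / \min x$ | — |
| MD  | absolute, complex | $\tfrac1n \sum_i (x_{best} - x_i)$ | years |
| ID  | relative, complex | $100 \cdot \mathrm{MD} / x_{best}$ | % |
| BGV | absolute, complex | $\sum_i p_i (x_i - \bar{x})^2$ | years² |
| STI | relative, complex | $s \cdot (T + \mathrm{MLD})/2$ | — |

with Theil index $T = \sum_i p_i (x_i/\bar{x}) \ln(x_i/\bar{x})$ and mean
log deviation $\mathrm{MLD} = \sum_i p_i \ln(\bar{x}/x_i)$. LED and LER use
only the two extreme countries; the other four use every country. Zero
(one for LER) means equality; all are designed for unordered groups —
there is no natural ranking of countries the way there is for income
quintiles, so slope- and concentration-type indices are out of scope.

Design choices where the definitions are genuinely open:

* **MD/ID denominator.** The reference (best) country is included in the
  count with a zero term (`mode = "n"`, the default, matching the plain
  reading of "divides by the number of countries"); `mode = "n-1"`
  implements the variant that excludes it. Both are exposed because the
  literature contains both and the choice shifts MD by a factor
  $n/(n-1)$ — material for small regions.
* **Weighting of the entropy measures.** Theil and MLD use population
  shares and the population-weighted mean, matching BGV's weighting. An
  unweighted variant would treat Haiti-sized and Aruba-sized countries
  symmetrically while BGV next to it does not; a mixed convention inside
  one "complex measure" family would be incoherent.
* **STI reporting scale.** Unscaled $(T+\mathrm{MLD})/2$ values for LE
  data are order $10^{-3}$–$10^{-2}$, awkward to read in tables, so a
  reporting multiplier is applied; 1000 is the common convention in health
  disparity reporting and is the default. The unscaled `theil` and `mld`
  are always returned alongside so no information is lost, and the scale
  is recorded in the suite row.
* **Reference-country ties** are broken lexicographically by country id,
  with a message — determinism over silent arbitrariness.
* **Combined-sex ("women & men") slices** default to computation on
  both-sex LE rows (derived as the population-weighted mean of the sexes
  via `ensure_both_sex()` when absent). The alternative, averaging the
  female and male suites, is available as `combined_mode =
  "average-of-suites"` in `run_config()`; the two differ because every
  metric is non-linear in the underlying LE values.

A useful internal consistency check connects the weighted measures: for
small dispersion, $T + \mathrm{MLD} \approx \mathrm{BGV}/\bar{x}^2$
(second-order Taylor expansion of $u\ln u$ and $-\ln u$ about 1), so
$\mathrm{BGV} \approx 2\bar{x}^2 \cdot \mathrm{STI}_{unscaled}$. The test
suite verifies the relative error of this reconciliation falls below 1%
once the spread is ≤ 0.5% of the mean, and below $10^{-4}$ as dispersion
shrinks further.

## Trends and headline summaries

Between-period change is reported per metric as
$100\,(v_{to} - v_{from})/v_{from}$, and summarized as the arithmetic mean
of the three absolute metrics' changes (`avg_absolute`: LED, MD, BGV) and
of the three relative metrics' changes (`avg_relative`: LER, ID, STI).
Headlines render the whole-percent magnitude ("a 14% reduction" for an
average change of −13.90%). A metric resting at its equality value in both
periods counts as an unchanged (0%) trend; a move off an exact zero has no
defined percent change and is surfaced as an error (`percent_change()`) or
`NA` (sensitivity rows) rather than a fabricated number.

## Leave-one-out sensitivity

Because regional membership is partly a convention — the Caribbean
especially so — `leave_one_out()` removes each member in turn and
recomputes the regional LE in a base and an end period, the LE change
between them, and the change of selected disparity metrics (MD and ID by
default, any suite metric on request). The removal obeys the exact
identity
$\bar{x}_{full} P = \bar{x}_{-r}(P - \mathrm{pop}_r) + x_r\,\mathrm{pop}_r$,
which the tests assert to $10^{-9}$ relative error against brute-force
enumeration. `summarize_sensitivity()` reports the extrema across removals
and which country's removal produces each — on real data the analogue of
"removing the largest low-LE member raises the average most".

## The synthetic panel generator

Real UN country panels cannot be redistributed here, so the generator
produces panels with their statistical shape: for each country a both-sex
baseline LE $\sim N(60, 4^2)$ years, a secular gain $\sim N(0.3, 0.08^2)$
years per calendar year applied linearly over the nine 5-year periods
1965–1970 … 2005–2010, observation noise $N(0, 0.5^2)$, a gender gap
$\sim N(5, 1^2)$ years split symmetrically around the both-sex value, and
log-normal populations (median 500k, log-sd 1.2) held constant over time.
The defaults mirror mid-1960s developing-region magnitudes: baselines near
60 years, gains of roughly 3–4 months of life per calendar year, women
outliving men by about five years. The `outlier_config()` scenario adds a
member with a 15-year baseline deficit holding 22% of the regional
population — a stylized large low-longevity country inside an otherwise
typical 21-member region.

What the generator deliberately does **not** emulate: logistic convergence
of LE toward a frontier (dynamics are linear-with-noise), population
growth (constant populations isolate the weighting logic), migration,
cohort effects, or demographically consistent mortality schedules. Tests
passing on these panels therefore certify the *arithmetic and invariances*
of the metrics — weighting, scale/translation behaviour, degeneracies,
removal identities, recovery of configured effect sizes — not the
substantive levels any real-world region would show. Published metric
levels depend on the actual country data and are checked only through
their printed arithmetic relationships (percent changes, averaged
reductions, gender cells, shortfalls).

Two recovery properties tie the generator to its configuration and are
exercised at fixed sizes chosen to keep the full suite fast while leaving
sampling error well below the tested effects: the mean shift of the
regional aggregate when the outlier is removed equals
$\text{share} \times \text{deficit} = 3.3$ years within three standard
errors over 200 seeds, and the regression slope of regional LE on elapsed
years recovers the 0.3 yr/yr mean gain within three standard errors over
100 seeds. The oracle-equivalence property compares every metric against
independent loop-based summations on 1,000 random slices of up to eight
countries, at an absolute tolerance of $10^{-10}$ (absolute, because the
entropy measures sit near zero where relative comparison amplifies
machine noise).

## Numerical and degenerate-input conventions

* Periods are half-open `[start, end)` intervals normalized to
  `"YYYY-YYYY"`; shorthand like `1965–70` is accepted on input.
* A single-country slice yields the degenerate suite (all zeros, LER 1) —
  valid, not an error; an empty slice is an error.
* Entropy measures require strictly positive LE; the panel type enforces
  LE ∈ (0, 130) years at construction.
* Zero total population makes weights degenerate and is an error.
* Uniform population rescaling leaves every metric unchanged; LED, LER,
  MD, ID ignore populations entirely by definition.
* All internal arithmetic is double precision with no rounding; display
  rounding (2 dp for values, whole percents for headlines) is applied only
  in `format_report_tables()` and friends.

## Limitations

* Percent-change comparisons against published tables inherit the rounding
  of the published inputs: a cell computed upstream from unrounded values
  can differ by one unit in the last printed digit from the same cell
  recomputed from printed values. The acceptance tests bound this
  explicitly instead of hiding it.
* The package operates on whatever period grid the panel supplies; it does
  not interpolate five-year estimates to annual series.
* No sampling variance or confidence intervals are attached to the metrics;
  the inputs are themselves model-based estimates without country-level
  uncertainty in the panel format.
* Country ids are matched exactly; harmonizing names across sources is a
  data-preparation task upstream of this package.

## A worked run

```{r example, eval = FALSE}
p <- generate_panel(outlier_config(seed = 7))
r <- panel_region(p, "Synthetic Caribbean")

run <- run_trend_analysis(run_config(
  p, r, period_pair = c("1965-1970", "2005-2010"),
  out_dir = tempfile("run-")))
cat(format_report_tables(run)[["summary"]], "\n")

rows <- leave_one_out(p, r, c("1965-1970", "2005-2010"), "both")
summarize_sensitivity(rows)$le_base
```
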