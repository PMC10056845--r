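---
title: "Identifying positive outliers in reducing zero-dose children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying positive outliers in reducing zero-dose children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zerodose)
library(dplyr)
```

## The problem and the measures

"Zero-dose" children are those who have received no routine vaccine doses at
all. The standard operational marker is no-DTP prevalence: the percentage of
under-one children with no doses of a diphtheria–tetanus–pertussis
containing vaccine, i.e. `100 - DTP1 coverage`. Progress against zero-dose
burdens has two geographic faces, and a country can do well on one while
failing on the other:

* **National level** — the country-wide no-DTP prevalence in a year.
* **Subnational gap** — the difference between the 95th and 5th percentiles
  of no-DTP prevalence across a country's second-level administrative units
  (districts, zones, communes, LGAs) in that year, in percentage points.

Percentiles rather than the min–max range are used so that a single outlying
district does not dominate the inequality measure, and so that the statistic
is less sensitive to how many admin-2 units a country happens to be divided
into (unit counts span roughly 8 to 800 across low- and lower-middle-income
countries). `units_gap_correlation()` quantifies that residual sensitivity on
any panel.

`zerodose` implements the full positive-outlier ("exemplar") identification
pipeline on such panels: metric construction, change quantification, a
four-way progress classification, dual-track ordinal ranking with mean-rank
aggregation, and baseline-matched neighborhood comparisons, plus a seeded
synthetic-panel generator so every stage is testable without the original
modelled estimates (which are not publicly deposited).

## Metric and ranking choices

**Quantile estimator.** The source analysis never states which quantile
definition it used. We pin linear interpolation between order statistics
(`stats::quantile()` type 7, the R default) and document it, because
reproducibility demands one fixed rule; the bundled validation fixtures
carry the published percentile *endpoints* directly, so the choice of rule
is testable independently of the published gaps. Percentiles are computed
over units unweighted, mirroring the unit-level treatment of the source
analysis; population-weighted quantiles are available behind a flag
(`weighted = TRUE`), using linear interpolation on cumulative-weight
midpoints.

**Scale.** Percent (0–100) everywhere, never proportions; gaps and absolute
changes are in percentage points (pp).

**Changes.** For a window `[start, end]` (2000–2019 in the published
analysis), absolute change is `end - start` (reductions negative, matching
the published tables) and relative change is `(end - start)/start * 100`,
undefined when the start value is 0. Relative change is scale-invariant;
absolute change is not — the two tracks deliberately reward different
starting points.

**Classification.** A country "reduced" a dimension only if its change is
strictly negative; zero change counts as not reduced, reading "some kind of
reduction" as a strict decrease.

**Ranking.** Within each track (absolute / relative), countries are ranked
1..N on each dimension separately — rank 1 is the largest reduction, rank N
the smallest reduction or largest increase — and the two ranks are averaged
with equal weight. Equal weighting operationalises the pro-equity stance
that national gains without subnational-gap gains should not make a country
an exemplar. Ties share the average (fractional) rank by default, which
keeps each rank column summing to `N(N+1)/2` (a tested invariant);
competition ranking is available. On the recomputed fixture, Ethiopia and
India tie at mean rank 5.5 on the absolute track, so exemplar selection
breaks mean-rank ties deterministically by larger national reduction, then
alphabetically. Countries with an undefined relative change are excluded
from the relative track with a notice rather than ranked last — ranking them
last would conflate "no defined denominator" with "worst performer".

## Neighborhood matching

A neighborhood comparison pairs a target country with another that started
from similar no-DTP measures in the baseline year but diverged by the end
year. `baseline_distance()` supports three dimensions: absolute difference
on the national level, absolute difference on the subnational gap, or
Euclidean distance in the joint (national, gap) plane, by default with each
axis standardized by the candidate pool's standard deviation so neither
metric dominates by units alone. `match_neighbor()` takes an explicit
candidate pool and dimension — the published pairings for the Gavi Learning
Hub countries are not reproducible from any single rule (on printed
2000 values, Nigeria's nearest exemplar nationally is the DRC, not its
published partner Ethiopia; Mali's nearest by gap is Ethiopia, not its
published partner DRC), so the metric must be explicit and configurable
rather than guessed.

`match_learning_hubs()` additionally matches a sequence of targets *without
replacement* — each exemplar is used at most once. That one-to-one
discipline, with Nigeria matched on the joint plane and Mali and Uganda on
their single dimensions, reproduces all three published pairings
(Nigeria–Ethiopia, Mali–DRC, Uganda–Burundi) and is the natural shape for a
learning-partnership pairing. Divergence is reported descriptively as the
per-year and end-year difference vector; no statistical test is attached,
because the inputs are modelled estimates whose uncertainty is not carried
through this pipeline.

The same machinery runs within one country at the admin-1 level via
`admin1_metrics()` (entities become states/regions; their "national" level
is the mean over their admin-2 units), supporting subnational neighborhood
analyses such as comparisons of bordering states.

## The synthetic-data generator

`synthetic_spec()` + `generate_study()` emulate the statistical structure
the pipeline assumes, so identity-recovery and invariance properties can be
tested end to end:

* **Logit-scale trajectories.** Unit `u` of country `c` has noiseless
  prevalence `plogis(b_cu - r_cu * t) * 100` in year `t`. Working on
  log-odds respects the 0–100 bounds intrinsically — clipping only guards
  noise excursions — and yields the decelerating, monotone-ish declines seen
  in real coverage series.
* **Hierarchical heterogeneity.** Country baselines `N(qlogis(0.2), 0.9)`
  put 2000 national no-DTP roughly between a few percent and above 50%, the
  observed spread; unit baselines scatter around the country mean (sd 0.7
  logits), creating subnational gaps; decline rates `N(0.10, 0.05)`
  logits/year give mostly-improving countries with occasional worsening
  ones, as observed.
* **Unit-count heterogeneity.** Counts are drawn log-uniformly on 8–800,
  matching the observed span from micro-states to Nigeria's 774 LGAs.
* **Observation noise** is Gaussian on the percent scale (default sd
  0.5 pp, the scale of rounding in published estimates). **Shock blocks**
  add a fixed increment to a random fraction of units over a year interval,
  emulating conflict periods. **Populations** are log-normal and constant
  over years.
* **Designed exemplar.** With `n_exemplars = 1`, the first country is
  constructed to dominate both reduction dimensions in the noiseless truth:
  it receives a baseline just above the rest, the widest unit dispersion
  (1.5×, so its starting gap is the largest) and the fastest decline, and
  the construction is adjusted deterministically until its true reductions
  exceed every other country's by at least `exemplar_margin_pp` (default
  5 pp) on both dimensions. The margin makes recovery a property of the
  design rather than of noise realisations.

The generator is deterministic given `seed` (per-country substreams are
derived from it), and its panels pass `validate_panel()` by construction.
What it does **not** emulate: spatial autocorrelation between neighboring
units, survey-driven estimation uncertainty, administrative boundary
changes, and correlated country-level shocks. Tests passing on synthetic
panels therefore demonstrate correctness of the pipeline's algebra and
ranking logic under the assumed structure, not robustness to those
real-data features.

## Numerical and degenerate-input choices

* Empty unit vectors and invalid quantile bounds are errors; a single-unit
  country has a well-defined gap of 0 and triggers a notice.
* Zero total population in a country-year is an error in population-weighted
  mode; a missing population column downgrades weighted options with a
  notice instead of failing.
* Duplicate (country, unit, year) keys and out-of-range percentages are
  validation errors naming the offending rows.
* The published change columns were computed from unrounded source values,
  so they can differ from changes recomputed from printed levels by up to
  ~0.1 pp; fixture reconciliation tests assert sign equality everywhere and
  agreement within ±0.15 pp, and exemplar recovery from the fixture is
  asserted as set identity, which is robust to that rounding provenance.
* Pipeline outputs are written at a fixed decimal precision (default 1,
  configurable), and a run manifest records the config hash, seed and an
  MD5 digest per output table; identical config and seed reproduce
  byte-identical tables.

## Worked example

```{r example, message = FALSE}
metrics <- table2_metrics()
changes <- change_metrics(metrics, 2000, 2019)
progress_counts(classify_progress(changes))

abs_track <- select_exemplars(ranking_table(changes, "absolute"), k = 3)
head(abs_track[, c("country", "rank_national", "rank_gap", "mean_rank")], 3)

match_learning_hubs(
  metrics,
  targets = c("Nigeria", "Mali", "Uganda"),
  pool = c("Dem Rep of the Congo", "Ethiopia", "India",
           "Bangladesh", "Burundi"),
  dimensions = c("joint", "gap", "national")
)
```

And end-to-end on a synthetic study with a designed exemplar:

```{r synthetic, message = FALSE}
study <- generate_study(synthetic_spec(
  n_countries = 8, n_units_range = c(8, 60), n_exemplars = 1, seed = 7
))
sm <- country_year_metrics(to_no_dtp(study$panel))
top <- select_exemplars(ranking_table(change_metrics(sm), "absolute"), k = 1)
top$country[top$exemplar] == study$truth$country[study$truth$designated_exemplar]
```

## Problem sizes used in the test suite

The suite exercises the quantile statistic against an independent
sort-and-interpolate oracle on 1,000 random vectors of lengths 1–800, runs
20 seeded recovery replicates at 8 countries × 8–60 units × 20 years, and
checks byte-determinism on small synthetic pipelines — sizes chosen to make
the properties sharp while keeping the default test run fast.

## Known limitations

* The pipeline operates on point estimates; if inputs are posterior
  summaries, their uncertainty is ignored.
* Geographic inequality is one dimension of vaccination inequity; gaps by
  wealth, gender, education or ethnicity are out of scope here.
* Exemplar status is sensitive to the chosen window endpoints; no
  multi-window sensitivity analysis is built in.
* The bundled published-results fixture carries endpoint years only
  (2000, 2019), so fixture-mode trajectories are two-point segments.
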