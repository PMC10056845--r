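# zerodose

Identifying positive outliers ("exemplars") in reducing zero-dose children
from subnational immunization coverage panels.

## What it does, and for whom

Zero-dose children — children with no doses of a DTP-containing vaccine —
are the focus of current global immunization strategies. For immunization
researchers and program analysts, `zerodose` turns panels of subnational
DTP1 coverage estimates (country × admin-2 unit × year) into the two
geographic progress measures used in positive-outlier analyses of
unvaccinated children, and runs the full exemplar-identification pipeline
on them:

1. **Metrics.** No-DTP prevalence is `100 − DTP1 coverage`. For each
   country-year the pipeline computes the national level and the
   **subnational gap**
   `gap(c, t) = Q₀.₉₅(no-DTP across admin-2 units) − Q₀.₀₅(no-DTP across admin-2 units)`
   in percentage points (pp), using type-7 linear interpolation between
   order statistics.
2. **Changes.** Over a study window (2000–2019 by default): absolute change
   `Δ = end − start` (pp; reductions negative) and relative change
   `Δ/start × 100` (%), per country and dimension, plus a four-way
   classification by the sign of progress in each dimension.
3. **Ranking.** On each track (absolute, relative), countries are ranked
   1..N per dimension (1 = largest reduction) and the two ranks averaged
   with equal weight; the smallest mean ranks are flagged as potential
   exemplars — countries whose progress on *both* national levels and
   subnational equity is exceptional.
4. **Neighborhoods.** Target countries (e.g. the Gavi Learning Hubs:
   Nigeria, Mali, Uganda, Bangladesh) are paired with exemplars that had
   similar baseline no-DTP measures but divergent trajectories, to motivate
   cross-country learning. Matching distance (national, gap, or
   standardized joint plane) is explicit and configurable; sequential
   matching without replacement yields one-to-one pairings.
5. **Synthetic data.** A seeded generator (`synthetic_spec()`,
   `generate_study()`) emulates multi-country panels with logit-scale
   declining trajectories, heterogeneous unit counts (8–800), optional
   shock periods, and an optional designed exemplar whose true reductions
   dominate by construction — so every stage is testable without the
   original modelled estimates, which are not publicly deposited.

The package bundles a plain-text fixture of the published country-level
results (56 low- and lower-middle-income countries, endpoint years 2000 and
2019) that the test suite validates against.

## Worked example

```r
library(zerodose)

metrics <- table2_metrics()            # bundled published endpoint metrics
changes <- change_metrics(metrics, 2000, 2019)
progress_counts(classify_progress(changes))
#> # A tibble: 4 × 3
#>   category                  n share
#>   <fct>                 <int> <dbl>
#> 1 both_reduced             44 78.6
#> 2 national_only_reduced     5  8.93
#> 3 gap_only_reduced          2  3.57
#> 4 both_increased            5  8.93
```

44 of the 56 countries (78.6%) reduced both national no-DTP prevalence and
the subnational gap between 2000 and 2019. Ranking both tracks:

```r
abs_track <- select_exemplars(ranking_table(changes, "absolute"), k = 3)
abs_track[abs_track$exemplar, c("country", "rank_national", "rank_gap", "mean_rank")]
#> # A tibble: 3 × 4
#>   country              rank_national rank_gap mean_rank
#> 1 Dem Rep of the Congo             2        2       2
#> 2 Ethiopia                         1       10       5.5
#> 3 India                           10        1       5.5
```

The DRC, Ethiopia and India achieved the largest absolute reductions across
both dimensions (Ethiopia's 51.7 pp national decline ranks 1st nationally;
India's 32.8 pp gap narrowing ranks 1st on equity); Bangladesh and Burundi
lead the relative track. Neighborhood matching pairs each Learning Hub with
a distinct exemplar that started from similar 2000 measures:

```r
match_learning_hubs(
  metrics, targets = c("Nigeria", "Mali", "Uganda"),
  pool = c("Dem Rep of the Congo", "Ethiopia", "India", "Bangladesh", "Burundi"),
  dimensions = c("joint", "gap", "national")
)
#> # A tibble: 3 × 7
#>   target  matched              dimension baseline_year distance divergence_national divergence_gap
#> 1 Nigeria Ethiopia             joint              2000     1.34               -17.2          -34.1
#> 2 Mali    Dem Rep of the Congo gap                2000     1                  -10.2          -24.5
#> 3 Uganda  Burundi              national           2000     3.5                 -4.4           -3.9
```

Mali and the DRC had near-identical subnational gaps in 2000 (47.8 vs
46.8 pp, distance 1.0 pp), yet by 2019 the DRC's gap was 24.5 pp narrower
than Mali's — exactly the kind of divergence that motivates cross-country
learning. `run_pipeline()` orchestrates all stages from a config (fixture,
CSV panel, or synthetic mode) and writes every stage table plus a
reproducibility manifest; `inst/scripts/zerodose-pipeline.R` wraps it for
shell use.

## Vignette

`vignettes/zero-dose-exemplars.Rmd` documents the measures, the ranking and
matching design choices, the synthetic generator's model and its limits, and
degenerate-input behaviour.
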