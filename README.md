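# nsindex

Quantifying how readily natural vegetation succession proceeds under
different climate conditions — and what that implies for allocating
restoration budgets.

Natural (unassisted) restoration relies on secondary succession:
grassland → shrub → forest. Across a climatically diverse province such
as Yunnan (southwest China), the same 30 years of protection produce
anything from unbroken grassland to closed forest, so province-wide
restoration plans need a way to compare climates on one scale. This
package is for landscape/restoration ecologists and planners working
with long-term monitoring-plot series. It provides:

* **Two-stage climate zonation** of towns: a primary split on annual
  accumulated temperature into regions C, M, W, H (coldest → hottest),
  then a secondary split on annual precipitation, relative humidity,
  mean annual temperature and mean altitude (Ward clustering, or exact
  threshold assignment from published temperature intervals).
* **Succession-outcome classification** of eligible plots observed every
  5 years from 1987 to 2017, with interval-censored stage durations
  (every transition is reported as a bracket plus a midpoint estimate).
* **The Natural Succession Index** per stratum. Each stage carries a
  habitat quality *Q*, the exact reciprocal of its landscape-matrix
  resistance (grassland 1/30, shrub 1/5, forest 1). For stage counts
  *n<sub>g</sub>, n<sub>s</sub>, n<sub>f</sub>* with total *N*:

  *P* = (*Q<sub>g</sub>n<sub>g</sub>* + *Q<sub>s</sub>n<sub>s</sub>* +
  *Q<sub>f</sub>n<sub>f</sub>*) / *N*,  1/30 ≤ *P* ≤ 1,

  with *P* = 1 exactly when every plot reached forest.
* **Budget re-balancing** around the mean index *K*:
  *I* = *I<sub>n</sub>* (1 + (*K* − *P<sub>x</sub>*)/*K*). Sub-areas
  above *K* are investment-surplus (budget shrinks), below *K*
  investment-deficient (budget grows); equal baselines conserve the
  total exactly.
* A **seeded synthetic-data generator** (uniform draws inside published
  per-sub-area climate boxes; a latent annual grassland→shrub→forest
  chain observed at the 5-year grid) plus the chain's closed-form
  outcome probabilities, so the whole pipeline is testable end to end
  without any external data.

## Worked example

Simulate a monitoring system under the default scenarios (13 sub-areas,
published sample sizes, 1311 plots) and run the full pipeline:

```r
library(nsindex)

sim <- run_simulate("data", seed = 20)
res <- run_full(sim$files[["towns"]], sim$files[["plots"]], "analysis",
                config = pipeline_config(
                  zonation = zonation_config(mode = "threshold")),
                seed = 20)

head(res$nsi[res$nsi$level == "subarea",
             c("stratum", "N", "pct_forest", "nsi_display")], 5)
#>   stratum     N pct_forest nsi_display
#> 1 H-IV      106       69.8       0.724
#> 2 H-I       212       68.9       0.721
#> 3 H-III     132       68.2       0.715
#> 4 W-IV      173       53.2       0.594
#> 5 M-III      15       46.7       0.551
```

Reading this: the hottest-region sub-areas head the table — about 69 %
of their plots reached forest within 30 years, giving indices around
0.72 — while cool or dry sub-areas trail. (Sub-area numerals are the
package's own deterministic labelling of clusters; the region prefix is
recovered from the accumulated-temperature thresholds.) The
re-balancing stage then moves budget toward the hardest climates:

```r
plan <- res$reallocation
head(plan[order(-plan$adjusted), ], 3)
#>   subarea_label   nsi baseline adjusted status
#> 1 H-II          0.337      100     134. deficit
#> 2 W-II          0.348      100     132. deficit
#> 3 M-I           0.378      100     126. deficit
mean_threshold(plan$nsi)
#> [1] 0.5107
```

With equal baselines of 100 per sub-area, the 13 adjusted budgets still
sum to 1300; a dry-hot-valley-type sub-area with index 0.337 (well
below the mean 0.51) gains 34 %, funded by the surplus sub-areas above
the mean.

The published per-stratum stage counts ship with the package and
reproduce the published index values exactly:

```r
counts <- reference_stage_counts("C-I")
round_half_up(compute_nsi(counts$n_grassland, counts$n_shrub,
                          counts$n_forest), 4)
#> [1] 0.2943
```

A thin command-line wrapper (`exec/nsindex.R`) exposes the same stages
as subcommands (`simulate`, `zonate`, `classify`, `nsi`, `reallocate`,
`run-all`).

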