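# atollnet

Residency, activity space and movement networks from passive acoustic
telemetry on fixed receiver arrays.

Arrays of moored acoustic receivers log time-stamped detections of tagged
animals whenever they swim within range. `atollnet` turns those detection
logs into the three standard products of a long-term movement study of
reef-associated sharks:

* **Residency** — detection-day cleaning (single-detection and minimum-days
  filters), the residency index *RI = days detected / expected days at
  liberty* (1877-day rated tag life, adjusted for reported captures and
  tags that outlive their rating), the span-based *RI_max*, the roaming
  index (receivers visited / 18), monthly residency series, cohort
  summaries, and Gaussian GLMs of the indices on total length and sex with
  AIC model selection, plus Mann-Whitney and Kruskal-Wallis comparisons
  with a Dunn-type post hoc.
* **Activity space** — 30-minute relocation series at projected receiver
  positions, bivariate normal kernel utilization distributions
  *f(x) = (1/n) Σᵢ N₂(x; xᵢ, h²I)*, and percent-volume contour areas (50%
  core, 95% total), with sex-specific size classes A/B/C (juvenile,
  subadult, mature).
* **Movement networks** — empirically derived Markov chains (EDMC): hourly
  presence states over 16 merged receiver nodes plus an absent state,
  pooled transition-count matrices, row-stochastic transition matrices, and
  eigenvector centrality — the stationary distribution π solving πP = π —
  by power iteration, exported as edge lists and GraphML.

A seeded synthetic-cohort simulator (`simulate_cohort()`) generates
detection data from known movement kernels so every stage is validated by
parameter recovery, and the package ships the published per-shark summary
table of a seven-year, 77-shark Caribbean reef shark study
(`lighthouse_table1()`) as a regression fixture for the cohort statistics.

## Worked example

Cohort statistics recomputed from the packaged per-shark table:

```r
library(atollnet)
tbl <- lighthouse_table1()
summarize_cohort(tbl)
#> Cohort residency summary (n = 77)
#>   RI      mean 0.22 +/- 0.21 sd; 90% below 0.50
#>   RI_max  mean 0.44 +/- 0.29 sd; 30 animals above 0.50
#>   site- and array-faithful (RI_max > 0.5, roaming < 0.5): 19 (63% mature F)
#>   of animals with roaming < 0.5, 61% are mature
#>   size classes by sex:
#>           sex
#> size_class  F  M
#>          A 14 10
#>          B  5  9
#>          C 20 19
```

Most sharks are weakly resident on the conservative tag-life denominator
(mean RI 0.22), yet 19 animals — mostly mature females — are both site- and
array-faithful. Roaming declines with body size:

```r
fit_linear_model("roaming_index", tbl, select = TRUE)
#> GLM (gaussian): roaming_index ~ tl_cm
#>             estimate std_error t_value p_value
#> (Intercept)   0.7843    0.1093  7.1748  0.0000
#> tl_cm        -0.0021    0.0007 -3.2603  0.0017
```

i.e. each additional centimetre of total length drops the roaming index by
0.0021 — larger sharks use fewer receivers.

A synthetic cohort runs through the same network machinery:

```r
sim <- simulate_cohort(simulation_config(seed = 1,
                                         n_sharks = c(FA = 3, FC = 3),
                                         study_days = 90,
                                         tagging_window_days = 10))
ds  <- merge_receiver_nodes(remove_false_detections(sim$detections))
edmc(ds)
#> Empirically derived Markov chain movement networks
#>   grouping:sex_size (2 chains, 6 animals)
#>   FA     17 states,   5958 transitions, pi(ABSENT) = 0.853
#>   FC     17 states,   5555 transitions, pi(ABSENT) = 0.795
```

π(ABSENT) is the stationary probability of being outside every receiver's
range; the mature-female group (FC) is the most array-resident, as its
generating kernel prescribes. `recovery_report(sim$truth, sim$detections)`
quantifies how well the pipeline recovers the generator's kernels, residency
and planted false detections.

The full pipeline (filter → residency → kernel density → networks) runs from
one call, `run_pipeline(pipeline_config(...))`, writing per-stage CSVs, a
JSONL run log and a machine-readable `report.json`; a thin command-line
wrapper lives at `inst/scripts/atollnet.R`. See the vignette
(`vignettes/atoll-telemetry-methods.Rmd`) for the model conventions,
numerical tolerances and design choices.

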