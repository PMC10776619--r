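# brcascreen

Cost-effectiveness modelling of population strategies for identifying BRCA1/2
pathogenic-variant carriers.

Most BRCA1/2 carriers are found only at cancer diagnosis: clinical criteria
and family history refer under 1% of women for genetic testing, with ~10%
positivity. A radiogenomic classifier applied to routine ovarian ultrasound
can flag likely carriers across the whole population. `brcascreen` is a
cohort decision model, for health-economics and cancer-prevention
researchers, that compares three testing strategies on a generation of
274,000 eighteen-year-old women followed to age 80:

* **model 1** — clinical criteria / family history alone;
* **model 2** — model 1 + the classifier at current performance
  (sensitivity 49%, specificity 87%);
* **model 3** — model 1 + the classifier at projected performance
  (sensitivity 80%, specificity 95%).

Per generation the model chains: eligibility for testing → carrier detection
(with carrier pool `C = Nπ` and clinical route probability
`r_clin = Neq / C`; generation-1 detection under screening is the union
`C·se + r_clin·C·(1 − se)`) → prophylactic-surgery uptake (none / RRM /
RRSO / both) → stratum-specific lifetime cancer risks → healthy life-years
lost (`cases × (80 − onset age)`) → direct costs (testing, surgery,
treatment bundles, follow-up) → incremental cost-effectiveness ratio (ICER,
€ per healthy life-year gained) against model 1. Awareness of carrier status
propagates across three generations through cascade testing of relatives;
the screen is withdrawn in generation 3. Central, best-case and worst-case
parameter scenarios are built in, and an individual-level Monte Carlo
microsimulation validates the deterministic engine's expectations.

## Worked example

```r
library(brcascreen)
res <- run_scenario("central")
build_table2(res)
#>                       quantity   model1 model2_gen1 model2_gen2 model2_gen3 model3_gen1 model3_gen2 model3_gen3
#> 1         eligible_for_testing  2685.00     38520.0    39248.00     4240.00    17426.00    17729.00     4252.00
#> 2            carriers_detected   269.00      1036.0     1776.00     1824.00     1522.00     1832.00     1835.00
#> 3                cancers_aware   102.00       392.0      673.00      691.00      576.00      694.00      695.00
#> 4              cancers_unaware  1246.00       635.0       47.00       10.00      249.00        3.00        1.00
#> 5                cancers_total  1348.00      1028.0      720.00      700.00      826.00      697.00      695.00
#> 6                hly_lost_daly 47168.00     35978.0    25199.00    24508.00    28898.00    24381.00    24341.00
#> 7       cost_total_billion_eur     1.25         1.3        1.29        1.24        1.27        1.26        1.24
#> 8 cost_per_year_per_person_eur    73.85        76.4       75.86       72.72       74.65       74.42       72.71
```

Reading the model-2 column: adding the current classifier raises detection
before cancer onset from 269 to 1,036 carriers (+41.8 percentage points of
the 1,836-carrier pool) and cuts BRCA-related cancers from 1,348 to 1,028
(−23.7%), at an extra ~2.6 €/year/person; by generation 3 cascade testing
alone keeps 1,824 carriers detected and the strategy is cheaper than the
status quo. ICERs per generation and scenario:

```r
build_table3()
#>   generation model central best worst
#> 1          1     2    3861 6576  4997
#> 2          1     3     738 1567  1055
#> 3          2     2    1550 2970  2019
#> 4          2     3     423 1072   654
#> 5          3     2    -849 -973  -952
#> 6          3     3    -849 -973  -952
```

Positive first-generation ICERs (≈3,900 € per healthy life-year for model 2,
≈740 € for model 3) turn negative — cost-saving with health gains — once
screening is withdrawn and cascade testing carries detection. The
microsimulation cross-check:

```r
validate_against_cohort(builtin_scenario("central"), model_config(2),
                        n_replicates = 100, seed = 42)
#> every compartment's cohort expectation within 3 Monte Carlo SE
```

Custom parameters load from YAML (`load_parameters("inst/extdata/central.yaml")`);
`write_reports()` emits CSV/JSON results with a run manifest, and
`inst/cli/brcascreen.R` wraps the same functions for shell use
(`run`, `table2`, `table3`, `compare`, `microsim` subcommands).

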