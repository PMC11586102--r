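# batnight

Nightly activity budgets of colonially roosting bats from PIT-tag detections
at roost entrances.

Passive integrated transponder (PIT) tags read by cord antennae at roost
entrances produce long streams of timestamped, direction-less, burst-repeated
reads. `batnight` turns such streams into per-bat, per-night activity
budgets and compares them across reproductive condition, sex, and
food-availability season — the analysis workflow used for nectar-feeding
bats (*Leptonycteris yerbabuenae*-type colonies) and applicable to any
gregarious rooster monitored with entrance RFID.

## What it computes

Detections are cleaned (post-tagging exclusion, burst deduplication, night
assignment against NOAA-computed sunset/sunrise windows) and coded into
alternating passages: the first passage of a bat-night is the emergence
(EXIT), the next an ENTRY, and so on. Four metrics per bat-night follow:

* **time of emergence** `e = t(first EXIT) − t(sunset)` in minutes;
* **returns to the roost** `r = #ENTRY`;
* **hours inside** `Σ (t(EXIT_{i+1}) − t(ENTRY_i))` over consecutive
  entry→exit pairs;
* **hours of activity** `Σ (t(ENTRY_i) − t(EXIT_i))` over exit→entry pairs,
  with an open-ended final EXIT flagged as censored rather than truncated.

For uncensored nights, `hours_inside + hours_active` equals the first-to-last
event span exactly (enforced to 1 s).

The statistical layer fits the field's standard models: per-metric GLMs
(Poisson for counts; gamma with inverse or log link for durations; Gaussian
for emergence) with likelihood-ratio tests against the null and Tukey-style
pairwise contrasts (multivariate-normal max-|z| adjustment); and, for the
sex/season analysis, a deterministic 16-model AIC-ranked candidate set of
GLMMs with crossed random intercepts for bat and year (ΔAIC < 2 = equivalent
support). Effect sizes are reported on the response scale with 95% CIs.

A synthetic-colony generator (`simulate_truth()`, `apply_detection_process()`)
plants known group effects and degrades them through an imperfect antenna, so
the entire chain is verifiable end to end (`recovery_experiment()`).

## Worked example

```r
library(batnight)

carmen <- site("CARMEN", 25.99, -111.16, -7)
nights <- night_table(carmen, as.Date("2016-04-15"))
nights
#>   site_id night_date              sunset             sunrise
#> 1  CARMEN 2016-04-15 2016-04-15 18:48:23 2016-04-16 06:00:01

# a bat-night: exit 30 min after sunset, return at +120, re-exit at +150,
# final return at +300
ev <- data.frame(tag_id = "A0153", night_date = nights$night_date,
                 site_id = "CARMEN",
                 timestamp = nights$sunset + c(30, 120, 150, 300) * 60,
                 direction = c("EXIT", "ENTRY", "EXIT", "ENTRY"),
                 roost_id = "CARMEN", ordinal = 1:4, pre_sunset = FALSE)
compute_activity_metrics(ev, nights)
#>   tag_id emergence_min_after_sunset n_returns hours_inside hours_active
#> 1  A0153                         30         2          0.5            4
```

The bat emerged 30 minutes after sunset, returned twice, spent half an hour
inside between its two foraging bouts, and was outside for 4 hours in total.

End to end on a synthetic colony with perfect detection, the pipeline must
reproduce the generator's ground truth exactly and recover its planted
return-rate ratios:

```r
rec <- recovery_experiment(sim_config(seed = 7))
rec
#> Synthetic recovery experiment
#>   bat-nights: 840 truth, 840 derived; exact match 100.0%
#>   mean absolute error:
#> emergence_min     n_returns  hours_inside  hours_active
#>             0             0             0             0
#>   returns rate ratios (Poisson GLM) vs truth:
#>                      contrast estimate ci_low ci_high truth covered
#> 1 lactating / nonreproductive    0.747  0.657   0.848 0.750    TRUE
#> 2        lactating / pregnant    0.504  0.447   0.567 0.500    TRUE
#> 3  nonreproductive / pregnant    0.674  0.605   0.751 0.667    TRUE
```

Full runs (simulate → derive → fit, with all artifacts written to a
directory) go through `run_pipeline()` with a YAML or list config, or the
wrapper script `inst/cli/batnight.R`:

```sh
Rscript inst/cli/batnight.R all --config run.yaml --seed 42 --out artifacts/
```

## Scope notes

The package consumes prepared daily covariates (`env.csv`); it does not fetch
gridded climate products. Direction inference assumes a single (or merged)
entrance per site and does not correct missed reads — the resulting bias is
quantified on synthetic colonies instead. See
`vignettes/activity-budgets.Rmd` for the full methods account.
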