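---
title: "Deriving nightly activity budgets from PIT-tag detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving nightly activity budgets from PIT-tag detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batnight)
```

## The problem

Colonially roosting bats carrying passive integrated transponder (PIT) tags
are re-detected every time they pass an antenna at a roost entrance. A single
cord antenna yields a timestamped stream of reads with no direction
information, re-reads the same tag many times per pass, and misses some passes
entirely. From such streams, `batnight` derives a nightly activity budget per
individual — when the bat emerged, how often it returned, and how long it spent
inside versus outside the roost — and compares those budgets across
reproductive condition, sex, and food-availability season.

## From raw reads to coded passages

The cleaning chain applies, in order:

1. **Post-tagging exclusion** (`filter_post_tagging()`, default 3 days):
   detections on the tagging day and the following `exclusion_days - 1`
   calendar days are discarded, because freshly handled animals can behave
   abnormally. The rule is calendar-day based: a detection is kept when its
   date is at least `exclusion_days` days after the tagging date.
2. **Condition window** (`select_condition_window()`, default 14 days,
   `Inf` = keep all): reproductive condition is assessed once, at tagging, so
   condition-based analyses keep only the 14 days that follow the exclusion
   window. Sex-based analyses pass `Inf`.
3. **Burst deduplication** (`deduplicate_bursts()`, default gap 60 s): maximal
   runs of same-tag reads with successive gaps at or below the threshold
   collapse to one *passage* stamped with the run's first read. The threshold
   is exposed because transceiver retry behaviour varies between
   installations; 60 s is a conservative default for a bat flying through an
   entrance. With a threshold of 0 no collapsing is done at all.
4. **Roost-complex merging** (`merge_roost_complex()`): where two roosts are
   close enough that individuals switch between them within a night, both
   entrances are treated as one, so an exit at one roost followed by an entry
   at the other is coded as time outside.
5. **Night assignment** (`assign_nights()`): a night runs from
   `sunset − 30 min` to the next sunrise, both computed for the site's
   coordinates with the NOAA solar-position method (`night_table()`). The
   30-minute tolerance admits occasional pre-sunset emergences (which are then
   reported as negative emergence times); anything outside every night window
   is a daytime read and is dropped with a count.

Direction is then inferred by **strict alternation** (`code_directions()`):
the first passage of a bat-night is the emergence and therefore an EXIT, the
next an ENTRY, and so on. This is the only defensible reading of a
single-antenna record. Its known failure mode is that one missed passage flips
every subsequent direction in that night. We deliberately do not attempt
probabilistic correction; instead the synthetic module quantifies the
resulting metric error as a function of the miss probability (the degradation
is monotone — see the test suite).

All timestamps are local *standard* time with an explicit UTC offset per site;
no daylight-saving rules are ever applied, so sunset-relative arithmetic is
unambiguous across years.

## The four metrics

For each bat-night (`compute_activity_metrics()`):

* **Time of emergence** — minutes from local sunset to the first EXIT
  (negative within the tolerance band). The absolute clock time is also kept,
  for single-season data sets where sunset normalisation is unnecessary.
* **Returns to the roost** — the number of ENTRY events.
* **Hours inside** — the summed durations of consecutive ENTRY→EXIT pairs.
  Time before the first exit contributes nothing, and a final unpaired ENTRY
  contributes nothing.
* **Hours of activity** — the summed durations of EXIT→ENTRY pairs.

A night whose last event is an EXIT leaves its final outside interval
unobserved. Such nights are flagged `censored_open_end = TRUE` and the open
interval is *excluded*, not truncated at sunrise: truncation would fabricate a
datum. For uncensored nights the two duration metrics partition the span from
first to last event exactly; `compute_activity_metrics()` enforces this
conservation identity to one second and fails loudly on violation.

Durations are reported in fractional hours, emergence in minutes — the units
in which effects on these metrics are conventionally discussed.

## Covariates

Food availability in columnar-cactus landscapes follows the cactus phenology;
`season_for_month()` maps months to the four-season partition
November–January = low, February–April = nectar, May–July = nectar-fruit,
August–October = fruit. Season and calendar year are assigned from the night
date (covariates are nightly, not tagging-time properties). Daily mean
temperature and precipitation join by night date; analysis rows lacking them
are dropped complete-case with a logged count. The reproductive-condition
analysis keeps females in {nonreproductive, pregnant, lactating} — males and
postlactating females are excluded — with *pregnant* as the reference level;
the sex/season analysis uses all bats with *female* and *fruit season* as
references.

## Statistical models

Two analysis modes mirror the two study designs:

**Reproductive condition (single-site, single-season)** — per metric, a GLM
with condition as the only fixed effect: Poisson(log) for returns, and
gamma(inverse) for the three positive continuous metrics. Significance of the
condition term is assessed with a likelihood-ratio test against the
intercept-only null (`lrt()`), and pairwise differences with Tukey-style
contrasts (`pairwise_contrasts()`).

**Sex and environment (multi-year, all seasons)** — per metric, a set of 16 a
priori candidate GLMMs over the fixed-effect menu {sex, season, temperature,
precipitation} with an optional sex×season interaction, each with crossed
random intercepts for bat identity and year: the null, the four single-term
models, the six additive pairs, the full additive model, and the four
interactive variants. The published analysis this reconstructs did not list
its candidate models in accessible form, so this deterministic menu is the
package's own documented choice (`build_candidate_set()`). Families follow
the response: negative binomial (NB2) for returns to absorb overdispersion,
gamma(log) for durations, Gaussian for emergence time. Models are ranked by
AIC (`select_by_aic()`); everything within 2 units of the minimum is reported
as equivalently supported, with no single winner forced.

Effect sizes (`effect_report()`) are presented on the response scale: ratios
for log links; for the inverse link, ratios of predicted means (delta-method
CIs on the log-ratio); plain differences in minutes or hours for the identity
link.

### Numerical and inferential choices

* **Tukey adjustment.** The family-wise adjustment is the multivariate-normal
  max-|z| method on link-scale contrasts: each adjusted p is the probability
  that the largest absolute standardised contrast exceeds the observed one
  under the joint normal with the contrasts' estimated correlation
  (`mvtnorm::pmvnorm`), and adjusted CIs use the matching critical value.
  This is the large-sample limit of the multivariate-t method used by
  estimated-marginal-means software; the test suite checks agreement with
  `emmeans` on shared cases.
* **Marginal means with covariates.** Contrast rows are built at the factor's
  levels with numeric covariates at their means and other factors at their
  reference level. For the single-factor reproductive-condition models this
  is exact.
* **Gamma zeros.** The gamma density is undefined at zero, and bat-nights
  with no return–exit pair have exactly zero hours inside. Such rows are
  excluded from that metric's model with a logged count
  (`drop_nonpositive()`); no offset is added, because an offset would change
  the estimand.
* **GLMM engine and fallback.** Crossed random intercepts are fitted by
  Laplace approximation (`glmmTMB`). If the optimizer fails, the Hessian is
  not positive definite, or fixed-effect standard errors come back NaN (as
  happens when an NB dispersion is unidentified on equidispersed data), the
  fit falls back to the fixed-effects GLM with cluster-robust standard errors
  on bat identity, and records that in `$fallback`. Singular fits (a variance
  component at zero) are flagged, not errors. `select_by_aic()` warns when a
  candidate set mixes engines, because such AICs are not comparable.
* **LRT degenerate case.** A model tested against itself has zero degrees of
  freedom; the p-value is defined as 1.
* **Rank deficiency.** Aliased coefficients (e.g. a covariate that is
  constant in a subset) are dropped from the coefficient table rather than
  reported as NA, and pipeline runs skip candidate models whose terms are
  constant in the data at hand.

## The synthetic colony

`simulate_truth()` generates ground truth so every stage is verifiable
without field data. Per bat-night: the emergence EXIT at
`sunset + Normal(mu_g, sd_g)` minutes; a Poisson(`lambda_g`) number of
returns; before each return a gamma-distributed outside bout, and between
consecutive returns a gamma inside gap followed by a re-exit. The sequence
therefore runs EXIT, ENTRY, EXIT, …, closing on the k-th ENTRY: a night with
k ≥ 1 returns ends inside the roost (uncensored), k = 0 leaves a lone
censored EXIT, and the expected number of returns equals `lambda_g` exactly.
Any event that would pass sunrise is dropped along with everything after it,
which can censor a night naturally. Ground-truth metrics are bookkept
analytically during generation, independently of the pipeline's metric code,
so the two can be compared event for event.

Distributional choices — normal emergence offsets, gamma (positive,
right-skewed) bouts and gaps — are modelling choices of this module, not
claims about any field system. The default colony (three female
reproductive-condition groups, 20 bats each, 14 nights from mid-April at
24.2° N) plants qualitative patterns of the kind reported for nectarivorous
colonies (a pregnant-like group returning most, a lactating-like group
foraging longest) without hard-coding any published estimate as truth.

Two generator details exist so that exactness claims are meaningful:

* Event times are whole seconds, so CSV round trips are bit-exact.
* Bout and gap durations are floored at 120 s (configurable), so genuinely
  distinct passages are never closer than the burst-deduplication threshold.
  A real colony can violate this; the floor makes "perfect detection implies
  exact recovery" a well-defined property of the chain rather than a race
  between the generator and the deduplicator.

`apply_detection_process()` then degrades truth: each passage is missed
independently with probability `detection_miss_prob` and survivors are
expanded into read bursts (1 + Poisson extra reads, 1–5 s apart).

**Truncation bias.** Because nights end at sunrise, high-rate, long-bout
configurations lose proportionally more late returns, so the *realized* ratio
of group return rates falls below the planted Poisson ratio. Recovery
experiments that assert a planted ratio therefore use modest rates and
identical bout kinetics across groups, where the truncation loss is
negligible (< 0.5%).

**What the generator does not emulate:** roost switching within a complex
beyond what the merge rule needs, tag loss and mortality, reader downtime,
heterogeneous per-bat detection probability, within-night weather, and any
spatial foraging structure. Passing the synthetic checks therefore
demonstrates the correctness of the computation chain under the stated
detection model, not the field accuracy of single-antenna activity budgets.

## Problem sizes used by the checks

The packaged verification runs use: a four-event worked fixture; a
10,038-bat-night perfect-detection colony for the exact-recovery check; 1,000
two-group null data sets (n = 200 each) for LRT calibration; 200 replicates
(n = 500 each) for CI coverage; a 200-bat × 14-night colony for planted-ratio
recovery; and 100 replicates of 40 bats × 8 nights for the AIC-selection
check. These sizes give stable Monte-Carlo behaviour at the tolerances tested
while keeping a full run in a few minutes on one core.

## Known limitations

* Direction inference cannot recover from a missed passage within the night;
  error grows with miss probability and is quantified, not corrected.
* Whether a field analysis should sunrise-truncate or exclude open-ended
  final intervals is a judgment call; this package excludes and flags them.
* The 16-model menu is a reconstruction; with the original list unavailable,
  AIC tables from this package and from the original software are comparable
  only model by model.
* Inverse-link marginal-mean ratios use the delta method; for very small
  samples the normal approximation underlying both the CIs and the max-|z|
  adjustment is optimistic.
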