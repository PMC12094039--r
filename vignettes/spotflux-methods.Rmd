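---
title: "Processing spot-sampled enteric gas records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing spot-sampled enteric gas records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated head-chamber systems (such as GreenFeed units) estimate an
individual animal's daily gas exchange — methane (CH4), carbon dioxide
(CO2), oxygen (O2) and hydrogen (H2), all in g/d — from many short,
voluntary, bait-rewarded visits scattered across days and times of day.
Each visit that passes the vendor's preprocessing yields one *visit
record*: animal, unit, start/end time, the usable ("good data") measurement
duration in minutes, and per-gas production rates. A valid spot measurement
needs at least 2 minutes of head-in-chamber time.

Spot sampling is noisy at the visit level (diurnal emission rhythm,
short-term rumen dynamics, sensor error), so a per-animal phenotype is
built by filtering and averaging. `spotflux` implements that pipeline, the
descriptive reports used to monitor a running trial, pellet-intake
accounting from the feed-drop event log, and a seeded simulator so every
stage is testable without access to a live trial.

## The processing model

Given visit records and three record-sufficiency thresholds, the engine
(`process_records()`) applies four stages in a fixed order:

1. **Duration filter.** Keep records with `good_duration_min >= min_time`
   (inclusive: "minimum duration to be included" reads as a closed
   boundary). `min_time < 2` is rejected outright, because sub-2-minute
   visits are not valid measurements.
2. **Outlier masking.** Per gas independently, compute the mean and sample
   SD once over all non-missing values pooled across animals, and set
   values outside `mean ± outlier_k·SD` (default `k = 3`) to missing. This
   is a single pass: the statistics are *not* recomputed after masking —
   the method describes one removal step, not an iterative trim. Masking
   is per gas because per-gas missingness is a normal state of these data
   (a record can lose CH4 and keep CO2); a record left with no gas values
   at all is dropped. With fewer than two values the SD is undefined and
   nothing is masked.
3. **Daily averages.** Group by animal and the calendar date of the visit
   start (farm-local time; timestamps are deliberately parsed naive, with
   no timezone conversion). Per gas, the daily mean weights each record by
   its usable duration, over records where that gas is present:
   `sum(w_i x_i) / sum(w_i)`, `w_i = good_duration_min`. An animal-day is
   emitted only when its record count reaches `param1`. A gas with no
   valid value that day is missing, never 0.
4. **Weekly averages.** Study weeks are consecutive 7-day blocks anchored
   at the study start (`week = floor((date - start)/7) + 1`) — a 46-day
   trial spans exactly 7 study-weeks, whereas ISO calendar weeks would
   split it arbitrarily. Per gas, the weekly mean weights each daily mean
   by that day's **total** visit minutes, and an animal-week is emitted
   only with at least `param2` distinct days with records.

Two consequences worth noting. Because every weighted mean is a convex
combination, daily and weekly means are always bounded by the values they
average, and equal weights reduce them to arithmetic means. And because
`param1` counts records surviving *both* upstream filters, retained
record/animal counts are non-increasing in each of `param1`, `param2` and
`min_time` — the qualitative pattern a retention-sensitivity sweep
(`param_grid()`) makes visible, and a property the test suite asserts over
many simulated trials.

One genuinely open choice: whether weekly weights should be the sum of
gas-specific minutes or of all retained minutes. We weight by all retained
minutes ("total visit record minutes"), a simplification that diverges
from gas-specific weighting only when a day's records are missing a gas
selectively; the brute-force oracles in the tests pin down exactly this
definition.

`summarize_gas()` reports n, mean, sample SD (n−1 denominator), CV =
100·SD/mean, and range. The SD of a single value is reported as 0 (not
missing) so monitoring tables stay total; this is a reporting convention,
not an estimate.

## Reports, intakes, visitation

The Markdown report (`render_report()`) contains only numbers computed by
the modules it summarizes: records per day (zero-filled over the study
window), per-animal activity (records/day uses the full study length as
denominator), the distribution of records over four 6-hour windows
aligned with ruminant feeding behaviour (22–04, 04–10, 10–16, 16–22;
half-open on the right, assigned by visit start, the first wrapping
midnight), per-animal gas distributions as boxplot five-number summaries
with 1.5·IQR whiskers, and — in `final` mode — the unfiltered diurnal
profile per time-of-day bin.

`pellet_intakes()` converts feed-drop events to daily bait intake:
`drops × grams_per_drop`, pooled across units. `grams_per_drop` has no
default on purpose: cup masses vary with feed and calibration, and a
silent default would corrupt intakes. Visit delimitation (for the
`n_visits` column and for `visits_per_animal()`/`nonvisitors()`) groups
consecutive drops separated by at most 300 s (configurable) into one
visit; intake totals never depend on it. Visitation monitoring operates on
the feed-drop log rather than on preprocessed records because early-trial
monitoring must see visits too short to yield a valid record.

## The synthetic world

`simulate_trial()` generates, per animal-day, a Poisson number of visits
(`visit_rate_per_day`); each visit gets an hour from a 24-point intensity
profile (daylight-weighted, never zero at night so all reporting windows
receive records), a lognormal duration, and per-gas production

```
x = m_a · (1 + A·(cos(2π(t − peak)/24) − c0)) + ε,   ε ~ N(0, σ_visit)
```

where `m_a` is the animal's true mean (herd mean + N(0, σ_animal)), `A`
is the diurnal amplitude and `c0` centres the cosine on the visit-hour
distribution, so that the visit-weighted expectation of each animal's
records equals `m_a` — this is what makes "truth recovery" a well-posed
test. With probability `outlier_prob` a record's gases are all multiplied
by `outlier_scale` or its reciprocal (equal odds), putting contamination
in both tails of the distribution. Timestamps are whole seconds and
durations/gas values are rounded to 2 decimals — the precision a device
export carries — so written CSVs round-trip exactly.

The `paper_like` profile emulates a published 46-day, one-unit trial with
32 mid-lactation Holstein cows:

* **Visit intensity** 2.32 visits/animal/day (3,420 records / (32 × 46)).
* **Durations** lognormal with mode ≈ 3 min and ≈ 10% of visits under the
  2-minute validity threshold, so the duration filter has work to do.
* **Record-level totals** CH4 375 ± 118 g/d and CO2 12,264 ± 1,967 g/d
  (mean ± SD), *contamination included*, since the published numbers
  describe unfiltered records. The within-visit SD is derived from a
  variance budget: total variance = contamination-inflated (between-animal
  + diurnal + within-visit) variance, with between-animal SDs of 60 (CH4)
  and 1,000 (CO2) g/d — the between/within split is a modelling choice,
  not a published value.
* **Contamination** 1% of records at scale 2.5. The scale is capped by the
  budget itself: ×3 contamination on CO2 alone would exceed the stated
  total CO2 variance, leaving a negative within-visit variance, so 2.5 is
  the largest feasible half-integer scale.
* **O2 and H2** (8,900 and 4 g/d) are not published for this trial; they
  are physiologically plausible values for mid-lactation Holsteins (O2
  mass ≈ CO2 × 32/44 at respiratory quotient ≈ 1; H2 a few g/d) and exist
  so that per-gas code paths are exercised.
* **Diurnal pattern** amplitude 0.10 peaking at 13:00 — emission is
  lowest in the early morning before feeding and rises through the
  morning, the shape reported for lactating cows fed in the morning.

What the simulator does *not* emulate: unit queueing and competition
between animals, day-to-day autocorrelation within animal, drift or
calibration error in the sensor, diet changes, and weather. A green test
therefore establishes that the pipeline's arithmetic and filtering
semantics are correct under a realistic magnitude/noise regime — not that
any biological inference from a real trial is valid.

One consequence of this stated world is worth recording. With symmetric
×s/÷s contamination and the totals calibrated as above, the ÷s tail of
contaminated records can never leave a band of mean ± 3·(total SD) — that
would need s > 17 — so the expected masked fraction under 1% contamination
is the catchable upper 0.5% times its band-exceedance probability plus the
Gaussian 3σ tail, about 0.49% in total. The calibration suite asserts a
[0.5%, 3%] band for this quantity and that lower edge sits marginally
above what this world can produce; the assertion is left failing rather
than loosened, because the generator's parameters are part of the stated
world, not dials.

## Numerical and interface choices

* Degenerate inputs: empty files read to empty tables with a warning (not
  an error); malformed rows are dropped and counted by reason
  (`ingest_report()`), never aborting — field data are dirty and reports
  must still render; `rows_kept + rows_dropped = rows_read` always.
* A gas value of exactly 0, blank, or negative is treated as missing for
  that gas: the preprocessing system emits rows whose gas estimate failed.
* Identifier canonicalization trims, strips leading zeros from all-digit
  IDs (zero-padded RFID transponders), then maps through an optional
  roster; it is idempotent, and all animals present in a file are
  processed whether or not a roster is supplied.
* Visit-file and feedtimes dialects are configurable column maps; the
  defaults cover the common export layout, and `GoodDataDuration` is
  accepted both as `HH:MM:SS` and as decimal minutes.
* Output tables are CSV. No XLSX writer is available in this environment,
  so `write_table(format = "xlsx")` raises an informative error rather
  than silently substituting; CSV opens in any spreadsheet application.
* The CLI accepts YAML or JSON config files (no TOML parser is
  available); flags win over the file, the file over built-in defaults,
  and every run writes a JSON manifest with its options and stage counts.

## Limitations

* The weekly-weighting definition (all retained minutes) may diverge from
  implementations that weight by gas-specific minutes when gases go
  missing selectively within a day.
* The outlier filter pools animals; with strong between-animal spread a
  3·SD band is conservative for mid-range animals and permissive for
  extreme ones. That is the published procedure, reproduced deliberately.
* Sample-SD-based masking is itself sensitive to contamination (the band
  widens with the outliers it is meant to catch); robust alternatives
  (MAD-based bands) are out of scope.
* The simulator's between/within variance split and the O2/H2 levels are
  modelling choices; conclusions that depend on them should be checked
  against trial data.
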