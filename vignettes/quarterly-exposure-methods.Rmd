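---
title: "Quarterly exposure-to-risk from dated microdata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quarterly exposure-to-risk from dated microdata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qexposure)
```

## The problem

Registry microdata carry, for every resident and every demographic event,
the exact calendar dates involved: the date of birth, and for deaths,
births and residential moves the date of occurrence. From those dates one
can place each person-instant on the Lexis plane — calendar time on one
axis, age on the other, each life a 45° line — and summarise stocks and
flows at sub-annual resolution without ever publishing an individual
record. `qexposure` implements that summarisation: quarterly event counts
and exposure times per (year, sex, integer age, age quarter, calendar
quarter) cell, smoothed daily series, weekday tabulations, and the
validation reports that check the results against each other.

## Calendar model and the Lexis grid

All dates are proleptic Gregorian, with no time-of-day component: a day is
the atom of the calculation, and every coordinate is evaluated at the
*start* of a calendar day. This makes the analytic engine exactly
comparable, bit for bit, with a brute-force oracle that classifies every
single day — which is how the partition code is tested.

Three conventions close the edge cases the calendar leaves open:

* **Age increments on the anniversary day itself.** Offset 0 belongs to the
  new age-year, so consecutive age-years compose without overlap or gap.
* **February 29 birthdays fall on February 28 in non-leap years.** Any
  consistent rule works; this one keeps the anniversary inside February.
  Consequently an age-year is always 365 or 366 days long.
* **Age quarters split the age-year by days, not months.** With `o` days
  since the last birthday and `D` the age-year length, the quarter index is
  `floor(4·o/D) + 1`; the boundary days sit at offsets `ceil(q·D/4)`.

The reference data product these conventions emulate does not document its
own choices at this level, so boundary disagreements of up to one day per
boundary with that product are possible; within this package the
conventions are applied uniformly and verified by property tests.

## Exposure computation

A calendar-year window of presence is partitioned analytically: the only
candidate breakpoints are the calendar-quarter starts (April 1, July 1,
October 1), the anniversary, and the age-quarter boundary days of the two
age-years touching the window — at most ten dates, against which the
window is segmented and each segment classified by its first day. Exposure
is accumulated in *integer day counts* per cell, with the year length
attached; division into fractional person-years happens only at
serialisation. This is why the conservation identities in the test suite
are asserted with `expect_identical`, not with a tolerance:

* each January-1 stock resident contributes exactly `year_length(Y)` days;
* for exits (deaths, emigrations) the event day is excluded from exposure,
  for entries (immigrations) it is included, so exposure plus non-exposure
  is exactly one person-year for anyone born before the event year.

The event-day convention (exits exclude, entries include) is a genuine
design choice — the half-open composition makes complements exact; sources
that count both the entry and the exit day would differ by one day per
event.

Event counts use the same grid: each event adds one to the cell of its
Lexis position on the event day. Counts deliberately carry the integer-age
column as well as the quarter labels, because total-exposure computation
joins counts and times by (age-calendar quarter, integer age, year).

The one systematic discrepancy between counts and times is documented by
`reconcile()`: a person born *within* the event year counts as a whole
event but contributes less than one person-year of presence, so the
relative difference `100·(time − count)/count` is never positive and is
zero exactly when no record is born within its event year.

## Summary tables and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 3 | moving-average half-width; window 2k+1 = 7 days |
| `horizon_years` | 100 | confidentiality horizon on published birth dates |
| age bands | [0,16), [16,65), [65,∞) | daily migration series grouping |

Moving averages omit the window edges rather than padding them — omission
never fabricates values. The 100-year suppression is applied *after*
averaging: the old dates still participate in windows centred on published
dates, they are just not published themselves. The daily migration series
(E_5/I_5) are emitted per sex and additionally for both sexes combined
(`gender = "all"`), since the reference layout lists only age groups and a
combined series is the safest superset.

The January-1 de-heaping correction estimates, per birth year, the genuine
January-1 count as the rounded mean daily count over the *rest of that
year* — the simplest unbiased local baseline — and re-dates the excess
January-1 records uniformly over the remaining days of the same year. The
record count and the birth-year marginals are conserved, and the operation
is deterministic given its seed.

## The synthetic registry generator

Because real registry microdata are confidential, every pipeline stage is
exercised against a generator whose structure is known exactly:

* **birth dates**: month drawn from 12 relative weights, day uniform within
  the month, then weekend dates thinned by rejection with factor
  `weekend_birth_factor ≤ 1` (expected Saturday share `f/(5+2f)`);
* **mortality**: annual death probability `min(1, a·e^{b·x})` at integer
  age `x` (Gompertz), capped to certain death at age 105 to avoid
  empty-cell explosions; the death day is drawn with per-day seasonal
  weights, so the expected winter share is `w_W·d_W / Σ_s w_s·d_s` with
  `d_s` the season's day count;
* **migrations**: per-capita annual probabilities, event days uniform
  except September scaled by `september_peak_factor`;
* **heaping**: each immigrant's birth date is overwritten to January 1 of
  its year with probability `jan1_heaping_rate`;
* **order of risks**: within a year, emigration is drawn first and death
  only among those who stay; newborns and immigrants of year Y join the
  stock of Y+1 and are not themselves at risk in Y. This keeps the
  closed-population identity `stock(Y+1) = stock(Y) + B + I − D − E` exact
  by construction, per year and sex.

`fertility_rate` is a *per-capita* annual birth rate (births are Poisson
with mean `rate × stock size`), so configurations scale coherently with
`n_stock`; the default 0.009 is in the range of recent southern-European
crude birth rates. The default configuration — 10,000 residents, five
simulated years, mild birth seasonality, a 15% weekend birth deficit,
winter-excess season weights (1.30, 0.95, 0.85, 0.90), Gompertz `a = 10⁻⁴`,
`b = 0.09`, migration rates 2%/1.5% with a 1.5× September peak, 5% January-1
heaping — is the condition under which the parameter-recovery checks run,
and `ground_truth_summary()` returns the closed-form expectations those
checks compare against (always within three standard errors of the
realised sample size).

What the generator deliberately does **not** emulate: cohort-size
variation (the age pyramid is the stationary one implied by the Gompertz
schedule), within-year competing risks for newborns and immigrants,
February 29 births (tests construct those directly), record linkage across
files, geographic structure, and administrative registration delays.
Passing the recovery tests therefore shows that the pipeline measures the
injected structure correctly — not that real registries are this simple.

## Numerical and degenerate-input choices

* Empty or inverted windows partition to zero rows; empty inputs produce
  empty but schema-valid tables throughout.
* Exposure cells absent from a ledger contribute zero when ledgers are
  combined.
* All builders are pure functions of (inputs, parameters, seed); output
  files are sorted by their key columns and written in a fixed dialect
  (semicolon delimiter, dot decimal, UTF-8, LF), so repeated runs are
  byte-identical.
* Strict date validation: impossible dates (Feb 29 in a non-leap year,
  April 31, rolled-over forms) are rejected at parse time, in both the ISO
  and the `ddmmyyyy` dialect; a 7-digit string is re-padded on the
  assumption that numeric storage stripped a leading zero.
* Weekday names are computed from the day number modulo 7 against a fixed
  epoch, so they are locale-independent English names.

## Problem sizes

The test suite verifies the analytic partition against day-by-day
classification on 1,400 random person-years (400 in the unit tests, 1,000
in the end-to-end checks), including forced February 29 births, leap
years and window boundaries; conservation identities on 1,000-person
stocks and event streams; and the full pipeline on registries of 600–
10,000 residents over one to five years. The de-heaping check uses 20,000
records at a 5% heaping rate. These sizes keep the whole suite in the
low minutes on a single core while leaving binomial standard errors small
enough for three-sigma recovery bounds to be meaningful.

## Known limitations

* Each record is processed within a single valuation year; multi-year
  exposure for one record is out of scope (as in the source statistics,
  records are independent).
* Immigrant deaths in the arrival year are not linked (presence for exits
  starts at max(Jan 1, birth)); the statistics are computed per file, not
  per person.
* The de-heaping baseline assumes the non-January-1 days of a birth year
  are approximately uniform; strong genuine seasonality biases the
  estimated excess slightly.
* The confidentiality horizon suppresses by the birth date of the
  published row (the window centre), not by window membership.
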