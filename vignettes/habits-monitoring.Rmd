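---
title: "Habits monitoring from two home sensors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habits monitoring from two home sensors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(habitviz)
library(dplyr)
```

## The problem

Frail, elderly people living alone can be monitored unobtrusively with a
very small sensor set: one passive-infrared (PIR) motion sensor in the main
living space, and one pressure pad under the mattress reporting bed `usage
start` / `usage end` messages. From those two discrete event streams alone,
a surprising amount of behavioral information can be extracted — bed and
wake times, sleep continuity, nocturnal bathroom visits, overall daytime
activity — and *changes* in those habits can flag deterioration before a
clinical event. habitviz implements the full path from raw events to
clinician-oriented summaries and figures, plus a simulator that generates
event streams with known ground truth so every stage can be tested without
patient data.

## Sensor physics

Two hardware behaviors shape the data and are modelled explicitly:

* **Motion dead time (2 minutes).** After emitting an event the PIR ignores
  further movement for 2 minutes (battery and bandwidth saving). The
  simulator implements this as a *non-retriggerable hold-off*: the first
  latent trigger is emitted, then every trigger strictly within the dead
  time of the last **emitted** event is suppressed. The alternative
  retriggerable model (each suppressed trigger restarting the clock) would
  let a continuously active subject produce *no* events, which contradicts
  how such sensors report; it is rejected. A consequence used by the tests:
  emitted inter-event gaps are always ≥ the dead time, and continuous
  motion yields events exactly 2 minutes apart.
* **Usage minimum registration (30 seconds).** The pad reports a state
  change only once the new state has persisted 30 s. We model this as state
  smoothing *before* emission: sub-threshold vacancies are merged into the
  surrounding occupancy, then sub-threshold occupancies are dropped; what
  survives is emitted as alternating start/end pairs at the true transition
  times. Smoothing-before-emission guarantees no orphan messages. The
  boundary is inclusive: a state lasting exactly 30 s *is* registered —
  "minimum time that must be registered" reads naturally as ≥.

## The activity function

Clinicians prefer a continuous level-of-activity trace over raw impulses.
Motion events are treated as unit-weight impulses and convolved with a
normal Gaussian kernel, σ = 15 minutes, truncated at ±3σ:

```{r kernel}
tz <- "Europe/London"
ev <- event_stream(as.POSIXct("2023-03-01 12:00:00", tz = tz),
                   "s1", "pir-1", "motion", "motion")
af <- activity_function(ev, kernel_params(),
  span = as.POSIXct(c("2023-03-01 09:00", "2023-03-01 15:00"), tz = tz))
max(af$activity)          # peak = 1/(15 sqrt(2*pi)) events/min
sum(af$activity)          # integral ~ 0.9973 of one event
```

Numerical choices, all configurable through `kernel_params()`:

* **No renormalization after truncation.** The truncated kernel keeps
  ≈ 99.73% of its mass; we keep the raw truncated density so the kernel is
  exactly the stated object, and tolerate (and test) the ≤ 0.3% mass
  deficit rather than hide it.
* **1-minute sampling grid.** The sensor's 2-minute dead time makes
  sub-minute structure uninformative; a finer grid would only cost memory.
  `resolution` must not exceed σ, or the sampled kernel would alias.
* **Units: events per minute.** With a unit-area kernel the function
  integrates to the event count, giving the tests a conserved quantity.

## Counting windows and the night

Event counts are reported per hour and per *day part*: early morning and
waking [06:00, 10:00), daytime [10:00, 22:00), nighttime [22:00, 06:00 the
next day). The three windows tile the 24-hour day exactly. All bins are
half-open, and the night is attributed to the **evening's** date — a
clinician reads "the night of day D" — so "day D" for counting purposes
runs 06:00 D to 06:00 D+1.

Per-night features live in a fixed 18-hour window from 18:00 (anchor date)
to 12:00 (next day). From the bed sensor: time in bed, time out of bed,
total period between them, accumulated time in / out of bed, continuity
(accumulated-in / total, 1 = uninterrupted night), and the mean time of
being in bed. From the motion sensor: nocturnal inactivity — start, end,
duration and mean time of the longest motion-free gap.

Design decisions where the definitions were genuinely open:

* **Mean time of being in bed** is the occupancy-weighted *centroid* of
  in-bed time, computed on an 18:00-anchored linear axis so midnight
  wraparound cannot corrupt it. This reading provably keeps the mean inside
  [time in bed, time out of bed]; a plain midpoint of first/last times
  would ignore interruptions.
* **An interval already in progress at 18:00** counts, clipped, with
  time-in-bed = 18:00 and a `window_truncated` flag: the "(after 18:00)"
  qualifier bounds the *search window*, not the behavior.
* **Nocturnal inactivity** is operationalized as the longest inter-event
  gap that intersects the night core 22:00–06:00 and lasts at least
  `min_gap` (default 3 h, configurable). Gaps touching the window edge use
  the boundary as a censored endpoint and are flagged. Brief morning
  returns to bed are *not* ignored: "the (last) time out of bed (before
  12:00)" is implemented literally.
* **Durations are integer seconds** throughout, so the conservation
  identity accumulated-in + accumulated-out = total holds exactly, not to
  floating-point tolerance.
* Missing nights are never dropped: every anchor date yields a row, with
  reason codes (`no_usage_events`, `unpaired_only`, `no_motion_events`,
  `no_qualifying_gap`).

## Baselines: usual pattern vs running average

Reviewing clinicians used "usual pattern" and "moving average"
interchangeably; the package deliberately keeps them as two distinct named
concepts:

* `usual_pattern()` — a **within-day shape**: per-bin mean ± sample sd of
  daily profiles over a trailing window (default 21 days, minimum 7
  complete days), excluding the day under review so today's anomaly cannot
  dilute its own template. Works on hourly, day-part or per-minute bins.
  `deviation_bounds()` draws mean ± k·sd lines (k default 1; the sd uses
  the n−1 denominator and a single contributing day suppresses the bounds).
* `running_average()` — an **across-day smoother**: trailing mean of one
  daily series, missing values excluded from numerator and denominator.
  Trailing, never centred: the tool is prospective and future data does not
  exist at review time. The window length is exposed because reviewers
  explicitly asked to vary it.

Whether the deployed 21-day template was rolling or fixed, and whether its
bounds were ±1 or ±2 sd, is not recoverable; both are configuration here
(`usual_pattern.window_days`, `deviation.k`).

## What the simulator emulates — and what it does not

`behavior_profile()` + `generate_schedule()` draw, per night: a bed
interval (normal bed/wake clock times), Poisson-count nocturnal exits with
exponential durations, and latent motion triggers as a Poisson process at a
constant hourly rate while out of bed and zero in bed (the bed is outside
the PIR's field of view by design). Defaults — bed 22:30 ± 30 min, wake
07:00 ± 30 min, 1.5 exits/night of ~5 min, 8 triggers/hour — were chosen
once as a realistic frail-elderly routine; no deployment event rates are
published to calibrate against, and the defaults are documented as this
package's choice. `inject_anomaly()` perturbs only targeted dates (delayed
bedtime, multiplied exit rate, thinned daytime activity) so recovery tests
can assert direction and locality.

Passing tests on simulated data show the *pipeline algebra* is right —
transitions are recovered exactly, counts partition, anomalies move the
right features on the right days. They do not show robustness to things the
generator does not model: visitors and pets triggering the PIR, sensor
drift or misplacement, radio loss bursts (the pairing rules handle loss
gracefully but the generator does not emit lossy streams), naps in view of
the sensor, or daylight-saving transitions mid-night (civil-time arithmetic
is used throughout; the two DST nights a year land inside the night window
and shift durations by an hour).

## Visualization catalogue

The final, clinician-preferred views (identifiers kept from the design
catalogue) are rendered from processed artifacts only — never recomputed
inside the plotting layer — so computation stays testable without pixel
comparison. Daily-series views draw the actual data as points and the
running average as a solid line; the 24-h motion view shows only the signed
difference from the usual pattern; the stacked-area bed view stacks
running-average in/out-of-bed hours and contains no raw points; day strips
rasterize each day as a 1440-minute vertical strip. Colour semantics
default to the final-cycle choices (actual blue, pattern dark grey, in-bed
green, out-of-bed red) and are configurable. Figure tests assert structure
— layer geometry and the data attached to it — not pixels, which font
rendering would make platform-fragile.

```{r demo, fig.alt = "stacked running-average bed occupancy"}
sched <- generate_schedule(behavior_profile(), n_days = 21, seed = 7)
evs <- simulate_events(sched)
feats <- nightly_feature_table(evs, sched$nights$anchor_date)
plot_usage_stacked_area(feats, window_days = 7)
```

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and is reproducible
bit-for-bit from `(profile, seed)`. The test suite exercises the identities
on 1000 random nights, mass conservation on 100 random streams, and
ground-truth recovery on 50 simulated nights; the Monte-Carlo anomaly
checks use 200 replicate seeds. These sizes give the estimators standard
errors comfortably below the asserted tolerances while keeping the default
suite quick on a laptop.

## Known limitations

* One motion plus one usage sensor; no multi-room fusion, no chair-specific
  behavior model.
* No sleep staging or actigraphy scoring — features derive only from
  presence/absence and event gaps, by design.
* No changepoint detection or alerting beyond the ±k·sd lines; the tool
  stops at visual comparison.
* The interactive dashboard of the deployed system is out of scope; output
  is static images plus CSV tables.
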