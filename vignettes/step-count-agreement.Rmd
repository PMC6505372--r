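---
title: "Validating wearable step counts: agreement statistics and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable step counts: agreement statistics and the synthetic study generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepagree)
```

## The problem

Consumer activity trackers report step counts on their own schedules — some
once a minute, some every few minutes, some only when they sync, and simple
pedometers only once a day via a diary. To decide whether such a device is
accurate enough for telemonitoring (for example, watching for a declining
activity trend in a patient with COPD or hypertension), it is validated
against a research-grade accelerometer worn simultaneously under free-living
conditions, typically for about 72 hours in around 30 volunteers.

`stepagree` implements that validation workflow end to end: a neutral CSV
interchange format for epoch-level step streams, reference-defined nonwear
cleaning, aggregation to per-participant paired totals, and the agreement
statistics used to judge the devices. Because raw data from such studies are
rarely shareable, the package also ships a simulator that generates
ground-truth activity and device-observed streams with the failure modes
these studies report — systematic under- or over-counting, sparse and
irregular reporting, whole lost days, battery death, and phantom steps
appearing overnight — so every stage of the pipeline can be exercised and
tested without any real data.

## Agreement statistics

For each tracker, participants' step totals over the analysis window are
paired with the reference totals. With differences
$d_i = \mathrm{ref}_i - \mathrm{trk}_i$:

* **Bias**: $\bar d$, the mean difference. The direction is fixed as
  reference minus tracker, so a *positive* bias means the tracker
  *undercounts*.
* **SD**: the sample standard deviation of the $d_i$ (denominator $n-1$).
* **95% limits of agreement**: $\bar d \pm 1.96\,s_d$. The multiplier is
  exactly 1.96, not a t-quantile; published step-count validation tables
  reproduce bias $\pm 1.96 \times$ SD to the step, and the package keeps
  that convention so its output is comparable.
* **MAD%**: $\mathrm{median}_i\,\lvert \mathrm{trk}_i - \mathrm{ref}_i
  \rvert / \mathrm{ref}_i \times 100$. The median (standard mean-of-two for
  even $n$) is used because 72-hour totals are strongly skewed across
  participants; 15% is the conventional clinical acceptability threshold,
  and the report flags devices against it.
* **LOOCV-corrected MAD%**: for each participant $i$, a bias
  $b_{-i} = \mathrm{mean}_{j \ne i}(d_j)$ is estimated on the other $n-1$
  participants and added to tracker total $i$; the MAD of the corrected
  pairs estimates the accuracy a user could achieve by calibrating the
  device's systematic error, without evaluating any participant on a
  correction trained on their own data.

The additive correction matches the Bland-Altman bias definition and is the
default. A proportional variant (`method = "proportional"`, multiplying by
the training ratio of means) is provided because a device whose error scales
with activity is better described multiplicatively, but it is not the
default: the bias being corrected is defined additively.

The contrast between the two MAD columns is diagnostic. A device whose error
is a stable systematic offset (like a hip tracker that consistently misses
~9% of steps) improves dramatically after correction; a device whose error
is dominated by participant-to-participant variance (like a diary pedometer
whose placement varies) improves little, because there is no stable bias to
learn. The test suite asserts this contrast quantitatively on replicated
simulated studies.

## Cleaning pipeline

**Nonwear detection** uses the reference stream only: maximal runs of
consecutive zero-step minutes of at least `nonwear_min_run` minutes (default
60) are flagged nonworn. The rule is strict — no interruption tolerance —
because commercial nonwear algorithms are proprietary and undocumented; the
simplest defensible convention is used and the threshold is exposed as a
parameter. Minutes inside the reference span with no data are treated as
zero-count, so long reference outages fold into nonwear rather than passing
silently. Sleep shows up as nonwear under this rule; since the reference
records zero steps while off-wrist or at rest, excising those intervals
removes no reference steps, only tracker artifacts.

**Masking** excises the nonworn intervals from every device of that
participant by wall-clock interval, because tracker epochs are irregular and
never align with reference epochs. Epochs fully inside a nonworn interval
are dropped; partial overlaps are trimmed to the worn sub-intervals with
steps apportioned proportionally to retained length and rounded to the
nearest integer (a 5-minute epoch of 50 steps losing 2 minutes keeps 30).
Trimming (rather than keeping the full epoch with scaled steps) makes a
masked stream's coverage equal exactly its worn data time, which the
aggregation step relies on. Proportional apportionment assumes steps are
uniform within an epoch; for coarse epochs straddling a worn/nonworn
boundary this slightly attenuates devices whose steps are concentrated in
the worn part. This is an inherent cost of interval masking at mismatched
resolutions, and it is why identity checks on 5-minute devices in the test
suite allow a few steps of slack while 1-minute devices must match exactly.

**Diary devices** (one epoch spanning a calendar day or more) cannot be
sub-day masked: the written-down daily total cannot be localised within the
day. Day epochs are therefore handled all-or-nothing — dropped only when the
whole day is nonworn, kept intact otherwise — both during masking and during
aggregation. This is a documented caveat of once-daily devices, not an
error.

**Aggregation** sums steps over the wall-clock set on which *both* members
of a pair have worn data: the analysis window intersected with the
reference's and the tracker's post-mask coverage. A tracker that loses one
day still contributes a pair computed over the remaining shared time (the
reference total shrinks correspondingly); a tracker with no usable time, or
a pair with non-positive reference total (MAD divides by it), is dropped
with a reason recorded in the exclusions table. The analysis window is per
participant: `window_hours` (default 72) from that participant's first
reference epoch.

## The synthetic study generator

Ground truth is generated at 1-minute resolution as a bout process, the
simplest structure that yields realistic mixtures of slow and fast walking:

* Bouts start as a Poisson process at `bout_rate` per hour within the waking
  window (default 07:00–23:00); each lasts an exponential number of whole
  minutes (mean `bout_duration`, default 4) and contributes a Normal cadence
  per minute (`cadence_mean` 80, `cadence_sd` 15, truncated at zero).
  Overlapping bouts superpose, which keeps the expected total in closed
  form.
* Every waking minute adds Poisson incidental steps (`background_rate` 0.5
  per minute).
* Sleep (outside the waking window) is zero steps. Sleep is *in-window
  zero-step time*, not nonwear; explicit device-off intervals can be
  injected through the study configuration's `nonwear` list, during which
  all devices read zero.

The closed-form expectation (`expected_steps()`) is
`bout_rate × waking_hours × bout_duration × cadence_mean +
background_rate × waking_minutes`, per day. When a profile is given a
`daily_total_target`, `bout_rate` is solved from this expression, which is
how studies are calibrated: participant heterogeneity is modelled by drawing
each participant's daily target from a log-normal with median 7,176
steps/day (21,527 per 72 h, the median reported for healthy adults over such
windows) and log-SD 0.2. Together with within-person bout noise this places
simulated 72-hour reference totals in the observed 10,000–36,000 range for
well over 95% of participants, which the test suite verifies over 100
study replicates. Bouts are clipped at the end of the waking window, so
realized totals run about 1% below the closed form; the calibration tests
use tolerances wide enough to see this and would catch anything larger.

A `deterministic = TRUE` profile lays bouts on a fixed, evenly spaced daily
schedule with exact integer cadence. It exists for exact arithmetic checks
in tests and worked examples, not for realistic simulation.

**Device observation** applies, in order: low-cadence minute misses
(minutes below `low_cadence_miss_threshold` steps/min dropped with
probability `low_cadence_miss_prob` — defaults off, since published
validation studies report no per-device cadence-dependent miss rates to
anchor them); re-binning to the device's update interval (fixed blocks, or
exponentially distributed gaps quantised to whole minutes for variable-rate
devices, the mean gap fixed by the average number of data points such
devices deliver over 72 h); deterministic under-/over-count scaling by
`1 - undercount_fraction` with rounding; additive Gaussian per-epoch noise;
the overnight carryover artifact (uniform phantom steps added to the first
epoch of each calendar day, emulating trackers that fail to reset to zero
overnight); whole-day malfunction loss; and battery-death truncation at a
uniform random time.

One numerical choice deserves note: per-epoch Gaussian noise clamped at zero
would systematically *inflate* low-count epochs (for an epoch with true
count far below the noise SD, `E[max(0, x + noise)]` substantially exceeds
`x`), silently turning a configured undercounter into an overcounter. Noise
is therefore applied only to epochs whose count is at least twice the noise
SD; the clamp then fires with probability below 2.3% and the truncation bias
is under 0.01 SD per epoch, so expected totals track
`(1 - undercount_fraction) × truth` as the error model intends. The
interpretation is that miscount noise scales with activity, while a
near-idle device reports what it counted.

**Default device models** (`default_device_models()`) emulate the behaviour
classes reported for consumer trackers validated this way: an error-free
1-minute reference; a variable-interval smartwatch (mean gap 9.25 min ≈ 467
points/72 h, 4.5% undercount, 10% battery-death risk); a 5-minute hip
tracker (9.4% undercount, rare day loss); a sparse-syncing tracker (mean gap
131 min ≈ 33 points/72 h, overcounting, noisy, carryover 100–600 steps/day);
and a once-daily diary pedometer (9.3% undercount, large day-level noise,
frequent lost days). The sparse tracker's overcount fraction (−0.12) is set
so that its bias *after* the cleaning pipeline — which, as noted above,
attenuates coarse-epoch devices — still comes out clearly negative
(overcounting), emulating the published behaviour of such devices
net of the same pipeline. These defaults are the package's chosen study
conditions; they are deliberately not re-tuned per analysis.

All timestamps are timezone-naive local time stored as UTC, day boundaries
at midnight, and every interval is half-open `[start, end)`. Seeds: a study
seed deterministically derives one sub-seed per stream, so studies are
reproducible byte-for-byte from the configuration alone, and the test suite
checks this at the file level.

## What the simulator does and does not establish

Passing tests on simulated studies show that the statistics are computed
correctly, that cleaning and pairing bookkeeping is exact, and that the
estimators recover known error parameters (a configured 2,004-step expected
deficit is recovered as the mean Bland-Altman bias across replicate
studies, within Monte-Carlo error). They do not show that any real device
has these error characteristics: real trackers have activity-dependent,
wear-site-dependent and firmware-dependent errors that no low-dimensional
error model captures, real nonwear is not always a clean zero-run, and the
simulator models neither heart rate, distance, intensity, nor wrist-versus-
hip differences. Published per-device MAD values depend on the original
studies' unreleased raw data and cannot be reproduced from simulation; what
can be, and is, checked are the internal identities of the published tables
(LoA = bias ± 1.96 × SD to the printed step) and the qualitative
correctability contrast between constant-bias and high-variance devices.

## Problem sizes and numerical conventions

The test suite and acceptance script run: 500 replicate studies of n = 30
for bias recovery; 200 replicates for the correction-contrast properties;
100 study replicates (3,000 participants) for the calibration range check;
brute-force oracle equivalence at 1e-9 relative tolerance on all fixtures
of n ≤ 5; and exact (to-the-step) checks on the hand-computed 3-participant
toy study with an injected 90-minute nonwear run, one lost tracker-day and
one fully lost stream. Reported tables round steps to integers and MAD to
one decimal, matching the precision of published validation tables; JSON
output retains full precision. Ties in the median take the standard
mean-of-central-two; no special handling.

## Known limitations

* Proportional apportionment of partially masked epochs assumes
  within-epoch uniformity of steps; coarse devices are slightly attenuated
  at worn/nonworn boundaries (quantified above).
* The 60-minute strict zero-run rule is a stand-in for proprietary nonwear
  detection; whether commercial software tolerates interrupted runs is
  unknown, so the threshold is exposed rather than hard-coded.
* When reference hours are missing, the pipeline shortens the shared
  analysis window (via coverage intersection) rather than imputing; runs
  record the exclusion reasons but do not attempt recovery.
* Vendor export formats (XML/JSON/CSV dialects) are out of scope; users
  convert to the neutral schema documented in `read_streams()`.
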