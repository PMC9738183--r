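---
title: "Methods: contactless two-stage sleep scoring in somnokit"
author: "somnokit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless two-stage sleep scoring in somnokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnokit)
```

## Scope and data model

`somnokit` analyses one-night, 1 Hz multi-channel recordings from a
contactless sensor suite: an eight-FSR pillow pressure array (sensor 0
leftmost, 7 rightmost), sound pressure level (dB), contactless body
temperature, room temperature, humidity, CO2, optional illuminance, and an
optional wearable heart-rate channel that serves exclusively as the
validation reference. Time is integer seconds since session start; all
event intervals are half-open `[start, end)`; scoring epochs are 60 s by
default (the last epoch may be partial). Sessions are stored as RFC-4180
CSV with a fixed header vocabulary (`t, p0..p7, sound_db, body_temp_c,
room_temp_c, humidity_pct, co2_ppm, lux, hr_bpm`); doubles are written at
17 significant digits so that write–read round-trips are bit-exact.
Missing samples are not represented: short gaps (≤ 5 s) can be imputed at
read time by holding the last sample, and the imputed indices are flagged.

## Posture discrimination

The pressure centroid — the index-weighted mean of the eight readings — is
a scale-free summary of head position. The heuristic model maps a window's
mean-profile centroid `c` to `LEFT` if `c ≤ 3`, `RIGHT` if `c ≥ 4`, else
`SUPINE`; cuts are placed so the symmetric centre (3.5) is supine. A window
whose mean total load falls below 5 % of the calibration head-on mean
(default calibration 250 force units, the nominal simulated head load) is
`OFF_PILLOW`. The low-index-means-left convention is arbitrary and
configurable; nothing downstream depends on it.

The margin classifier is a radial-kernel SVM on an 18-value window feature
vector: 8 per-sensor means, 8 per-sensor standard deviations, the centroid
of the means and the total mean load. Features are accumulated per minute
by default; per-second frames work through the same interface (a window of
one frame). The training protocol is a stratified 80/20 split under a
fixed seed; `cost = 10` with the default kernel width is sufficient on the
synthetic benchmark and both hyperparameters are exposed.

### Night segmentation

Posture is discriminated on a variable cycle: 60 s windows by default,
shortened to 10 s whenever a supra-threshold pressure delta lies within
the upcoming base window, until the deltas subside. Three further choices
make segmentation robust, and are deliberate design decisions rather than
consequences of the classification rule:

* windows classify from their *quiet* frames (sub-threshold deltas only);
  movement transients carry no posture information and would otherwise
  drag the window profile toward the centre;
* a label switch is accepted only if supra-threshold movement occurred in
  the current or previous window — a posture cannot change without
  movement. This suppresses flapping when a profile sits near a centroid
  cut;
* centroid models additionally apply a hysteresis margin of 0.2 sensor
  units: leaving the running posture requires clearing the cut by the
  margin.

Segments tile the session exactly; each boundary emits one
`POSTURE_CHANGE` event.

## Event detection

**Toss-and-turn.** The movement statistic is the summed absolute
per-sensor change between consecutive seconds. The threshold defaults to
4× the median nightly delta — the median is dominated by quiescent sensor
noise, so the default adapts to the (arbitrary) FSR scale; a numeric
threshold can be supplied instead. An event opens at the first
supra-threshold second and closes once deltas have stayed at or below the
threshold for 5 consecutive seconds ("no change in pressure for 5 s" —
exact-zero change would be vacuous under noise); the recorded interval
spans the supra-threshold activity. Event *duration* is first-class
output: for staging, how long the sleeper moved matters more than how
often. Events separated by less than the quiescence gap within one posture
segment are merged.

**Snoring.** A capture opens when the SPL exceeds 30 dB and closes when
the level falls back to the threshold or at the 15 s capture cap; the
detector then stays dead for 2 s before re-arming. Distinct threshold
crossings are distinct events even inside one notional capture window.
Each event records its peak dB and the onset-to-onset gap to the previous
event. Regularity is operationalized as the coefficient of variation
(sd/mean) over a sliding window of the five preceding onset intervals:
regular iff CV ≤ 0.25. Both the window and the cut are configurable; the
first events of a bout, lacking a full window, carry an undefined flag.
The sound channel is an SPL series — audio content (e.g. separating
snoring from teeth grinding) is out of scope.

**Heart rate.** Maximal runs below 60 bpm (bradycardia) or above 100 bpm
(tachycardia), strict inequalities, become events when they last at least
5 s; the minimum suppresses single-sample flicker while real episodes last
minutes.

**CO2.** Concentrations are banded GOOD < 400 ≤ AVERAGE < 700 ≤ POOR <
1000 ≤ VERY_POOR ppm, left-closed. CO2 is context, not a staging input:
its overnight drift mostly tracks time asleep.

**Temperature artifacts.** The contactless thermometer aims at the head;
during a posture change it briefly reads 33.5–34 °C. Samples within ±30 s
of any posture-change boundary are flagged and excluded from temperature
statistics. An optional additive calibration offset (default 0) models the
up-to-±2 °C seasonal drift of the sensor.

## Two-stage scoring

The epoch feature table aggregates movement (count, rate, overlap
duration), snoring (count by onset epoch, regular fraction, mean
intensity), masked body-temperature mean/sd, room temperature, CO2,
dominant posture, and — for reference only — heart-rate mean/sd.

The rule-based scorer is a linear-weighted combination of three bounded
NREM-likeness terms (see the README for the formula), with weights
(0.5, 0.3, 0.2) for movement, snoring and temperature. The sign of the
movement term deserves emphasis, because two readings circulate in the
sleep-monitoring literature: frequent posture change is sometimes
described as heralding the transition into NREM, yet overnight recordings
consistently show frequent tossing during REM and waking and long
maintained postures during NREM. This package follows the latter,
empirical account — the movement term is the reciprocal `1/(1 + rate)`, so
quiet epochs score toward NREM — and flags the choice prominently here
because it is the central modelling decision a reviewer should see. The
weights
reflect the same account: movement is the strongest single discriminator,
snore regularity second, temperature stability a weak tiebreaker. Epochs
without snores take a neutral 0.5 snore term (no evidence either way), as
do epochs with undefined regularity or fully masked temperature.

Tree classifiers (CART decision tree, random forest; fixed seed,
reproducible) train on the same features with heart-rate columns excluded
by construction — the model class validity enforces it. `NA` features are
imputed with their neutral values before training (0.5 regularity, 0
intensity, median temperature spread). WAKE reference epochs are mapped to
REM for binary training and evaluation: in this framework WAKE resembles
REM (movement, irregular or absent snoring, elevated heart rate), and the
scorers emit only the two sleep stages.

The heart-rate reference hypnogram (NREM iff epoch mean ≤ 65 bpm and
sd ≤ 5 bpm) shares no input channel with the scorers, so agreement between
the two is a meaningful validation statistic rather than a tautology.
Evaluation reports accuracy, precision, recall and F1 at the 0.5 cut and
AUC by the trapezoidal rule over the empirical ROC (one point per distinct
score, anchored at (0,0) and (1,1)); REM is the positive class — a choice
that the source metric table leaves unstated.

## The synthetic night generator

Hardware recordings of this kind are not redistributable, so the simulator
is a first-class module: every pipeline stage is tested against its ground
truth. Its defaults, fixed once, are the generative regime every packaged
benchmark assumes:

| quantity | default | note |
|---|---|---|
| night | 6 h, four 90 min cycles | NREM block then REM block per cycle |
| REM fraction | 0.15 → 0.35 across cycles | REM minutes strictly increase |
| terminal wake | 5 min | movement-heavy tail |
| pressure profiles | per-posture 8-vectors, peak ≈ 80 units | supine centred, left/right skewed |
| pressure noise | sd 3/sensor/s; head shift sd 0.5 sensors; load sd 10 % | per-segment shift and load |
| movement | 4 (NREM), 60 (REM), 120 (WAKE) events/h, 2–4 s | plus 3 s posture-change transients, amplitude 40 |
| posture changes | 3 per REM/WAKE hour | confined to REM/WAKE by default |
| snore intervals | N(3, 0.3) s NREM; N(6, 4) s REM; floor 3 s | see below |
| snore bursts | 1 s at max(N(40, 3), 30.5) dB over a 25 dB floor | floor keeps detection non-trivial |
| heart rate | N(58, 2) NREM; N(75, 8) REM; N(80, 5) WAKE bpm | stand-ins for "low" vs "relatively high" |
| episodes | bradycardia 54 bpm in NREM, tachycardia 105 bpm in REM, 0.5/h, 30–90 s | |
| CO2 | 450 ppm + 60 ppm/h drift, +10 ppm during snores, noise sd 5 | |
| body temperature | 36.5 °C, dips to 33.5–34 °C for 15 s + 30 s recovery at posture changes | |
| room | 22–23 °C band; humidity 50 % + 0.5 %/h | |

Each channel draws from its own deterministically derived substream, so
adding or resizing one channel never perturbs another; identical
`(params, seed)` give bit-identical sessions.

Grid-closure choices: on a 1 Hz SPL channel with a 2 s detector dead time,
two snore onsets closer than 3 s cannot be resolved, so bursts are 1 s
plateaus and onset gaps are floored at 3 s; the REM interval distribution
therefore has a point mass at 3 s and its realized mean is ≈ 6.5 s, which
leaves the NREM/REM CV separation intact (window CV ≤ 0.25 for > 99 % of
NREM windows, > 0.25 for ≈ 94 % of REM windows). Burst level is floored
just above the 30 dB cut because a "snore event" is by definition a
supra-threshold sound — this is what makes the closure invariant (every
injected event is detectable in the zero-noise limit) hold exactly. The
movement rates have no authoritative reference values; they were chosen
once to express the qualitative picture the scorer assumes (quiet NREM,
frequent light movement in REM, near-constant movement when awake) at
magnitudes a sleep researcher would accept for a restless sleeper, and are
configurable.

What the simulator does **not** emulate: FSR drift, hysteresis and
temperature sensitivity; respiratory or cardiac fine structure (no HRV
spectra — heart rate is white noise around stage means); apnea; audio
content; multiple sleepers; room-climate interventions. Passing tests
therefore demonstrate that the pipeline recovers the *structure* this
generative world shares with real overnight recordings — not clinical
validity on real sleepers. In particular the near-perfect synthetic
benchmark scores (posture accuracy ≈ 100 %; staging AUC ≈ 1.0, where
mid-90s percentages and AUC ≈ 0.9 are typical of comparable hardware
studies) reflect the simulator's cleanliness:
snore interval statistics separate the stages almost perfectly by
construction.

## Numerical choices and degenerate inputs

* Session CSV doubles at 17 significant digits (exact round-trip); t on an
  integer grid, non-monotone timestamps rejected, gaps > 5 s rejected.
* All-zero pressure frames have an undefined centroid (error in
  `pressureCentroid()`); in window features an empty-pillow window takes
  the centre value 3.5 and is caught by the presence threshold first.
* REM epochs per cycle are rounded with a +1e-9 nudge: the binary
  representation of 0.35 × 90 falls a hair below 31.5 and naive rounding
  would break the strictly-increasing REM schedule.
* Single-class training inputs error (posture classifier, stage
  classifier, AUC).
* Events returned by every detector satisfy the shared invariants (sorted,
  non-overlapping per kind, half-open, `end > start`), enforced by
  `validateEvents()` in the test suite's property checks.

## Benchmark problem sizes

The packaged benchmarks use 3 × 500 one-minute posture windows (stratified
80/20 split), 20 simulated 6 h nights (15 train / 5 test) for the
random-forest staging AUC, 1 000 random 10-minute streams per detector for
the brute-force oracle-equivalence sweeps, and 10 seeds for the
Monte-Carlo check of the stage-conditioned heart-rate means. These sizes
give stable estimates (binomial se < 1 % on the accuracy benchmarks) while
keeping the full suite fast on a single CPU.

## Known limitations

Three lying postures only (no prone); two sleep stages only (the evidence
channels cannot resolve the four-stage architecture); the heart-rate
reference is itself a heuristic, not polysomnography; WAKE is only
available from simulator truth or as a terminal-wake reading of sustained
movement with tachycardia; no real-time ingestion. The default thresholds
(30 dB, CV 0.25, 65/5 bpm) suit the simulator's regime and a
single-sleeper, quiet-bedroom setting; on new hardware they are the first
thing to re-examine.
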