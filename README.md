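# somnokit

Contactless, unconstrained sleep-pattern monitoring in R: posture
discrimination from an eight-sensor pillow pressure array, toss-and-turn and
snore event detection, and two-stage (REM/NREM) sleep scoring validated
against a heart-rate reference.

## The problem

Polysomnography scores sleep accurately but requires electrodes and a lab.
An alternative is to watch a sleeper with nothing attached to the body: a
pillow with eight force-sensitive resistors (FSRs) sampled at 1 Hz, a
sound-pressure-level sensor, a contactless body-temperature sensor, room
climate and CO2 sensors, and (for validation only) a wrist heart-rate band.
`somnokit` implements the full analysis chain for such recordings, for
researchers in unobtrusive sleep monitoring who need a tested, reproducible
reference pipeline — plus a seeded full-night simulator, because published
recordings of this kind are rarely redistributable.

## The model

Each 60 s epoch is scored by a sleep-state function over three evidence
terms, each mapped to an NREM-likeness score in [0, 1]:

    nrem_score = w_move * s_move + w_snore * s_snore + w_temp * s_temp

* `s_move = 1 / (1 + r)`, with `r` the toss-and-turn rate (events/min):
  long maintained postures mean NREM, frequent movement means REM.
  Movement events are detected from the inter-frame pressure delta
  `sum_i |p_i(t) - p_i(t-1)|` over the 8 sensors, with a 5 s quiescence rule
  closing each event.
* `s_snore` = fraction of the epoch's snores flagged *regular*
  (coefficient of variation of the last five onset-to-onset intervals
  <= 0.25). Snoring at steady ~3 s intervals marks NREM; irregular snoring
  marks REM. Snores are captured when the SPL exceeds 30 dB (15 s maximum
  capture, ~2 s re-arm delay).
* `s_temp = 1 / (1 + sd)` of the artifact-masked body temperature: the
  contactless sensor mis-reads during posture changes (dips to
  33.5–34 °C), so ±30 s around each posture change is excluded.

Default weights are (0.5, 0.3, 0.2); an epoch is NREM iff
`nrem_score >= 0.5`. Alongside the rule, decision-tree and random-forest
classifiers can be trained on the same epoch features (never on heart
rate). Validation uses a heart-rate-derived reference — NREM iff epoch mean
<= 65 bpm and sd <= 5 bpm — with accuracy/precision/recall/F1 at the 0.5
cut and AUC by the trapezoidal rule, REM being the positive class.
Bradycardia (< 60 bpm) and tachycardia (> 100 bpm) episodes and CO2
air-quality bands (400/700/1000 ppm) are annotated as additional context.

## Worked example

```r
library(somnokit)

path <- system.file("extdata", "synthetic_session.csv", package = "somnokit")
s <- readSession(path)
s
#> SessionRecord: 240 s (4.0 min) at 1 Hz
#>   start: 2021-10-22T00:00:00
#>   channels: pressure[8], soundDb, bodyTemp, roomTemp, humidity, co2, lux, heartRate

seg <- postureSegments(s)
seg$segments
#>   posture start end duration
#> 1   RIGHT     0 240      240

snore <- snoreRegularity(detectSnoreEvents(s))
nrow(snore); mean(snore$interval, na.rm = TRUE)
#> [1] 56
#> [1] 4.22                      # ~3 s intervals in NREM, longer/looser in REM

toss <- detectTossTurn(s, segments = seg$segments)
fe <- epochFeatures(s, list(tossTurn = toss, snore = snore,
                            postureChange = seg$changes), seg$segments)
rb <- stageRuleBased(fe)
round(rb$scores$nrem_score, 3)
#> [1] 0.989 0.990 0.690 0.689   # regular snoring pushes epochs 1-2 to NREM

stageLabels(hrReferenceHypnogram(s))
#> [1] "NREM" "NREM" "REM"  "REM"
```

The four-minute demo session has two NREM-scheduled and two REM-scheduled
epochs. The first two score 0.99 (quiet, regular snoring) and the last two
0.69: their snoring is irregular, but they contain no movement, so the
movement term still pulls them above the 0.5 NREM cut — exactly the kind of
epoch the independent heart-rate reference (last line) catches. On full
nights, where REM epochs do carry movement, rule-based agreement with the
simulator's ground truth is ≥ 80%; see the methods vignette
(`vignettes/somnokit-methods.Rmd`) for what the simulator does and does not
emulate.

A command-line interface wrapping the same functions ships in
`inst/scripts/somnokit.R` (subcommands `simulate`, `detect`, `posture`,
`stage`, `evaluate`, `pipeline`, `report`).

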