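---
title: "Assessment methods: tracking, game responses and outcome reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessment methods: tracking, game responses and outcome reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpkit)
```

`rtpkit` implements the computational core of a game-based assessment
platform for manual dexterity rehabilitation. A player manipulates an
instrumented everyday object (a ball, a mug, a dowel) whose rotation drives a
one-dimensional game paddle on screen; standardized game trials are logged at
100 Hz and scored automatically. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic player can
and cannot establish.

## Coordinate and logging conventions

The screen is the unit square, origin top-left, x rightward, y downward.
The paddle is one-dimensional: it slides along a fixed axis line
(y = 0.95 for falling-object games) and its scalar position is `paddle_pos`.
Timestamps are integer milliseconds from trial start; the default 100 Hz
sampling gives 10 ms spacing with no jitter modeling, and
`duration_s * sample_rate_hz` must be a whole number of samples. A session is
stored as a JSON header (configuration, participant, event stream) plus a
CSV sample table; doubles are written with 17 significant digits so the
files round-trip bit-exactly.

## Cyclic tracking (CT)

The CT target oscillates about the screen centre as
$x(t) = c + A\sin(2\pi f t + \phi)$ with configurable amplitude $A$ and
frequency $f$. A sinusoid is the minimal smooth cyclic waveform consistent
with "configurable amplitude and frequency" (the waveform shape itself is
not prescribed by the platform description), and it makes half-cycle
segmentation analytic.

Performance measures:

* **Residual error.** Per sample, $e_i = |x^{target}_i - x^{paddle}_i|$
  along the movement axis. The **total residual error** (TRE) is
  $\sum_i e_i$ and the **average residual error** (ARE) its mean. Absolute
  rather than signed differences are used so errors on opposite sides of the
  target cannot cancel; axis-wise absolute error in normalized units is the
  documented interpretation (a Euclidean definition would be identical here,
  since the paddle only moves along one axis).
* **Amplitude variation.** Half-cycle boundaries are placed at consecutive
  extrema of the *target* waveform — every $1/(2f)$ s from the first
  extremum at a quarter period — rather than at detected paddle extrema,
  which stays well defined for impaired, non-periodic paddle motion. Each
  half-cycle's movement amplitude is the paddle's peak-to-trough excursion
  within the closed interval (the turning-point sample belongs to both
  neighbouring half-cycles, so a perfect tracker scores exactly $2A$). The
  coefficient of variation is $100 \cdot SD/\bar{a}$ using the sample
  ($n-1$) SD; a COV is only reported from at least 4 analyzed half-cycles,
  and a zero mean amplitude flags the COV as undefined rather than dividing
  by zero.
* **Exclusion rule.** The first two full target periods are excluded from
  both the residual errors and the amplitude statistics, because subjects
  typically need a cycle or two to engage with the target. "Two cycles" is
  measured from trial start (four half-cycles). Trials shorter than three
  target cycles are rejected: the exclusion would leave nothing.

A 30 s trial contains $2fd$ half-cycle intervals including the trailing
partial stretch between the last extremum and trial end; that partial
interval is reported by the segmentation (`complete = FALSE`) but never
enters the amplitude statistics, since it is not a full half-cycle of
movement.

## Motor skill game (MSG)

A trial of duration $d$ with event duration $\delta$ schedules
$\lfloor d/\delta \rfloor$ back-to-back game events. Each object spawns at a
uniformly random admissible position on the far screen edge and travels in a
straight line to the paddle's axis line, arriving exactly at event end; its
speed is therefore derived ($0.95/\delta$ normalized units/s) rather than
independently configurable. Events are distractors with probability
`distractor_fraction`; diagonal trajectories offset the arrival point
laterally by 0.25 normalized units with a random sign, clipped to the
admissible range. One object is on screen at a time; a coexisting-distractor
mode is out of scope.

Per-event scores:

* **Success** is decided at the arrival sample only — the games catch
  falling objects at the paddle line, not during transit. A target is caught
  iff the paddle centre is within `paddle_halfwidth + object_radius` of the
  arrival coordinate; a distractor is handled successfully iff the paddle is
  *not* overlapping there. The success rate (SR) is the percent of target
  events caught; distractor events never enter the denominator.
* **Movement onset time** (MOT; the outcome tables' "response time") uses a
  two-threshold (hysteresis) detector, described below.
* **Movement time** (MT) runs from onset to arrival stabilization: the last
  time the paddle enters the catch window and remains inside it through
  event end. If the paddle does not end the event inside the window there is
  no stabilization and MT is missing.
* **Movement error** (ME) is the mean absolute deviation of the paddle from
  the required interception coordinate over the samples from onset to event
  end, in normalized units. It deliberately includes the transit: a slow or
  meandering approach scores worse than a crisp one, matching the intent of
  a "magnitude of movement error" measure. ME is missing when no onset was
  detected.
* **Movement variation** is the coefficient of variation of the
  per-response peak displacement within each movement-direction group, with
  the same minimum-group-size rule as the CT COV. "Response time" and
  "movement time" are distinct measures here; the published tables report
  only the former, which this package maps to MOT.

### Onset detection

The platform description names MOT but prescribes no detector. The package
uses a relative-displacement rule with debounce — onset is the first time
the paddle has moved at least 5% of the required movement distance from its
pre-movement position, sustained for at least 30 ms — hardened in three ways
that matter on noisy pediatric/impaired traces:

1. **Baseline.** The pre-movement position is the mean over the first 50 ms
   (and the required distance is measured from this baseline to the arrival
   coordinate). A single noisy sample as reference makes every later
   displacement inherit its error.
2. **Noise floor and hysteresis.** A robust noise estimate $\hat\sigma$
   (MAD over the first 100 ms) sets two thresholds: movement is *confirmed*
   at the first sustained crossing of
   $\max(0.05\,d,\ 3\hat\sigma)$, then the onset is read by walking back to
   the last sample below $\max(0.05\,d,\ 1.28\hat\sigma)$ and linearly
   interpolating the crossing time. At zero noise both thresholds collapse
   to the plain 5% rule. Movements whose required distance does not clear
   the confirmation floor ($d < 3\hat\sigma$) are reported as undetectable
   (`NA`): their plateau cannot reliably cross any threshold, and a forced
   answer would be a noise artefact placed hundreds of milliseconds late.
3. **Interpolation.** Reporting the interpolated threshold crossing rather
   than the first supra-threshold sample removes most of the one-sample
   quantization bias.

With the simulator, this detector recovers programmed reaction times with a
mean delay of about +8 ms at zero noise (it must wait for 5% of the distance
to be covered) and stays within 20 ms at position noise SD 0.02 normalized
units — the acceptance suite asserts exactly this, at reaction times of
200, 300 and 500 ms.

## The synthetic player

The simulator is a pure-delay + gain + additive-noise response model — the
simplest model whose parameters map one-to-one onto the performance
measures:

| parameter | units | default | maps to |
|---|---|---|---|
| `tracking_lag_ms` | ms | 0 | CT residual error |
| `gain` | — | 1 | half-cycle amplitude (CT), endpoint reach (MSG) |
| `noise_sd` | normalized units | 0 | amplitude COV, ME |
| `reaction_time_ms` (± SD) | ms | 300 | MOT |
| `miss_prob` | probability | 0 | success rate |
| `max_speed` | units/s | 2 | movement time |

For CT, `paddle(t) = c + gain * (target(t - lag) - c) + e(t)`: the gain
multiplies the displacement about the waveform centre (it is a gain on the
*movement*, not on the screen coordinate, so a timid tracker stays centred).
For MSG, the paddle holds until the drawn reaction time, then moves toward
the arrival coordinate along a minimum-time ramp bounded by `max_speed`
(2 screen-widths/s by default — generous enough that a default player
catches everything), with a Gaussian endpoint error.

Two modeling choices deserve justification:

* **Missed events are errant responses, not resting paddles.** `miss_prob`
  exists to make SR controllable. A paddle that simply rests at screen
  centre is "caught" by luck whenever a target happens to arrive nearby
  (with default geometry about 16% of the time), which would break both
  SR = 0 at `miss_prob = 1` and SR ≈ 100 (1 − `miss_prob`). A missed target
  therefore elicits a movement toward a random location outside the catch
  window — an *inadequate* response rather than no response.
* **One RNG stream per log.** Every simulation seeds its own stream and
  restores the caller's RNG state; the schedule is driven by the trial
  seed and the player by its own, so (config, player, seed) determines the
  session files byte for byte.

The simulator emulates response timing, spatial precision and lapses. It
does **not** emulate biomechanics (no spasticity, fatigue, tremor spectra or
submovement structure), so a green parameter-recovery test establishes that
the *analysis chain* is correct — that programmed latencies, gains and miss
rates survive the trip through logging, segmentation and scoring — not that
the metrics are clinically valid for any patient population.

## Outcome and reliability reporting

Pre/post outcome tables report each participant's measure averaged over the
two practiced movement directions, the integer percent change
$100(post - pre)/pre$, and the group average of the rounded changes.
Rounding is half-away-from-zero, the convention that reproduces every
self-consistent printed cell of the published pilot tables. Latency
improvements are conventionally printed as positive percent *reductions*
($100(pre - post)/pre$); before rounding the two conventions are exact
negatives. A zero pre score makes the change undefined and is flagged, never
silently dropped.

The packaged worked-example tables (`cue_participants()`, `cue_pdms()`,
`cue_task_table()`) are transcribed cell by cell as printed. Recomputing the
percent-change columns from their own pre/post cells exposes a handful of
internal inconsistencies — one out-of-range score, one cell off by a single
rounding step, and several percent cells in the fine-rotation table that do
not follow from their own row. These are catalogued in `cue_errata()` and
asserted in the tests; `corrected = TRUE` applies the documented
corrections, and nothing is corrected silently.

Test-retest reliability uses ICC(2,1): two-way random effects, absolute
agreement, single measure, computed from the variance decomposition
$ICC = (MS_R - MS_E) / (MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$. The platform
literature says only "interclass correlation coefficients"; ICC(2,1) is the
conventional choice for test-retest designs where sessions are a random
factor, and the implementation is configurable enough to audit (the tests
cross-check it against `stats::aov` mean squares). Derived quantities:
$SEM = SD\sqrt{1 - ICC}$ over all scores, and the minimal detectable change
at the 95% level $MDC = 1.96\sqrt{2}\,SEM$, also expressed as a percent of
the grand mean. A score table with zero total variance is flagged degenerate
rather than producing 0/0.

## Worked example

```{r example}
cfg <- msg_config(duration_s = 60, event_duration_s = 2, rng_seed = 42)
player <- player_model(reaction_time_ms = 350, reaction_time_sd_ms = 40,
                       noise_sd = 0.01, miss_prob = 0.2, seed = 43)
log <- simulate_msg(cfg, player)
msg_summary(log)
```

```{r ct-example}
ct <- simulate_ct(ct_config(duration_s = 30, target_frequency_hz = 0.25),
                  player_model(tracking_lag_ms = 150, noise_sd = 0.02, seed = 1))
ct_summary(ct)
```

## Known limitations

* The logger records at most one active game object per sample; scenes
  where a distractor and a target coexist are not representable.
* CT analysis assumes the sinusoidal target of this package's generator;
  logs from an external front end with a different waveform would segment
  incorrectly.
* Onset detection requires roughly 100 ms of pre-movement baseline;
  reaction times much below that bias the noise estimate.
* The outcome tooling reproduces single-group pre/post percent-change
  reporting only; between-group inference is out of scope.
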