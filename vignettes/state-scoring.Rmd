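---
title: "Scoring sleep and freezing from cortical spindle power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep and freezing from cortical spindle power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlescore)
```

## The problem

Longitudinal rodent electrophysiology needs automated behavioral-state
scoring: which stretches of a recording are slow-wave sleep (SWS), REM sleep,
quiet wakefulness, or freezing. The classical recipe detects immobility from a
motion readout and then splits it by the hippocampal theta (6--9 Hz) over
delta (0.5--4 Hz) power ratio: theta-dominated immobility is REM, the rest is
taken to be SWS. That recipe presumes all immobility is rest. In fear
paradigms it is not: freezing is immobility too, and the respiration-coupled
~4 Hz rhythm that accompanies rodent freezing falls inside the delta band, so
the theta/delta ratio cannot tell a freezing animal from one in SWS. Scoring
freezing and sleep independently then labels the same minutes as both.

`spindlescore` implements an alternative: sleep spindles (9--17 Hz
thalamocortical bursts) occur in SWS and not in freezing, so the *smoothed*
spindle-band amplitude of a single neocortical channel separates the two.
Individual spindles are brief, but they are frequent enough in SWS that a wide
Gaussian smoothing of the spindle-band Hilbert envelope is roughly constant
and high throughout SWS, and stays at the noise floor during any awake
immobility. Across a session's immobility the smoothed envelope is therefore
bimodal, and an unsupervised two-means threshold separates the modes.

## The pipeline

`score_session()` runs five detectors in a fixed order, each consuming the
remainder left by the previous one, which guarantees zero pairwise overlap
between states by construction:

1. **Immobility** — speed below a threshold; movements shorter than 0.2 s are
   ignored and bouts shorter than 1.5 s dropped. The threshold is supplied by
   the user or estimated as the two-means split of log speed (unreliable when
   the session is all-moving or all-still; a warning says so).
2. **SWS** — cortical LFP band-passed 9--17 Hz, Hilbert envelope, Gaussian
   smoothing (14 s), two-means threshold on the immobility-restricted samples
   (thinned to one per 0.5 s to reduce serial correlation); supra-threshold
   immobility becomes SWS after closing gaps < 1 s and dropping bouts < 30 s.
3. **REM** — within the remaining immobility, 1 s bins of the theta/delta
   power ratio above a threshold (hippocampal channel: fixed at 1; cortical
   fallback: Otsu threshold of the 8 s-smoothed log ratio) form candidates of
   at least 5 s, kept only if they start within 30 s of the end of a SWS
   epoch — REM is nested in sleep cycles and never occurs in isolation.
4. **Quiet wakefulness** — remaining immobility epochs ending within 2 min
   before a SWS onset. Animals readjust posture before sleeping, so the
   immobility that runs into sleep is waking rest, not freezing.
5. **Freezing** — everything still left, with interruptions < 0.2 s bridged
   and bouts < 2 s dropped.

`standard_score()` implements the classical baseline (freezing = immobility
≥ 1.5 s; sleep = immobility ≥ 60 s split by a two-means threshold on the
theta/delta bins) with its freezing and sleep pipelines deliberately
independent, to expose the overlap failure the spindle pipeline avoids.

## Parameters

All knobs live in `scoring_params()` with the defaults above (bands in Hz,
durations in seconds). The ones that matter most:

- `spindle_smooth_window` (14 s) and `cortical_ratio_smooth_window` (8 s).
  These are Gaussian **standard deviations** by default
  (`smooth_window_is_sd = TRUE`), the convention of the Matlab smoothing
  utilities this field uses. Setting `smooth_window_is_sd = FALSE` reads them
  as total kernel support (SD = window/6). We default to the SD reading
  because only it produces the "relatively constant" smoothed spindle power
  the method relies on: under the support reading, shot noise from
  individual spindle events (a few per minute) leaves the smoothed envelope
  fluctuating across the threshold and SWS shatters into sub-minimum
  fragments.
- `sws_min_duration` / `sws_max_gap` (30 / 1 s), `freezing_min_duration` /
  `freezing_max_gap` (2 / 0.2 s): bout filters; gap comparisons are strict
  (`< max_gap` merges), duration comparisons inclusive (`>= min` survives).
- `rem_max_delay_after_sws` (30 s): SWS-to-REM transitions last up to tens of
  seconds, so at least 30 s should be allowed.
- `quiet_wake_max_lead` (120 s): reasonable choices span 30 s to a few
  minutes.
- `sws_effectiveness_floor` (0.5) and `sws_contrast_floor` (1.5): the
  no-sleep guards, below.

## Numerical choices

**Smoothing-window quality.** `separation_effectiveness()` scores a two-group
split by `m = 1 - sigma_i / sigma_tot` (population variances; pooled
within-group over total). `smoothing_window_sweep()` reports `m` across
candidate smoothing windows; on sessions mixing sleep and freezing it rises
from short windows to a plateau containing the 14 s default.

**No-sleep sessions.** A two-means split of *any* roughly Gaussian unimodal
sample still "explains" about 64% of the variance (split a standard normal at
its mean: the between-class share is 2/pi), so an effectiveness floor alone
cannot recognize a session without sleep. Smoothed spindle envelopes are
positive, and the designed SWS/floor contrast is threefold or more, while a
unimodal noise floor splits into groups whose means differ by a few percent.
`detect_sws()` therefore declares no sleep (with a warning, not an error)
when the high/low group-mean ratio falls below `sws_contrast_floor = 1.5`,
keeping the `m` floor as a secondary guard.

**Exact 1-D two-means.** In one dimension both k-means clusters are
contiguous runs of the sorted sample, so `kmeans2_threshold()` finds the
global within-group sum-of-squares optimum by scanning all sorted splits with
prefix sums. This is deterministic and is a fixed point of Lloyd's algorithm;
plain Lloyd iterations from fixed starting centroids reach a merely local
optimum on a few percent of skewed samples, which is why the exact scan is
used. The threshold is the midpoint of the two centroids — in 1-D, exactly
the nearest-centroid assignment boundary.

**Otsu on the log ratio.** The cortical theta/delta ratio spans several
decades (REM bins can exceed awake bins 10,000-fold). Equal-width-bin Otsu on
the linear ratio puts the cut far above the REM mode, and linear-scale
smoothing smears the huge REM values tens of seconds into adjacent sleep. The
cortical REM mode therefore smooths and thresholds `log(ratio)` and reports
the back-transformed cut. The hippocampal mode keeps the fixed threshold of 1
on the linear ratio.

**Filtering.** All band-pass filtering is zero-phase (4th-order Butterworth,
forward-backward) so envelope timing stays aligned with behavior; signals are
mirror-padded before filtering and smoothing (reflection indices fold, so
kernels wider than the signal still leave constants fixed). When a band's low
edge is a tiny fraction of Nyquist (delta at 1250 Hz) the direct IIR design
is ill-conditioned; the trace is then filtered at an internally decimated
rate and spline-interpolated back, which is exact for the band-limited
result. `score_session()` decimates LFP to `analysis_rate = 250` Hz up front:
every band used lies below 20 Hz, so this loses nothing and keeps 30-minute
sessions fast.

**Intervals.** Epochs are half-open `[start, end)` tibbles in seconds;
touching intervals merge on construction, so durations add exactly and masks
round-trip. Detectors close gaps before applying duration filters (merging
rescues bouts fragmented by micro-movements), then re-intersect with
immobility (SWS/REM) or re-subtract already-claimed states (freezing), which
is what makes the zero-overlap and subset invariants structural rather than
empirical.

## The synthetic generator

No public recordings accompany the method, so `generate_session()` renders
sessions with the statistical structure the classifier assumes, from a
planned state timeline (`state_plan()`, `random_state_plan()`): per state, a
recipe of sinusoids plus broadband noise (SD 0.2); SWS adds 1.5 Hz delta
(amp 1.0) and Poisson-placed 12 Hz Hann-windowed spindle bursts (amp 0.8,
0.7 s, 0.25 bursts/s); freezing a 4 Hz rhythm (amp 1.0); REM 7.5 Hz theta;
speed traces sit below (immobile) or above (active) the designed threshold of
1, with brief 0.1--0.2 s spikes inside immobile stretches to exercise
gap-closing. Everything is a deterministic function of the seed.

Two generator choices deserve note. Bursts are placed by a Poisson process,
so burst lulls of tens of seconds occur at realistic rates; the smoothed
envelope then dips below threshold and the detector loses those stretches —
recovery is therefore high but deliberately not perfect. And in random plans
a rest block that follows freezing starts with 150--300 s of locomotion: the
method's own premise (and rodent physiology) is that animals do not move from
fear-induced freezing into sleep within two minutes, so ground truth that
placed freezing just before sleep onset would contradict the quiet-wakefulness
rule by construction, not test it.

What the generator does *not* emulate: 1/f background spectra, ripples,
respiration-locked modulation, electrode artifacts, gradual state
transitions, or across-animal variability. Passing recovery tests on these
sessions shows the pipeline implements its stated rules and separates the
designed contrasts; it does not certify performance on real recordings.

## Problem sizes used in tests

The test suite verifies the zero-overlap and subset invariants on 100 random
~32-minute sessions, recovery (median per-1 s-bin agreement >= 90%, median
SWS boundary error <= 5 s) and the hippocampal/cortical REM correspondence
(>= 85% of REM bins) on 20 sessions, threshold-oracle equivalence on 1,000
random inputs, and the freezing/sleep failure-mode contrast on a
freezing-only session. `scripts/acceptance.R` recomputes the same quantities
from scratch for any seed.

## Known limitations

- The speed-threshold estimate is ill-posed on sessions that are entirely
  moving or entirely still; supply `speed_threshold` for such data.
- SWS boundaries inherit the smoothing timescale: onsets/offsets are accurate
  to a few seconds, and deep spindle lulls inside real SWS will split bouts.
- REM detection is anchored to *detected* SWS; if SWS ends are detected
  early by more than `rem_max_delay_after_sws`, the following REM epoch is
  lost (raise the delay for fragmented sleep).
- The cortical REM fallback assumes some REM is present in the session;
  on REM-free sessions the Otsu cut sits inside noise, and candidates are
  mostly, but not provably, removed by the SWS-anchoring rule.
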