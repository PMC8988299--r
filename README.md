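# spindlescore

Automated behavioral-state scoring for rodent electrophysiology: partitions
immobility into **slow-wave sleep (SWS)**, **REM sleep**, **quiet
wakefulness**, and **freezing** from one neocortical LFP channel plus a motion
readout (e.g. IMU angular speed), with an optional hippocampal channel for REM
detection.

## Why

The classical sleep scorer detects immobility and splits it by the hippocampal
theta/delta power ratio (theta 6–9 Hz, delta 0.5–4 Hz). In fear paradigms this
fails structurally: freezing is immobility too, and the ~4 Hz
respiration-coupled rhythm that accompanies rodent freezing sits *inside* the
delta band, so both freezing and SWS look delta-dominated and the standard
freezing and sleep scorers label the same minutes as both behaviors.

Sleep spindles (9–17 Hz thalamocortical bursts) occur in SWS and not in
freezing. Spindles are brief, but frequent enough in SWS that the spindle-band
Hilbert envelope, smoothed with a wide Gaussian (14 s), is high and roughly
constant through SWS and stays at the noise floor in any awake immobility.
Across a session's immobility the smoothed envelope is bimodal, so an
unsupervised two-means threshold separates sleep from non-sleep immobility:

1. **immobility**: speed < threshold (movements < 0.2 s ignored, bouts ≥ 1.5 s);
2. **SWS**: smoothed spindle envelope above the two-means threshold
   (gaps < 1 s closed, bouts ≥ 30 s);
3. **REM**: remaining immobility with theta/delta ratio > 1 (hippocampal LFP;
   or Otsu-thresholded smoothed log-ratio of the cortical LFP), within 30 s
   after a SWS epoch;
4. **quiet wakefulness**: remaining immobility ending < 2 min before SWS onset;
5. **freezing**: everything left (interruptions < 0.2 s bridged, bouts ≥ 2 s).

Later detectors consume the remainder of earlier ones, so the four states are
pairwise disjoint by construction. `standard_score()` provides the classical
baseline (independent freezing ≥ 1.5 s and sleep ≥ 60 s + theta/delta k-means
pipelines) to expose the overlap failure.

## Worked example

No public recordings accompany the method, so the package ships a seeded
generator that renders sessions (LFP + speed + ground truth) with the
statistical structure the classifier assumes:

```r
library(spindlescore)

plan <- state_plan(
  c("active", "quiet_wake", "sws", "rem", "sws", "active", "freezing", "active"),
  c(60, 60, 240, 60, 120, 60, 180, 60)
)
ses <- generate_session(plan, seed = 42)
scoring <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
scoring
#> <state_scoring>
#>   session: 840.0 s, immobility 660.0 s, REM mode 'hpc'
#>   sws         326.2 s in 2 bouts
#>   rem          48.0 s in 1 bouts
#>   quiet_wake   60.6 s in 1 bouts
#>   freezing    225.2 s in 2 bouts

generics::tidy(scoring)
#> # A tibble: 6 × 4
#>   start   end duration state
#>   <dbl> <dbl>    <dbl> <chr>
#> 1   60   121.     60.6 quiet_wake
#> 2  121.  369.    248.  sws
#> 3  369.  417.     48.0 rem
#> 4  417.  495.     77.8 sws
#> 5  495.  540      45.2 freezing
#> 6  600   780     180   freezing

scoring_agreement(scoring, ses$truth)$agreement
#> [1] 0.912
```

The plan put 360 s of SWS, 60 s of REM, 60 s of quiet wakefulness and 180 s of
freezing among active stretches; the scorer recovers that timeline with 91% of
1-second immobility bins labeled like the ground truth (boundaries blur by a
few seconds because of the 14 s envelope smoothing). On the same session the
baseline labels *all* 660 s of immobility both "freezing" and "sleep":

```r
standard_score(ses$hpc, ses$speed, params = scoring$params)
#> <standard_scoring> (independent freezing and sleep pipelines)
#>   freezing 660.0 s | sleep 660.0 s (SWS 601.0, REM 59.0) | freezing-sleep overlap 660.0 s
```

`ggplot2::autoplot(scoring)` draws the hypnogram; `generics::glance(scoring)`
returns the thresholds and per-state totals as a one-row tibble.

Real recordings enter through `read_lfp_channel()` (Neuroscope-style
flat-binary int16, 0-based channel indexing) and `read_motion_csv()`, or from
the shell:

```sh
Rscript inst/scripts/spindlescore --lfp session.lfp --n-channels 32 --rate 1250 \
    --cortical-ch 5 --hpc-ch 12 --motion speed.csv --out scored/ --standard
```

which writes `states.tsv` (start_s, end_s, label), a diagnostics side-car, and
a log; `--synthetic default --seed 7` runs the same pipeline on a generated
session.

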