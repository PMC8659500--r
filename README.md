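# cowcollar

Calving detection from neck-mounted cattle collar logs.

On extensive farms, pregnant cows range freely and nobody sees the
calving start. A cow approaching parturition, however, becomes
restless: the frequency of her *lying bouts* (lie-down/stand-up cycles)
rises from a baseline of about 9.3 bouts/day to about 13 bouts/day on
the day of calving, with most of the increase packed into the final
hours. A cheap neck collar with an accelerometer can see this — if the
algorithm is simple enough to run on the collar's microcontroller.

`cowcollar` provides that algorithm end to end, plus everything needed
to exercise it without field data:

* a bit-exact reader/writer for the collar's fixed-width binary record
  format (13 four-byte fields: millisecond timestamp, two temperatures,
  scaled-integer GNSS, float32 accelerometer and gyroscope) with hourly
  file rollover and gap accounting;
* synchronisation of timestamped observer annotations (standing/lying
  `B1`/`B2`, or general behaviour `A1`–`A4`) with sensor streams,
  including the two-minute pre-transition exclusion that absorbs
  observer reaction lag;
* posture classification from the Y-axis accelerometer: block-mean
  resampling 17.6 Hz → 0.27 Hz, a trailing 15-minute banded count

  `f_count(t) = Σ_{i ∈ (t−15 min, t]} [thr_inf < a_y(i) < thr_sup]`,

  thresholded into the binary standing signal
  `f_standing(t) = [f_count(t) > thr_standing]`, with band and
  threshold calibrated from labelled data;
* the parturition proxy: transition signal
  `f_lb(t) = |f_standing(t) − f_standing(t−1)|` and its trailing
  five-hour count `f_parturition(t) = Σ_{i ∈ (t−5 h, t]} f_lb(i)`,
  which rises sharply shortly before calving;
* per-animal alarm triggers (running maximum over a calving-free
  calibration window + margin), gestation-window gating, refractory
  alarms, and lead-time scoring;
* a memory-bounded streaming evaluator (one 15-minute window + one
  five-hour window of state) that reproduces the batch pipeline
  exactly, as it would run on-collar;
* a behaviour simulator (`sim_scenario()`, `simulate_bout_schedule()`,
  `emit_accelerometer()`, `emit_annotations()`) generating collar
  streams and annotations with baseline bout dynamics, the 8→2 h
  pre-calving escalation, posture-conditional sensor noise and observer
  lag.

## Worked example

Calibrate posture thresholds on a day of annotated synthetic data, then
run a simulated week in which the cow calves at hour 120:

```r
library(cowcollar)

params <- synthetic_calibration(seed = 1)
params
#> <posture_params> band (0.5415, 0.9709) g, thr_standing 118/243, 900 s window at 0.27 Hz
#>   calibration: separation 236.1 counts, balanced accuracy 1.000

scenario <- sim_scenario(duration = 168, calving_time = 120,
                         seed = 101, cow_id = "cow-03")
scenario
#> <sim_scenario> cow-03: 168 h, 9.3 LB/day baseline, calving at 120 h (peak 27.1 LB/day), seed 101

run <- simulate_and_detect(scenario, params = params)
run$trigger
#> <trigger_model> cow cow-03: trigger 9 (calibration max 8 + margin 1, 91 h)
run$alarms
#> # A tibble: 1 × 5
#>   cow_id    time f_parturition trigger gated
#>   <chr>    <dbl>         <int>   <int> <lgl>
#> 1 cow-03 423915.            10       9 FALSE

lead_time(run$alarms, run$calving_time_s)
#> [1] 2.245885
```

Reading the output: the calibrated accelerometer band (0.54–0.97 g)
captures standing-typical Y-axis values, and a 15-minute window count
above 118 (of 243) classifies the posture as standing. Over 91 valid
hours of pre-calving baseline this cow's five-hour transition count
never exceeded 8, so her personal trigger is 9. The count crosses the
trigger at t = 423,915 s — 2.25 hours before the true calving instant —
and the 24-hour refractory period keeps the escalation from raising
further alarms. `plot_parturition(run$series, run$trigger,
run$calving_time_s)` draws the corresponding week-long trace.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/cowcollar.R simulate  --duration 30 --seed 9 --out-dir run1
Rscript inst/cli/cowcollar.R calibrate --in run1/logs --annotations run1/annotations.csv --out-dir run1
Rscript inst/cli/cowcollar.R detect    --in run1/logs --params run1/posture-params.yaml --out-dir run1
```

Every subcommand writes a provenance record (package version + merged
configuration) beside its outputs.

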