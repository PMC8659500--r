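## End-to-end pipeline runs: calibrate once on annotated synthetic data,
## then push simulated streams through posture classification and the
## bout statistics. These drive the package's self-evaluation.

#' Calibrate posture thresholds on a synthetic annotated day
#'
#' Simulates a calving-free scenario with the given sensor model, has
#' the simulated observer annotate it, applies the pre-transition
#' exclusion, and runs [calibrate_thresholds()] on the result. This is
#' the synthetic analogue of calibrating on the labelled field data.
#'
#' @param seed Integer seed.
#' @param hours Length of the calibration recording.
#' @param sensor [sensor_model()] the thresholds must work under.
#' @param ... Further arguments passed to [sim_scenario()].
#' @return A [posture_params()] with calibration metrics attached.
#' @export
synthetic_calibration <- function(seed = 1L, hours = 24,
                                  sensor = sensor_model(), ...) {
  sc <- sim_scenario(duration = hours, sensor = sensor,
                     seed = .derive_seed(seed, 77), ...)
  schedule <- simulate_bout_schedule(sc)
  stream <- emit_accelerometer(schedule, sc, channels = "ay")
  events <- emit_annotations(schedule, sc, label_set = "posture")
  labelled <- trim_pre_transition(synchronize(stream, events))
  calibrate_thresholds(labelled)
}

#' Valid observation span of a classified series, in days
#'
#' Counts sample steps on which a posture transition could have been
#' detected (both endpoints valid and contiguous), the proper
#' denominator for a detected bouts-per-day rate.
#'
#' @param series A [posture_series()] result.
#' @return Days of observed, transition-capable signal.
#' @export
observed_days <- function(series) {
  fs <- series$f_standing
  n <- length(fs)
  if (n < 2L) return(0)
  i <- 2:n
  ok <- !is.na(fs[i]) & !is.na(fs[i - 1L]) &
    series$block[i] == series$block[i - 1L] + 1L
  params <- attr(series, "params")
  sum(ok) / params$resample_rate / 86400
}

#' Recover the configured lying-bout rate through the full pipeline
#'
#' For each seed, simulates a constant-rate scenario, renders the
#' 17.6 Hz accelerometer stream with the default (moderately noisy)
#' sensor model, classifies posture with thresholds calibrated once on
#' separate annotated synthetic data, counts detected lie-down events
#' and divides by the observed span. The across-seed mean estimates the
#' configured rate; Monte-Carlo standard error quantifies the
#' uncertainty of that mean.
#'
#' @param bout_rate Configured lying-bout rate, LB/day.
#' @param days Simulated days per seed.
#' @param n_seeds Number of independent seeds.
#' @param seed Master seed.
#' @param params Optional pre-calibrated [posture_params()]; calibrated
#'   via [synthetic_calibration()] when `NULL`.
#' @return List: `mean`, `se`, per-seed `rates`, `params`.
#' @export
evaluate_bout_recovery <- function(bout_rate, days = 1, n_seeds = 50,
                                   seed = 1L, params = NULL) {
  if (is.null(params)) params <- synthetic_calibration(seed)
  rates <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    sc <- sim_scenario(duration = days * 24, baseline_bout_rate = bout_rate,
                       seed = .derive_seed(seed, 1000 + i))
    schedule <- simulate_bout_schedule(sc)
    stream <- emit_accelerometer(schedule, sc, channels = "ay")
    series <- posture_series(stream, params)
    rates[i] <- count_lying_bouts(series) / observed_days(series)
    rm(stream, series)
  }
  list(mean = mean(rates), se = sd(rates) / sqrt(n_seeds), rates = rates,
       params = params)
}

#' Run the complete detection pipeline on one scenario
#'
#' Simulates the scenario, classifies posture, computes the transition
#' and rolling-bout statistics, fits the per-animal trigger on the
#' pre-calving calibration window and detects alarms.
#'
#' @param scenario A [sim_scenario()] (typically with a calving time).
#' @param params Optional [posture_params()]; calibrated synthetically
#'   from the scenario seed when `NULL`.
#' @param calibration_end End of the trigger-calibration window in
#'   seconds; defaults to 24 h before calving (or the full stream when
#'   the scenario has no calving).
#' @param margin Trigger margin (see [fit_trigger()]).
#' @param gate Optional [gestation_gate()].
#' @return List: `series` (with all statistics), `trigger`, `alarms`,
#'   `schedule`, `calving_time_s`, `params`.
#' @export
simulate_and_detect <- function(scenario, params = NULL,
                                calibration_end = NULL, margin = 1,
                                gate = NULL) {
  if (is.null(params)) params <- synthetic_calibration(scenario$seed)
  schedule <- simulate_bout_schedule(scenario)
  stream <- emit_accelerometer(schedule, scenario, channels = "ay")
  series <- rolling_bout_count(bout_transitions(posture_series(stream, params)))
  rm(stream)
  calving_s <- attr(schedule, "calving_time_s")
  if (is.null(calibration_end)) {
    calibration_end <- if (is.na(calving_s)) max(series$time) else
      calving_s - 24 * 3600
  }
  trigger <- fit_trigger(series, calibration_end = calibration_end,
                         margin = margin, gate = gate,
                         cow_id = scenario$cow_id)
  alarms <- detect_parturition(series, trigger)
  list(series = series, trigger = trigger, alarms = alarms,
       schedule = schedule, calving_time_s = calving_s, params = params)
}

#' Mean detection lead time over seeded calving scenarios
#'
#' Each scenario carries the default pre-calving escalation (linear ramp
#' from 8 h to 2 h before calving, flat peak thereafter). The trigger is
#' fitted per animal on the data up to 24 h before calving and the lead
#' time is measured from the first alarm to the true calving instant.
#'
#' @param n_scenarios Number of seeded scenarios.
#' @param seed Master seed.
#' @param duration Scenario length, hours.
#' @param calving_time Calving time, hours from stream start.
#' @param params Optional shared [posture_params()].
#' @return List: `mean_lead` (hours, over detected calvings), per-seed
#'   `leads` (`NA` where no alarm), `n_detected`, `triggers`.
#' @export
evaluate_lead_time <- function(n_scenarios = 20, seed = 1L, duration = 121,
                               calving_time = 120, params = NULL) {
  if (is.null(params)) params <- synthetic_calibration(seed)
  leads <- numeric(n_scenarios)
  triggers <- integer(n_scenarios)
  for (i in seq_len(n_scenarios)) {
    sc <- sim_scenario(duration = duration, calving_time = calving_time,
                       seed = .derive_seed(seed, 5000 + i))
    run <- simulate_and_detect(sc, params = params)
    leads[i] <- lead_time(run$alarms, run$calving_time_s)
    triggers[i] <- run$trigger$trigger_value
    rm(run)
  }
  list(mean_lead = mean(leads, na.rm = TRUE), leads = leads,
       n_detected = sum(!is.na(leads)), triggers = triggers)
}
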