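## Simulation scenarios: the statistical conditions a synthetic cow lives
## under. Durations are in hours unless a field name says otherwise.

#' Posture-conditional sensor model for the simulator
#'
#' Describes how accelerometer and gyroscope channels are drawn given the
#' animal's posture. The Y axis carries the posture information: standing
#' readings have a higher mean than lying ones, with overlapping spread at
#' the raw 17.6 Hz rate (moderate, not perfect, separation). The Z axis is
#' more dispersed while standing. These defaults are synthetic choices in
#' units of g, not fitted to any herd. GNSS and temperature channels are
#' constant placeholders.
#'
#' @param ay_mean,ay_sd Named numeric (standing, lying): Y-axis mean and
#'   raw-sample standard deviation in g.
#' @param az_mean,az_sd Same for the Z axis.
#' @param ax_sd,gyro_sd X-axis acceleration (g) and angular-rate
#'   (degrees/s) noise.
#' @param noise Global noise multiplier; 0 gives the noiseless limit in
#'   which every channel equals its posture-conditional mean.
#' @param placeholders Named list of constant values for the
#'   temperature/GNSS channels.
#' @return A list of class `sensor_model`.
#' @export
sensor_model <- function(ay_mean = c(standing = 0.60, lying = 0.10),
                         ay_sd = c(standing = 0.25, lying = 0.25),
                         az_mean = c(standing = 0.70, lying = 0.92),
                         az_sd = c(standing = 0.30, lying = 0.12),
                         ax_sd = 0.20, gyro_sd = 5, noise = 1,
                         placeholders = list(temp_imu = 30, temp_skin = 38.5,
                                             lon = -5.66, lat = 40.97,
                                             alt = 800, speed = 0)) {
  stopifnot(ay_mean[["standing"]] > ay_mean[["lying"]], noise >= 0)
  structure(list(ay_mean = ay_mean, ay_sd = ay_sd, az_mean = az_mean,
                 az_sd = az_sd, ax_sd = ax_sd, gyro_sd = gyro_sd,
                 noise = noise, placeholders = placeholders),
            class = "sensor_model")
}

#' Define a synthetic cow-behaviour scenario
#'
#' A scenario fixes everything the simulator needs: the lying-bout rate
#' dynamics (baseline, day-of-calving mean, pre-calving escalation window
#' and post-calving relaxation), the posture process geometry, the sensor
#' model, and the observer's annotation lag. Identical scenario + seed
#' yields identical output.
#'
#' Rates are lying bouts per day. The baseline default (9.3) and
#' day-of-calving default (13.0) are the literature rates for cows four
#' days before and on the day of calving. During the escalation window
#' (default 8 h to 2 h before calving) the instantaneous rate ramps
#' linearly from baseline to a peak and stays at the peak until calving;
#' the peak is solved so that the mean rate over the 24 h ending at
#' calving equals `calving_day_bout_rate` (about 27 LB/day with the
#' defaults). After calving the rate drops to `post_calving_dip` times
#' baseline and relaxes back with half-life `post_calving_half_life`.
#'
#' Dwell times in each posture are a minimum dwell plus an exponential
#' tail whose hazard follows the instantaneous rate, so the realised
#' lying-bout onset rate matches the configured rate in expectation.
#'
#' @param duration Stream length in hours.
#' @param baseline_bout_rate Baseline lying-bout rate (LB/day).
#' @param calving_day_bout_rate Mean rate over the 24 h ending at calving.
#' @param escalation_start,escalation_end Escalation window bounds, hours
#'   before calving (`start > end >= 0`).
#' @param calving_time Calving time in hours from stream start, or `NA`
#'   for a non-calving scenario.
#' @param standing_fraction Long-run proportion of time spent standing.
#' @param min_bout_min Minimum dwell in either posture, minutes.
#' @param post_calving_dip Post-calving rate as a fraction of baseline.
#' @param post_calving_half_life Half-life of the post-calving
#'   relaxation, hours.
#' @param sensor A [sensor_model()].
#' @param observer_lag,observer_jitter Mean and SD of the observer's
#'   annotation delay, seconds (delay is truncated at zero).
#' @param burn_in Hours of pre-stream simulation discarded so the posture
#'   process starts near stationarity.
#' @param cow_id Animal identifier carried into streams and annotations.
#' @param seed Integer seed; every simulator draw derives from it.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(duration = 96,
                         baseline_bout_rate = 9.3,
                         calving_day_bout_rate = 13.0,
                         escalation_start = 8,
                         escalation_end = 2,
                         calving_time = NA_real_,
                         standing_fraction = 0.5,
                         min_bout_min = 10,
                         post_calving_dip = 0.6,
                         post_calving_half_life = 24,
                         sensor = sensor_model(),
                         observer_lag = 20,
                         observer_jitter = 10,
                         burn_in = 48,
                         cow_id = "sim-01",
                         seed = 1L) {
  stopifnot(
    duration >= 0,
    baseline_bout_rate >= 0,
    calving_day_bout_rate >= 0,
    escalation_start > escalation_end, escalation_end >= 0,
    escalation_start <= 24,
    standing_fraction > 0, standing_fraction < 1,
    min_bout_min >= 0,
    post_calving_dip >= 0,
    post_calving_half_life > 0,
    observer_lag >= 0, observer_jitter >= 0,
    inherits(sensor, "sensor_model")
  )
  sc <- structure(
    list(duration = duration,
         baseline_bout_rate = baseline_bout_rate,
         calving_day_bout_rate = calving_day_bout_rate,
         escalation_start = escalation_start,
         escalation_end = escalation_end,
         calving_time = calving_time,
         standing_fraction = standing_fraction,
         min_bout_min = min_bout_min,
         post_calving_dip = post_calving_dip,
         post_calving_half_life = post_calving_half_life,
         sensor = sensor,
         observer_lag = observer_lag,
         observer_jitter = observer_jitter,
         burn_in = burn_in,
         cow_id = cow_id,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
  pk <- escalation_peak_rate(sc)
  if (!is.na(sc$calving_time) && pk < baseline_bout_rate) {
    stop("calving_day_bout_rate too low: implied escalation peak (",
         signif(pk, 4), " LB/day) is below baseline", call. = FALSE)
  }
  ## the minimum dwell must leave room for the exponential tail at peak rate
  r_max <- max(baseline_bout_rate,
               if (!is.na(sc$calving_time)) pk else 0) / 86400
  if (r_max > 0) {
    shortest <- min(standing_fraction, 1 - standing_fraction) / r_max
    if (shortest <= min_bout_min * 60) {
      stop("min_bout_min too large for the peak bout rate", call. = FALSE)
    }
  }
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %s: %.0f h, %.1f LB/day baseline%s, seed %d\n",
    x$cow_id, x$duration, x$baseline_bout_rate,
    if (is.na(x$calving_time)) "" else
      sprintf(", calving at %.0f h (peak %.1f LB/day)", x$calving_time,
              escalation_peak_rate(x)),
    x$seed
  ))
  invisible(x)
}

## Peak escalation rate P solved from the day-of-calving mean constraint:
## over the 24 h ending at calving the rate is baseline B outside the
## escalation window [a, b] h pre-calving, ramps linearly B -> P inside
## [a, b], and holds P over the final b hours, so
##   (24 - a) B + (a - b)(B + P)/2 + b P = 24 C.
escalation_peak_rate <- function(scenario) {
  a <- scenario$escalation_start
  b <- scenario$escalation_end
  B <- scenario$baseline_bout_rate
  C <- scenario$calving_day_bout_rate
  (24 * C - B * (24 - a + (a - b) / 2)) / ((a + b) / 2)
}

#' Instantaneous lying-bout rate of a scenario
#'
#' The rate profile the simulator draws from: baseline far from calving,
#' a linear ramp to the escalation peak inside the pre-calving window, a
#' flat peak until calving, and a dip-and-relax after it.
#'
#' @param scenario A [sim_scenario()].
#' @param t_hours Numeric vector of times in hours from stream start.
#' @return Lying-bout rate in LB/day at each time.
#' @export
bout_rate_at <- function(scenario, t_hours) {
  B <- scenario$baseline_bout_rate
  ct <- scenario$calving_time
  if (is.na(ct)) return(rep(B, length(t_hours)))
  P <- escalation_peak_rate(scenario)
  a <- scenario$escalation_start
  b <- scenario$escalation_end
  rel <- t_hours - ct # hours after calving (negative before)
  r <- rep(B, length(t_hours))
  ramp <- rel >= -a & rel < -b
  r[ramp] <- B + (P - B) * (rel[ramp] + a) / (a - b)
  r[rel >= -b & rel <= 0] <- P
  post <- rel > 0
  r[post] <- B * (1 - (1 - scenario$post_calving_dip) *
                    2^(-rel[post] / scenario$post_calving_half_life))
  r
}

## Seed streams: each simulator stage perturbs the scenario seed by a
## fixed offset so stages are independently reproducible.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
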