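## Synthetic cow behaviour: an alternating two-state (standing/lying)
## renewal process with time-varying lying-bout rate, rendered into
## 17.6 Hz collar records and observer annotation events.

#' Simulate a standing/lying bout schedule
#'
#' Draws the alternating posture process defined by a scenario. Dwell
#' times in each posture are `min_bout_min` plus an exponential tail
#' whose hazard is modulated by the instantaneous bout rate (sampled by
#' thinning), so the expected dwell in posture `s` at rate `r` is
#' `frac_s / r` and the realised lying-bout onset rate matches the
#' configured rate in expectation. The process is started `burn_in`
#' hours before the stream and the pre-stream portion discarded, giving
#' a near-stationary start.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble of class `bout_schedule` with columns `start`, `end`
#'   (seconds from stream start) and `posture` (`"standing"`/`"lying"`),
#'   contiguous and alternating; attributes `calving_time_s`,
#'   `duration_s` and `cow_id`.
#' @export
simulate_bout_schedule <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dur_s <- scenario$duration * 3600
  min_dwell <- scenario$min_bout_min * 60
  frac <- c(standing = scenario$standing_fraction,
            lying = 1 - scenario$standing_fraction)
  peak <- if (is.na(scenario$calving_time)) scenario$baseline_bout_rate else
    max(scenario$baseline_bout_rate, escalation_peak_rate(scenario))
  r_max_s <- peak / 86400

  withr::with_seed(.derive_seed(scenario$seed, 0), {
    state <- if (runif(1) < frac[["standing"]]) "standing" else "lying"
    if (r_max_s <= 0) {
      sched <- tibble::tibble(start = 0, end = dur_s, posture = state)
    } else {
      ## hazard of ending the exponential part of a dwell in posture s at
      ## absolute time t (seconds): 1 / (frac_s / r(t) - min_dwell)
      hazard <- function(s, t_s) {
        r <- bout_rate_at(scenario, t_s / 3600) / 86400
        mu <- frac[[s]] / r - min_dwell
        ifelse(r <= 0, 0, 1 / mu)
      }
      lam_max <- c(
        standing = 1 / (frac[["standing"]] / r_max_s - min_dwell),
        lying    = 1 / (frac[["lying"]] / r_max_s - min_dwell)
      )
      t <- -scenario$burn_in * 3600
      starts <- numeric(0); postures <- character(0)
      while (t < dur_s) {
        starts <- c(starts, t); postures <- c(postures, state)
        ## thinning for the inhomogeneous exponential tail
        w <- 0
        repeat {
          w <- w + rexp(1, lam_max[[state]])
          t_cand <- t + min_dwell + w
          if (t_cand > dur_s) break
          if (runif(1) < hazard(state, t_cand) / lam_max[[state]]) break
        }
        t <- t + min_dwell + w
        state <- if (state == "standing") "lying" else "standing"
      }
      ends <- c(starts[-1], dur_s)
      keep <- ends > 0
      starts <- pmax(starts[keep], 0)
      sched <- tibble::tibble(start = starts,
                              end = pmin(ends[keep], dur_s),
                              posture = postures[keep])
    }
  })
  structure(sched,
            class = c("bout_schedule", class(sched)),
            calving_time_s = if (is.na(scenario$calving_time)) NA_real_ else
              scenario$calving_time * 3600,
            duration_s = dur_s,
            cow_id = scenario$cow_id)
}

#' Count true lying bouts in a schedule
#'
#' A lying bout is a transition into the lying posture strictly inside
#' the stream (the initial interval, which has no onset, is not a bout).
#'
#' @param schedule A [simulate_bout_schedule()] result.
#' @return Integer count of lying-bout onsets.
#' @export
true_bout_count <- function(schedule) {
  sum(schedule$posture == "lying" & schedule$start > 0)
}

#' Render a bout schedule into a 17.6 Hz collar record stream
#'
#' Samples every record channel at the IMU rate. Y-axis acceleration is
#' drawn from the posture-conditional distribution of the scenario's
#' sensor model (standing mean above lying mean), the Z axis with larger
#' spread while standing; GNSS and temperature channels are constant
#' placeholders. With `sensor$noise = 0` every channel equals its
#' posture-conditional mean exactly.
#'
#' @param schedule A [simulate_bout_schedule()] result.
#' @param scenario The [sim_scenario()] that produced it.
#' @param rate Sampling rate in Hz.
#' @param channels `"full"` draws every inertial channel from the sensor
#'   model; `"ay"` draws only the Y axis (identically to `"full"`) and
#'   zero-fills the channels the posture pipeline never reads — a
#'   performance mode for long Monte-Carlo runs.
#' @return A [collar_stream()].
#' @export
emit_accelerometer <- function(schedule, scenario, rate = 17.6,
                               channels = c("full", "ay")) {
  stopifnot(inherits(schedule, "bout_schedule"),
            inherits(scenario, "sim_scenario"))
  channels <- match.arg(channels)
  sm <- scenario$sensor
  dur_s <- attr(schedule, "duration_s")
  n <- floor(dur_s * rate)
  if (n == 0L) {
    return(collar_stream(decode_records(raw(0)), collar_id = scenario$cow_id,
                         nominal_rate = rate))
  }
  t_ms <- round((seq_len(n) - 1) * 1000 / rate)
  idx <- findInterval(t_ms / 1000, schedule$start)
  ## 1 = standing, 2 = lying, for indexing the posture-conditional params
  ii <- 2L - (schedule$posture == "standing")[idx]
  pick <- function(v) unname(v[c("standing", "lying")])[ii]
  ns <- sm$noise
  ph <- sm$placeholders
  withr::with_seed(.derive_seed(scenario$seed, 1), {
    ay <- pick(sm$ay_mean) + ns * pick(sm$ay_sd) * rnorm(n)
    if (channels == "full") {
      recs <- tibble::tibble(
        timestamp = t_ms,
        temp_imu = rep(ph$temp_imu, n),
        temp_skin = rep(ph$temp_skin, n),
        lon = rep(ph$lon, n),
        lat = rep(ph$lat, n),
        alt = rep(ph$alt, n),
        speed = rep(ph$speed, n),
        ax = ns * sm$ax_sd * rnorm(n),
        ay = ay,
        az = pick(sm$az_mean) + ns * pick(sm$az_sd) * rnorm(n),
        gx = ns * sm$gyro_sd * rnorm(n),
        gy = ns * sm$gyro_sd * rnorm(n),
        gz = ns * sm$gyro_sd * rnorm(n)
      )
    } else {
      zeros <- numeric(n) # shared (copy-on-write) filler column
      recs <- tibble::tibble(
        timestamp = t_ms,
        temp_imu = zeros, temp_skin = zeros, lon = zeros, lat = zeros,
        alt = zeros, speed = zeros, ax = zeros,
        ay = ay,
        az = zeros, gx = zeros, gy = zeros, gz = zeros
      )
    }
  })
  collar_stream(recs, collar_id = scenario$cow_id, nominal_rate = rate)
}

#' Emit observer annotation events for a schedule
#'
#' Produces the event stream a human observer would have typed into the
#' annotation software. For the posture label set, one `B1` (standing) or
#' `B2` (lying) event is emitted at each posture onset, delayed by the
#' observer's reaction lag (truncated-normal, never negative). For the
#' general label set, each posture interval is subdivided into behaviour
#' spells (exponential, 20 min mean): standing cows graze/walk or stand
#' neutral (`A1`, `A4`, `A3`), lying cows ruminate or lie neutral
#' (`A2`, `A3`) — so `A3` (Neutral) occurs under both postures and is
#' uninformative about posture.
#'
#' @param schedule A [simulate_bout_schedule()] result.
#' @param scenario The [sim_scenario()] that produced it.
#' @param label_set `"posture"` (B1/B2) or `"general"` (A1-A4).
#' @return Tibble of events: `timestamp` (ms), `cow_id`, `label_set`,
#'   `label`, `note`.
#' @export
emit_annotations <- function(schedule, scenario,
                             label_set = c("posture", "general")) {
  stopifnot(inherits(schedule, "bout_schedule"),
            inherits(scenario, "sim_scenario"))
  label_set <- match.arg(label_set)
  lag_of <- function(k) {
    if (scenario$observer_lag == 0 && scenario$observer_jitter == 0) {
      rep(0, k)
    } else {
      pmax(0, rnorm(k, scenario$observer_lag, scenario$observer_jitter))
    }
  }
  withr::with_seed(.derive_seed(scenario$seed, 2 + (label_set == "general")), {
    if (label_set == "posture") {
      lab <- ifelse(schedule$posture == "standing", "B1", "B2")
      t_s <- schedule$start + lag_of(nrow(schedule))
    } else {
      t_s <- numeric(0); lab <- character(0)
      for (i in seq_len(nrow(schedule))) {
        len <- schedule$end[i] - schedule$start[i]
        cuts <- 0
        while (sum(cuts) < len) cuts <- c(cuts, rexp(1, 1 / 1200))
        offs <- cumsum(cuts[-length(cuts)])
        offs <- offs[offs < len]
        pool <- if (schedule$posture[i] == "standing") {
          sample(c("A1", "A4", "A3"), length(offs), replace = TRUE,
                 prob = c(0.5, 0.25, 0.25))
        } else {
          sample(c("A2", "A3"), length(offs), replace = TRUE,
                 prob = c(0.6, 0.4))
        }
        t_s <- c(t_s, schedule$start[i] + offs)
        lab <- c(lab, pool)
      }
      t_s <- t_s + lag_of(length(t_s))
    }
  })
  ord <- order(t_s)
  tibble::tibble(
    timestamp = round(t_s[ord] * 1000),
    cow_id = attr(schedule, "cow_id"),
    label_set = label_set,
    label = lab[ord],
    note = NA_character_
  )
}
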