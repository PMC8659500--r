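## The parturition proxy: posture transitions and their five-hour
## rolling count, an individually calibrated trigger, and gated alarms.

#' Posture transition signal
#'
#' `f_lb(t) = |f_standing(t) - f_standing(t-1)|`: each lie-down or
#' stand-up event becomes a 1. The first sample, warmup samples and
#' samples whose predecessor sits across a coverage gap carry no value.
#'
#' @param series A [posture_series()] result (or any tibble with
#'   `block` and `f_standing` columns).
#' @return The input with an `f_lb` column.
#' @export
bout_transitions <- function(series) {
  n <- nrow(series)
  fs <- series$f_standing
  flb <- rep(NA_integer_, n)
  if (n >= 2L) {
    i <- 2:n
    ok <- !is.na(fs[i]) & !is.na(fs[i - 1L]) &
      series$block[i] == series$block[i - 1L] + 1L
    flb[i][ok] <- abs(fs[i][ok] - fs[i - 1L][ok])
  }
  series$f_lb <- flb
  series
}

#' Rolling lying-bout transition count
#'
#' `f_parturition(t)`: the number of posture transitions in the trailing
#' `bout_window` seconds (default five hours). A transition exactly one
#' window plus one step old has expired. The count is undefined until a
#' full window of valid transition samples exists after the stream start
#' or after any coverage gap.
#'
#' @param series A [bout_transitions()] result.
#' @param bout_window Trailing window in seconds.
#' @return The input with `f_parturition` (integer, `NA` while
#'   undefined); the window length is attached as attribute
#'   `bout_window`.
#' @export
rolling_bout_count <- function(series, bout_window = 5 * 3600) {
  params <- attr(series, "params")
  rate <- if (!is.null(params)) params$resample_rate else
    attr(series, "resample_rate")
  stopifnot(!is.null(rate))
  w <- window_samples(bout_window, rate)
  flb <- series$f_lb
  x0 <- ifelse(is.na(flb), 0, flb)
  rs <- rolling_sum(x0, w)
  n_na <- rolling_sum(as.numeric(is.na(flb)), w)
  contig <- window_contiguous(series$block, w)
  fp <- ifelse(!contig | is.na(n_na) | n_na > 0, NA_real_, rs)
  series$f_parturition <- as.integer(fp)
  attr(series, "bout_window") <- bout_window
  series
}

#' Count detected lying bouts in a classified series
#'
#' A detected lying bout is a standing-to-lying transition
#' (`f_standing` falling edge) between consecutive valid samples.
#'
#' @param series A [posture_series()] (after [classify_standing()]).
#' @return Integer count of lie-down events.
#' @export
count_lying_bouts <- function(series) {
  fs <- series$f_standing
  n <- length(fs)
  if (n < 2L) return(0L)
  i <- 2:n
  ok <- !is.na(fs[i]) & !is.na(fs[i - 1L]) &
    series$block[i] == series$block[i - 1L] + 1L
  sum(ok & fs[i - 1L] == 1L & fs[i] == 0L)
}

#' Gestation gate around an expected calving date
#'
#' Alarms outside the gate are biologically inviable and suppressed. The
#' default interval is one month either side of the expected calving
#' date implied by the observed mount.
#'
#' @param expected_calving Expected calving time, seconds on the stream
#'   clock.
#' @param interval_days Allowed interval either side, days.
#' @return A list of class `gestation_gate` with `start` and `end`
#'   (seconds).
#' @export
gestation_gate <- function(expected_calving, interval_days = 30) {
  stopifnot(interval_days > 0)
  structure(list(start = expected_calving - interval_days * 86400,
                 end = expected_calving + interval_days * 86400),
            class = "gestation_gate")
}

#' Fit a per-animal parturition trigger
#'
#' The trigger must be calculated dynamically for each cow because
#' baseline restlessness differs between individuals. The rule is the
#' running maximum of `f_parturition` over a calving-free calibration
#' window plus a safety margin: the smallest value that none of the
#' animal's ordinary behaviour reaches. It needs O(1) memory on the
#' collar.
#'
#' @param series A [rolling_bout_count()] result.
#' @param calibration_end End of the calibration window, seconds on the
#'   stream clock; `NULL` uses the whole series. The window must be free
#'   of known calvings (caller's responsibility) and span at least
#'   `min_hours` of valid statistic.
#' @param margin Safety margin added to the calibration maximum.
#' @param min_hours Minimum valid calibration span, hours.
#' @param gate Optional [gestation_gate()].
#' @param cow_id Animal identifier.
#' @return A list of class `trigger_model`.
#' @export
fit_trigger <- function(series, calibration_end = NULL, margin = 1,
                        min_hours = 24, gate = NULL, cow_id = NA_character_) {
  ok <- !is.na(series$f_parturition)
  if (!is.null(calibration_end)) ok <- ok & series$time <= calibration_end
  if (!any(ok)) {
    stop("no valid f_parturition samples in the calibration window",
         call. = FALSE)
  }
  span_h <- diff(range(series$time[ok])) / 3600
  if (span_h < min_hours) {
    stop(sprintf(
      "calibration window spans %.1f h of valid data; at least %g h required",
      span_h, min_hours
    ), call. = FALSE)
  }
  cal_max <- max(series$f_parturition[ok])
  margin <- as.integer(round(margin))
  structure(list(cow_id = cow_id,
                 trigger_value = cal_max + margin,
                 calibration_max = cal_max,
                 calibration_end = calibration_end,
                 calibration_hours = span_h,
                 margin = margin,
                 gate = gate),
            class = "trigger_model")
}

#' @export
print.trigger_model <- function(x, ...) {
  cat(sprintf(
    "<trigger_model> cow %s: trigger %d (calibration max %d + margin %d, %.0f h)%s\n",
    x$cow_id, x$trigger_value, x$calibration_max, x$margin,
    x$calibration_hours,
    if (is.null(x$gate)) "" else sprintf(", gate [%.0f, %.0f] h",
                                         x$gate$start / 3600,
                                         x$gate$end / 3600)
  ))
  invisible(x)
}

#' Detect parturition alarms
#'
#' Raises an alarm at the first time `f_parturition` strictly exceeds
#' the fitted trigger inside the gestation gate (when the model carries
#' one). After an alarm the detector is refractory for `refractory`
#' seconds so a single pre-calving escalation does not produce an alarm
#' storm. Exceedance episodes outside the gate are suppressed and
#' returned in the `suppressed` attribute.
#'
#' @param series A [rolling_bout_count()] result.
#' @param model A [fit_trigger()] result.
#' @param refractory Dead time after an alarm, seconds.
#' @return Tibble of alarms (`cow_id`, `time`, `f_parturition`,
#'   `trigger`, `gated`); suppressed episodes as attribute `suppressed`.
#' @export
detect_parturition <- function(series, model, refractory = 24 * 3600) {
  stopifnot(inherits(model, "trigger_model"))
  exceed <- !is.na(series$f_parturition) &
    series$f_parturition > model$trigger_value
  in_gate <- if (is.null(model$gate)) rep(TRUE, nrow(series)) else
    series$time >= model$gate$start & series$time <= model$gate$end
  alarm_idx <- integer(0)
  next_allowed <- -Inf
  for (i in which(exceed & in_gate)) {
    if (series$time[i] >= next_allowed) {
      alarm_idx <- c(alarm_idx, i)
      next_allowed <- series$time[i] + refractory
    }
  }
  alarms <- tibble::tibble(
    cow_id = model$cow_id,
    time = series$time[alarm_idx],
    f_parturition = series$f_parturition[alarm_idx],
    trigger = model$trigger_value,
    gated = !is.null(model$gate)
  )
  sup_idx <- which(exceed & !in_gate)
  suppressed <- if (length(sup_idx) > 0L) {
    runs <- cumsum(c(1L, diff(sup_idx) > 1L))
    tibble::tibble(
      from = tapply(series$time[sup_idx], runs, min),
      to = tapply(series$time[sup_idx], runs, max),
      max_value = as.integer(tapply(series$f_parturition[sup_idx], runs, max))
    )
  } else {
    tibble::tibble(from = numeric(0), to = numeric(0),
                   max_value = integer(0))
  }
  if (nrow(suppressed) > 0L) {
    message(nrow(suppressed),
            " exceedance episode(s) outside the gestation gate suppressed")
  }
  attr(alarms, "suppressed") <- suppressed
  alarms
}

#' Lead time of the first alarm before calving
#'
#' @param alarms A [detect_parturition()] result.
#' @param truth True calving time, seconds on the stream clock.
#' @return Hours between the first alarm and calving (positive when the
#'   alarm precedes calving, negative when late); `NA_real_` when there
#'   is no alarm.
#' @export
lead_time <- function(alarms, truth) {
  if (nrow(alarms) == 0L) return(NA_real_)
  (truth - alarms$time[1]) / 3600
}
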