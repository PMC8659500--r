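# series with hand-set f_standing / f_lb on a gapless unit grid
stat_series <- function(f_standing = NULL, f_lb = NULL, rate = 1) {
  n <- max(length(f_standing), length(f_lb))
  out <- toy_series(rep(0, n), rate = rate)
  if (!is.null(f_standing)) out$f_standing <- as.integer(f_standing)
  if (!is.null(f_lb)) out$f_lb <- as.integer(f_lb)
  out
}

test_that("the transition signal is the absolute first difference", {
  const <- bout_transitions(stat_series(rep(1L, 50)))
  expect_true(is.na(const$f_lb[1]))
  expect_true(all(const$f_lb[-1] == 0L))
  alt <- bout_transitions(stat_series(c(0L, 1L, 0L, 1L)))
  expect_identical(alt$f_lb, c(NA_integer_, 1L, 1L, 1L))
  # a warmup NA in f_standing invalidates both adjacent differences
  gap <- stat_series(c(1L, 1L, NA, 0L, 0L))
  expect_identical(bout_transitions(gap)$f_lb,
                   c(NA_integer_, 0L, NA_integer_, NA_integer_, 0L))
})

test_that("the rolling bout count sums the trailing window, half-open", {
  flb <- rep(0L, 100)
  flb[c(20, 35, 50)] <- 1L
  s <- rolling_bout_count(stat_series(f_lb = flb), bout_window = 40)
  expect_identical(s$f_parturition[55], 3L)
  # at index 59 the transition at 20 is the oldest sample still inside
  # the half-open window; one step later it has expired
  expect_identical(s$f_parturition[59], 3L)
  expect_identical(s$f_parturition[60], 2L)
  # warmup: undefined until one full window of defined f_lb exists
  expect_true(all(is.na(s$f_parturition[1:39])))
  expect_false(anyNA(s$f_parturition[40:100]))
})

test_that("rolling bout count equals its brute-force oracle", {
  withr::with_seed(51, {
    for (rep in 1:15) {
      n <- sample(50:3000, 1)
      w <- sample(5:200, 1)
      flb <- c(NA_integer_, rbinom(n - 1, 1, 0.05))
      s <- rolling_bout_count(stat_series(f_lb = flb), bout_window = w)
      oracle <- brute_rolling_sum(flb, w) # NA while any NA is in-window
      expect_identical(as.numeric(s$f_parturition), as.numeric(oracle))
    }
  })
})

test_that("adding a transition never lowers the in-window count", {
  withr::with_seed(52, {
    for (rep in 1:10) {
      flb <- rbinom(400, 1, 0.05)
      base <- rolling_bout_count(stat_series(f_lb = flb), bout_window = 60)
      i <- sample(which(flb == 0 & seq_along(flb) > 60), 1)
      flb2 <- flb; flb2[i] <- 1L
      more <- rolling_bout_count(stat_series(f_lb = flb2), bout_window = 60)
      ok <- !is.na(base$f_parturition)
      expect_true(all(more$f_parturition[ok] >= base$f_parturition[ok]))
    }
  })
})

test_that("the trigger is the calibration maximum plus the margin", {
  flb <- rep(0L, 30 * 3600) # 30 h at 1 Hz
  s <- rolling_bout_count(stat_series(f_lb = flb), bout_window = 5 * 3600)
  s$f_parturition[!is.na(s$f_parturition)] <-
    rep_len(c(0L, 4L, 9L, 2L), sum(!is.na(s$f_parturition)))
  m <- fit_trigger(s, margin = 1, cow_id = "c03")
  expect_identical(m$trigger_value, 10L) # max 9 + margin 1
  expect_identical(m$calibration_max, 9L)
  # permutation invariance of the calibration values
  s2 <- s
  ok <- !is.na(s2$f_parturition)
  s2$f_parturition[ok] <- sample(s2$f_parturition[ok])
  expect_identical(fit_trigger(s2, margin = 1)$trigger_value, 10L)
  # constant zero statistic: the trigger is the bare margin
  s$f_parturition[ok] <- 0L
  expect_identical(fit_trigger(s, margin = 1)$trigger_value, 1L)
})

test_that("the trigger refuses under-long calibration windows", {
  flb <- rep(0L, 10 * 3600) # 10 h only
  s <- rolling_bout_count(stat_series(f_lb = flb), bout_window = 3600)
  expect_error(fit_trigger(s), "at least 24")
  expect_error(fit_trigger(s, calibration_end = -1), "no valid")
})

test_that("alarms fire on first exceedance, with refractory and gating", {
  n <- 60 * 3600 # 60 h at 1 Hz
  s <- rolling_bout_count(stat_series(f_lb = rep(0L, n)), bout_window = 3600)
  ok <- !is.na(s$f_parturition)
  s$f_parturition[ok] <- 2L
  base <- fit_trigger(s, calibration_end = 30 * 3600, margin = 1)
  expect_identical(nrow(detect_parturition(s, base)), 0L) # never exceeded
  # two exceedance episodes 20 h apart: refractory melds or splits them
  s$f_parturition[s$time > 35 * 3600 & s$time < 35.2 * 3600] <- 9L
  s$f_parturition[s$time > 55 * 3600 & s$time < 55.2 * 3600] <- 9L
  two <- detect_parturition(s, base, refractory = 10 * 3600)
  expect_identical(nrow(two), 2L)
  one <- detect_parturition(s, base, refractory = 24 * 3600)
  expect_identical(nrow(one), 1L)
  expect_equal(one$time[1], s$time[s$time > 35 * 3600][1])
  # the same exceedances outside the gestation gate are suppressed
  gated <- fit_trigger(s, calibration_end = 30 * 3600, margin = 1,
                       gate = gestation_gate(200 * 3600, interval_days = 1))
  expect_message(res <- detect_parturition(s, gated), "suppressed")
  expect_identical(nrow(res), 0L)
  expect_identical(nrow(attr(res, "suppressed")), 2L)
})

test_that("lead time is signed hours from first alarm to calving", {
  alarms <- tibble::tibble(cow_id = "x", time = 98 * 3600,
                           f_parturition = 11L, trigger = 10L, gated = FALSE)
  expect_equal(lead_time(alarms, 100 * 3600), 2.0)
  expect_equal(lead_time(alarms, 98 * 3600), 0.0)
  expect_lt(lead_time(alarms, 97 * 3600), 0)
  expect_true(is.na(lead_time(alarms[0, ], 100 * 3600)))
})
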