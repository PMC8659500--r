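test_that("schedules are deterministic in the seed and sensitive to it", {
  sc <- sim_scenario(duration = 24, seed = 5)
  s1 <- simulate_bout_schedule(sc)
  s2 <- simulate_bout_schedule(sc)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  s3 <- simulate_bout_schedule(sim_scenario(duration = 24, seed = 6))
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
})

test_that("schedules are contiguous, alternating and clipped to the stream", {
  sch <- simulate_bout_schedule(sim_scenario(duration = 48, seed = 3))
  expect_equal(sch$start[-1], sch$end[-nrow(sch)])
  expect_true(all(sch$posture[-1] != sch$posture[-nrow(sch)]))
  expect_equal(sch$start[1], 0)
  expect_equal(sch$end[nrow(sch)], 48 * 3600)
  expect_true(all(diff(range(sch$start)) >= 0))
})

test_that("a zero bout rate yields a single interval with no transitions", {
  sch <- simulate_bout_schedule(
    sim_scenario(duration = 24, baseline_bout_rate = 0, seed = 1)
  )
  expect_identical(nrow(sch), 1L)
  expect_identical(true_bout_count(sch), 0L)
})

test_that("realized bout counts match the renewal-process expectation", {
  # 9.3 LB/day over 4 days: expectation 37.2 onsets; brute-force
  # Monte-Carlo average must agree within its own uncertainty
  counts <- vapply(1:100, function(i) {
    sch <- simulate_bout_schedule(
      sim_scenario(duration = 96, baseline_bout_rate = 9.3, seed = 2000 + i)
    )
    as.numeric(true_bout_count(sch))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 37.2), 2.5 * se)
})

test_that("calving schedules escalate: final hours beat the baseline rate", {
  # pooled over seeds, the rate in the last 5 h pre-calving far exceeds
  # the baseline-period rate
  final5 <- 0; base <- 0; base_h <- 0
  for (i in 1:10) {
    sc <- sim_scenario(duration = 72, calving_time = 66, seed = 300 + i)
    sch <- simulate_bout_schedule(sc)
    onset <- sch$start[sch$posture == "lying" & sch$start > 0]
    c_s <- 66 * 3600
    final5 <- final5 + sum(onset > c_s - 5 * 3600 & onset <= c_s)
    base <- base + sum(onset <= 48 * 3600)
    base_h <- base_h + 48
  }
  expect_gt((final5 / (10 * 5)) , (base / base_h))
})

test_that("the escalation peak reproduces the day-of-calving mean rate", {
  sc <- sim_scenario(duration = 48, calving_time = 36, seed = 1)
  # mean of the rate profile over the 24 h ending at calving
  tt <- seq(12, 36, by = 1 / 60)
  expect_equal(mean(bout_rate_at(sc, tt)), 13.0, tolerance = 1e-3)
  # far from calving the profile sits at baseline
  expect_equal(bout_rate_at(sc, 5), 9.3)
  # post-calving dip below baseline
  expect_lt(bout_rate_at(sc, 37), 9.3)
})

test_that("accelerometer emission has the documented rate, units and separation", {
  sc <- sim_scenario(duration = 1, seed = 9)
  sch <- simulate_bout_schedule(sc)
  st <- emit_accelerometer(sch, sc)
  expect_identical(nrow(st$records), 63360L) # 17.6 Hz x 3600 s
  expect_identical(nrow(st$gaps), 0L)
  for (i in 1:5) {
    sci <- sim_scenario(duration = 6, seed = 400 + i)
    schi <- simulate_bout_schedule(sci)
    if (length(unique(schi$posture)) < 2) next
    sti <- emit_accelerometer(schi, sci)
    standing <- schi$posture[findInterval(sti$records$timestamp / 1000,
                                          schi$start)] == "standing"
    expect_gt(mean(sti$records$ay[standing]), mean(sti$records$ay[!standing]))
    expect_gt(IQR(sti$records$az[standing]), IQR(sti$records$az[!standing]))
  }
})

test_that("the noiseless sensor model emits exact posture-conditional means", {
  sc <- sim_scenario(duration = 2, seed = 10,
                     sensor = sensor_model(noise = 0))
  sch <- simulate_bout_schedule(sc)
  st <- emit_accelerometer(sch, sc)
  expect_true(all(st$records$ay %in% c(0.60, 0.10)))
})

test_that("posture annotations map schedule onsets one-to-one (plus initial state)", {
  sc <- sim_scenario(duration = 12, seed = 21, observer_lag = 0,
                     observer_jitter = 0)
  sch <- simulate_bout_schedule(sc)
  ev <- emit_annotations(sch, sc, label_set = "posture")
  expect_identical(nrow(ev), nrow(sch))
  expect_equal(ev$timestamp, round(sch$start * 1000))
  expect_identical(ev$label, ifelse(sch$posture == "standing", "B1", "B2"))
})

test_that("observer lag delays annotations without reordering them", {
  sc <- sim_scenario(duration = 12, seed = 22)
  sch <- simulate_bout_schedule(sc)
  ev <- emit_annotations(sch, sc, label_set = "posture")
  expect_true(all(ev$timestamp >= round(sch$start * 1000)))
  expect_false(is.unsorted(ev$timestamp))
})

test_that("neutral (A3) general-behaviour events occur in both postures", {
  sc <- sim_scenario(duration = 24, seed = 23, observer_lag = 0,
                     observer_jitter = 0)
  sch <- simulate_bout_schedule(sc)
  ev <- emit_annotations(sch, sc, label_set = "general")
  # +1 ms slack: event timestamps are rounded to the millisecond, so an
  # event at an interval onset can round to just before the boundary
  post <- sch$posture[findInterval(ev$timestamp / 1000 + 1e-3, sch$start)]
  neutral <- ev$label == "A3"
  expect_true(any(neutral & post == "standing"))
  expect_true(any(neutral & post == "lying"))
  expect_true(all(ev$label[post == "lying"] %in% c("A2", "A3")))
  expect_true(all(ev$label[post == "standing"] %in% c("A1", "A3", "A4")))
})
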