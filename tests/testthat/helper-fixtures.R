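# Fixture builders and independent brute-force oracles shared by the suite.

# Round a double through IEEE float32 so codec round-trips are exact.
f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
          n = length(x), size = 4L)
}

# Random records valid under the codec invariants (float fields
# float32-representable, integer-backed fields on their storage grid).
random_records <- function(n, start_ms = 0, period_ms = 57) {
  tibble::tibble(
    timestamp = start_ms + period_ms * (seq_len(n) - 1),
    temp_imu = f32(runif(n, -10, 45)),
    temp_skin = f32(runif(n, 30, 41)),
    lon = sample.int(2e9, n, replace = TRUE) * 1e-7 - 100,
    lat = sample.int(1.6e9, n, replace = TRUE) * 1e-7 - 80,
    alt = sample.int(2e6, n, replace = TRUE) * 1e-3,
    speed = sample.int(2e4, n, replace = TRUE) * 1e-3,
    ax = f32(runif(n, -2, 2)),
    ay = f32(runif(n, -2, 2)),
    az = f32(runif(n, -2, 2)),
    gx = f32(runif(n, -250, 250)),
    gy = f32(runif(n, -250, 250)),
    gz = f32(runif(n, -250, 250))
  )
}

# A stream with 1 Hz nominal sampling and hand-chosen ay values, for
# window arithmetic tests where the 17.6 Hz grid would only obscure.
plain_stream <- function(ay, t_s = seq_along(ay) - 1) {
  recs <- tibble::tibble(
    timestamp = t_s * 1000, temp_imu = 0, temp_skin = 0, lon = 0, lat = 0,
    alt = 0, speed = 0, ax = 0, ay = ay, az = 0, gx = 0, gy = 0, gz = 0
  )
  collar_stream(recs, collar_id = "test", nominal_rate = 1)
}

# A bare resampled-series tibble on a gapless unit grid (rate 1 Hz).
toy_series <- function(ay, rate = 1) {
  out <- tibble::tibble(time = seq_along(ay) / rate,
                        block = seq_along(ay) - 1L, ay = ay)
  attr(out, "resample_rate") <- rate
  out
}

# O(n * w) brute-force trailing-window sum, NA until the window fills.
brute_rolling_sum <- function(x, w) {
  sapply(seq_along(x), function(i) {
    if (i < w) NA_real_ else sum(x[(i - w + 1L):i])
  })
}

# Brute-force banded count straight from the definition.
brute_banded_count <- function(ay, thr_inf, thr_sup, w) {
  brute_rolling_sum(as.numeric(ay > thr_inf & ay < thr_sup), w)
}

# Run the batch chain on a gapless resampled series.
batch_chain <- function(ay, params, bout_window) {
  s <- classify_standing(banded_count(toy_series(ay, params$resample_rate),
                                      params), params)
  attr(s, "params") <- params
  rolling_bout_count(bout_transitions(s), bout_window = bout_window)
}

# Feed the same series one sample at a time.
stream_chain <- function(ay, params, bout_window) {
  det <- streaming_detector(params, bout_window = bout_window)
  out <- lapply(ay, function(a) detector_step(det, a))
  list(
    f_count = vapply(out, function(x) as.numeric(x$f_count), numeric(1)),
    f_standing = vapply(out, function(x) as.numeric(x$f_standing), numeric(1)),
    f_lb = vapply(out, function(x) as.numeric(x$f_lb), numeric(1)),
    f_parturition = vapply(out, function(x) as.numeric(x$f_parturition),
                           numeric(1)),
    det = det
  )
}
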