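## Streaming (sample-at-a-time) evaluation of the whole statistic chain,
## as it would run on the collar microcontroller: two ring buffers (one
## 15-minute count window, one 5-hour transition window) plus a handful
## of scalars. No history beyond the two windows is retained.

#' Create a streaming calving detector
#'
#' Consumes resampled Y-axis samples one at a time and maintains
#' `f_count`, `f_standing`, `f_lb` and `f_parturition` incrementally,
#' producing exactly the values the batch pipeline computes on the same
#' gapless series. State is bounded by one count window plus one bout
#' window of samples.
#'
#' @param params [posture_params()].
#' @param bout_window Transition-count window, seconds.
#' @return An environment of class `streaming_detector`.
#' @export
streaming_detector <- function(params, bout_window = 5 * 3600) {
  stopifnot(inherits(params, "posture_params"))
  det <- new.env(parent = emptyenv())
  det$params <- params
  det$bout_window <- bout_window
  det$w1 <- params$capacity
  det$w2 <- window_samples(bout_window, params$resample_rate)
  detector_reset(structure(det, class = "streaming_detector"))
}

#' Reset a streaming detector
#'
#' Clears both windows, as after a coverage gap: every statistic
#' re-enters warmup.
#'
#' @param det A [streaming_detector()].
#' @return The detector, invisibly usable in place.
#' @export
detector_reset <- function(det) {
  stopifnot(inherits(det, "streaming_detector"))
  det$ring1 <- integer(det$w1); det$pos1 <- 0L; det$n1 <- 0L; det$sum1 <- 0L
  det$ring2 <- rep(NA_integer_, det$w2); det$pos2 <- 0L; det$n2 <- 0L
  det$sum2 <- 0L; det$na2 <- 0L
  det$prev_standing <- NA_integer_
  det
}

#' Feed one resampled sample to a streaming detector
#'
#' @param det A [streaming_detector()].
#' @param ay One resampled Y-axis reading in g.
#' @return List with the current `f_count`, `f_standing`, `f_lb` and
#'   `f_parturition` (each `NA` while its window is warming up).
#' @export
detector_step <- function(det, ay) {
  p <- det$params
  inb <- as.integer(ay > p$thr_inf & ay < p$thr_sup)
  det$pos1 <- det$pos1 %% det$w1 + 1L
  if (det$n1 < det$w1) {
    det$n1 <- det$n1 + 1L
    det$sum1 <- det$sum1 + inb
  } else {
    det$sum1 <- det$sum1 + inb - det$ring1[det$pos1]
  }
  det$ring1[det$pos1] <- inb
  f_count <- if (det$n1 == det$w1) det$sum1 else NA_integer_
  f_standing <- if (is.na(f_count)) NA_integer_ else
    as.integer(f_count > p$thr_standing)
  f_lb <- if (is.na(f_standing) || is.na(det$prev_standing)) NA_integer_ else
    abs(f_standing - det$prev_standing)
  det$prev_standing <- f_standing

  det$pos2 <- det$pos2 %% det$w2 + 1L
  if (det$n2 < det$w2) {
    det$n2 <- det$n2 + 1L
  } else {
    old <- det$ring2[det$pos2]
    if (is.na(old)) det$na2 <- det$na2 - 1L else det$sum2 <- det$sum2 - old
  }
  if (is.na(f_lb)) det$na2 <- det$na2 + 1L else det$sum2 <- det$sum2 + f_lb
  det$ring2[det$pos2] <- f_lb
  f_parturition <- if (det$n2 == det$w2 && det$na2 == 0L) det$sum2 else
    NA_integer_

  list(f_count = f_count, f_standing = f_standing, f_lb = f_lb,
       f_parturition = f_parturition)
}

#' Size of a streaming detector's retained state
#'
#' @param det A [streaming_detector()].
#' @return Named integer vector: samples held in the count window, in
#'   the bout window, and their total.
#' @export
detector_state_size <- function(det) {
  c(count_window = length(det$ring1),
    bout_window = length(det$ring2),
    total = length(det$ring1) + length(det$ring2))
}
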