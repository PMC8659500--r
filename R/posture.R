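## Posture classification: resample the Y-axis accelerometer, count
## samples inside an amplitude band over a trailing 15-minute window,
## and threshold the count into a binary standing/lying signal.

#' Posture-classification parameters
#'
#' @param thr_inf,thr_sup Inferior/superior accelerometer band bounds in
#'   g; a resampled Y-axis reading counts when strictly inside the band.
#' @param thr_standing Count threshold: counts strictly above it are
#'   classified standing, at or below it lying.
#' @param count_window Trailing count window, seconds.
#' @param resample_rate Rate of the resampled Y-axis series, Hz.
#' @return A list of class `posture_params`.
#' @export
posture_params <- function(thr_inf, thr_sup, thr_standing,
                           count_window = 900, resample_rate = 0.27) {
  stopifnot(thr_inf < thr_sup, count_window > 0, resample_rate > 0)
  capacity <- window_samples(count_window, resample_rate)
  stopifnot(thr_standing >= 0, thr_standing <= capacity)
  structure(list(thr_inf = thr_inf, thr_sup = thr_sup,
                 thr_standing = thr_standing, count_window = count_window,
                 resample_rate = resample_rate, capacity = capacity),
            class = "posture_params")
}

#' @export
print.posture_params <- function(x, ...) {
  cat(sprintf(
    "<posture_params> band (%.4g, %.4g) g, thr_standing %d/%d, %g s window at %g Hz\n",
    x$thr_inf, x$thr_sup, x$thr_standing, x$capacity, x$count_window,
    x$resample_rate
  ))
  cal <- attr(x, "calibration")
  if (!is.null(cal)) {
    cat(sprintf("  calibration: separation %.1f counts, balanced accuracy %.3f\n",
                cal$separation, cal$balanced_accuracy))
  }
  invisible(x)
}

#' Number of samples a trailing window holds
#'
#' @param window Window length in seconds.
#' @param rate Sample rate in Hz.
#' @return `floor(window * rate)` with floating-point guard.
#' @export
window_samples <- function(window, rate) {
  as.integer(floor(window * rate + 1e-9))
}

#' Resample Y-axis acceleration by block means
#'
#' Averages the stream's `ay` channel over non-overlapping blocks of
#' `1/rate` seconds, timestamped at the block end. Block means (rather
#' than decimation) preserve band-occupancy semantics under raw-sample
#' noise. A block is emitted only when it holds a full complement of
#' samples, so blocks overlapping data gaps (and the trailing partial
#' block) yield no sample; the surviving block index is kept so that
#' downstream windows can recognise interrupted coverage.
#'
#' @param stream A [collar_stream()].
#' @param rate Target rate in Hz (default 0.27, down from 17.6).
#' @return Tibble with `time` (seconds, block end), `block` (index on
#'   the uninterrupted block grid) and `ay` (block mean, g); attribute
#'   `resample_rate`.
#' @export
resample_ay <- function(stream, rate = 0.27) {
  stopifnot(inherits(stream, "collar_stream"))
  ts <- stream$records$timestamp
  empty <- tibble::tibble(time = numeric(0), block = integer(0),
                          ay = numeric(0))
  attr(empty, "resample_rate") <- rate
  if (length(ts) == 0L) return(empty)
  d_ms <- 1000 / rate
  k <- floor((ts - ts[1]) / d_ms + 1e-9)
  need <- window_samples(1 / rate, stream$nominal_rate)
  cnt <- tabulate(k + 1L, nbins = max(k) + 1L)
  sums <- rowsum(stream$records$ay, k, reorder = TRUE)
  blocks <- as.integer(rownames(sums))
  full <- cnt[blocks + 1L] >= need
  out <- tibble::tibble(
    time = ts[1] / 1000 + (blocks[full] + 1) / rate,
    block = blocks[full],
    ay = as.vector(sums[full, 1]) / cnt[blocks[full] + 1L]
  )
  attr(out, "resample_rate") <- rate
  out
}

## Trailing rolling sum of x over w samples; NA before w samples exist.
rolling_sum <- function(x, w) {
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  cs <- cumsum(x)
  c(rep(NA_real_, w - 1L), cs[w:n] - c(0, cs[seq_len(n - w)]))
}

## A trailing window of w samples ending at i is trustworthy only when
## those samples sit on consecutive blocks (no gap hidden inside).
window_contiguous <- function(block, w) {
  n <- length(block)
  if (n < w) return(rep(FALSE, n))
  c(rep(FALSE, w - 1L), block[w:n] - block[seq_len(n - w + 1L)] == w - 1L)
}

#' Banded in-window count of Y-axis readings
#'
#' For each resampled sample, counts how many of the trailing
#' `count_window` seconds of Y-axis readings fall strictly inside the
#' accelerometer band `(thr_inf, thr_sup)`. The window is trailing
#' (right-aligned) so the statistic is computable in real time on the
#' collar. Samples whose window is not yet full, or whose window spans a
#' coverage gap, are flagged as warmup and carry no count.
#'
#' @param resampled A [resample_ay()] result.
#' @param params [posture_params()].
#' @return The input tibble with `f_count` (integer, `NA` in warmup) and
#'   `warmup` (logical) columns.
#' @export
banded_count <- function(resampled, params) {
  stopifnot(inherits(params, "posture_params"))
  rate <- attr(resampled, "resample_rate")
  if (!is.null(rate) && abs(rate - params$resample_rate) > 1e-9) {
    stop("resampled series rate does not match params$resample_rate",
         call. = FALSE)
  }
  w <- params$capacity
  in_band <- resampled$ay > params$thr_inf & resampled$ay < params$thr_sup
  fc <- rolling_sum(as.numeric(in_band), w)
  ok <- window_contiguous(resampled$block, w)
  fc[!ok] <- NA_real_
  resampled$f_count <- as.integer(fc)
  resampled$warmup <- !ok
  resampled
}

#' Threshold the banded count into the standing/lying signal
#'
#' `f_standing` is 1 (standing) where `f_count` strictly exceeds
#' `thr_standing` and 0 (lying) where it is at or below; warmup samples
#' carry no value.
#'
#' @param counted A [banded_count()] result.
#' @param params [posture_params()].
#' @return The input tibble with an `f_standing` column.
#' @export
classify_standing <- function(counted, params) {
  stopifnot(inherits(params, "posture_params"))
  counted$f_standing <- ifelse(is.na(counted$f_count), NA_integer_,
                               as.integer(counted$f_count > params$thr_standing))
  counted
}

#' Full posture classification of a collar stream
#'
#' Convenience composition: [resample_ay()], [banded_count()] and
#' [classify_standing()] in one call.
#'
#' @param stream A [collar_stream()].
#' @param params [posture_params()].
#' @return A `posture_series` tibble: `time`, `block`, `ay`, `f_count`,
#'   `f_standing`, `warmup`; the parameters are attached as attribute
#'   `params`.
#' @export
posture_series <- function(stream, params) {
  out <- classify_standing(
    banded_count(resample_ay(stream, params$resample_rate), params),
    params
  )
  attr(out, "params") <- params
  class(out) <- unique(c("posture_series", class(out)))
  out
}
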