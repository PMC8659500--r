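## Threshold calibration from annotated data: pick the accelerometer
## band that best separates the posture-conditional banded counts, then
## place the count threshold midway between the two class means.

#' Calibrate posture thresholds from a labelled stream
#'
#' Grid-searches the accelerometer band `(thr_inf, thr_sup)` over
#' quantiles of the resampled Y-axis signal, maximising the difference
#' between the mean banded count while standing and while lying (the
#' study's calibration rule, applied to the labelled distributions).
#' `thr_standing` is then set to the midpoint of the two
#' posture-conditional count means, floored so that with an odd window
#' capacity the lie-down and stand-up detection latencies are equal.
#'
#' Block-level posture labels are the majority label among the block's
#' retained (non-excluded) records; blocks with less than half of their
#' records labelled are ignored. Class means and the balanced accuracy
#' are evaluated over posture-pure count windows (every block in the
#' trailing window carrying the same label): a window straddling a
#' transition holds a mid-flight count that neither class can claim.
#' Signed separation (standing minus lying) is maximised, preserving
#' the convention that standing produces the larger count.
#'
#' @param labelled A [synchronize()] (and typically
#'   [trim_pre_transition()]) result carrying posture labels `B1`/`B2`.
#' @param count_window,resample_rate See [posture_params()].
#' @param n_grid Number of quantile candidates per threshold.
#' @return A [posture_params()] whose `calibration` attribute records
#'   the achieved count separation, the balanced classification accuracy
#'   on the calibration data, the class count means and the block count.
#' @export
calibrate_thresholds <- function(labelled, count_window = 900,
                                 resample_rate = 0.27, n_grid = 24) {
  stopifnot(inherits(labelled, "labelled_stream"))
  if (identical(labelled$label_set, "general")) {
    stop("general-behaviour labels: run map_general_to_posture() first",
         call. = FALSE)
  }
  rs <- resample_ay(labelled, resample_rate)
  lab <- block_labels(labelled, rs)
  n_st <- sum(lab == "B1", na.rm = TRUE)
  n_ly <- sum(lab == "B2", na.rm = TRUE)
  if (n_st == 0L) stop("calibration data contain no standing (B1) blocks",
                       call. = FALSE)
  if (n_ly == 0L) stop("calibration data contain no lying (B2) blocks",
                       call. = FALSE)
  w <- window_samples(count_window, resample_rate)
  ok <- window_contiguous(rs$block, w)
  ## posture-pure windows: every block in the trailing window labelled
  ## with the same class. Windows straddling a transition are ambiguous
  ## by construction (the count is mid-flight) and are left out of the
  ## class means and the accuracy figure.
  labnum <- ifelse(lab == "B1", 1, 0)
  n_lab <- rolling_sum(as.numeric(!is.na(lab)), w)
  n_st <- rolling_sum(ifelse(is.na(lab), 0, labnum), w)
  pure_st <- ok & !is.na(n_lab) & n_lab == w & n_st == w
  pure_ly <- ok & !is.na(n_lab) & n_lab == w & n_st == 0
  if (!any(pure_st)) stop("no uninterrupted standing (B1) windows in the ",
                          "calibration data", call. = FALSE)
  if (!any(pure_ly)) stop("no uninterrupted lying (B2) windows in the ",
                          "calibration data", call. = FALSE)
  ay_lab <- rs$ay[!is.na(lab)]
  cand <- unique(c(
    min(ay_lab) - sd(ay_lab), # open band edges beyond the data
    quantile(ay_lab, probs = seq(0.02, 0.98, length.out = n_grid),
             names = FALSE, type = 7),
    max(ay_lab) + sd(ay_lab)
  ))
  best <- list(sep = -Inf)
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (cand[i] >= cand[j]) next
      fc <- rolling_sum(as.numeric(rs$ay > cand[i] & rs$ay < cand[j]), w)
      m_st <- mean(fc[pure_st])
      m_ly <- mean(fc[pure_ly])
      sep <- m_st - m_ly
      if (is.finite(sep) && sep > best$sep) {
        best <- list(sep = sep, inf = cand[i], sup = cand[j],
                     m_st = m_st, m_ly = m_ly, fc = fc)
      }
    }
  }
  if (!is.finite(best$sep)) {
    stop("calibration failed: no band separates the posture classes",
         call. = FALSE)
  }
  thr_standing <- as.integer(floor((best$m_st + best$m_ly) / 2))
  params <- posture_params(best$inf, best$sup, thr_standing,
                           count_window = count_window,
                           resample_rate = resample_rate)
  bal <- mean(c(mean(best$fc[pure_st] > thr_standing),
                mean(best$fc[pure_ly] <= thr_standing)))
  attr(params, "calibration") <- list(
    separation = best$sep,
    balanced_accuracy = bal,
    mean_count_standing = best$m_st,
    mean_count_lying = best$m_ly,
    n_windows = sum(pure_st) + sum(pure_ly)
  )
  params
}

## Majority posture label per resampled block; NA when fewer than half
## of the block's records are labelled and retained.
block_labels <- function(labelled, resampled) {
  rate <- attr(resampled, "resample_rate")
  ts <- labelled$records$timestamp
  d_ms <- 1000 / rate
  k <- floor((ts - ts[1]) / d_ms + 1e-9)
  usable <- !is.na(labelled$records$label) & !labelled$records$excluded
  nb <- max(k) + 1L
  tot <- tabulate(k + 1L, nbins = nb)
  n_st <- tabulate((k + 1L)[usable & labelled$records$label == "B1"],
                   nbins = nb)
  n_ly <- tabulate((k + 1L)[usable & labelled$records$label == "B2"],
                   nbins = nb)
  bl <- resampled$block + 1L
  lab <- rep(NA_character_, nrow(resampled))
  enough <- (n_st[bl] + n_ly[bl]) >= tot[bl] / 2
  lab[enough & n_st[bl] > n_ly[bl]] <- "B1"
  lab[enough & n_ly[bl] > n_st[bl]] <- "B2"
  lab
}
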