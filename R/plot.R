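#' Plot the rolling bout statistic with trigger and calving marks
#'
#' A week of `f_parturition` with the per-animal trigger as a horizontal
#' dashed line and the calving instant as a vertical one — the standard
#' way to inspect a detection run.
#'
#' @param series A [rolling_bout_count()] result.
#' @param trigger Optional [fit_trigger()] result.
#' @param calving_time Optional calving time, seconds on the stream
#'   clock.
#' @return A ggplot object.
#' @export
plot_parturition <- function(series, trigger = NULL, calving_time = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_parturition() needs the ggplot2 package", call. = FALSE)
  }
  df <- data.frame(hours = series$time / 3600,
                   f_parturition = series$f_parturition)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$f_parturition)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(x = "time [h]", y = "transitions in trailing 5 h") +
    ggplot2::theme_minimal()
  if (!is.null(trigger)) {
    p <- p + ggplot2::geom_hline(yintercept = trigger$trigger_value,
                                 linetype = "dashed", colour = "darkgreen")
  }
  if (!is.null(calving_time)) {
    p <- p + ggplot2::geom_vline(xintercept = calving_time / 3600,
                                 linetype = "dotted", colour = "red")
  }
  p
}
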