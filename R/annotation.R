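## Joining observer annotations to sensor streams. The annotation GUI
## records state *changes*, so labels extend forward in time until the
## next event (last observation carried forward).

#' Synchronise annotation events with a collar stream
#'
#' Joins observer events to sensor records by timestamp: each record
#' takes the most recent preceding event's label, records before the
#' first event are unlabelled, and blank events (label `NA` or `""`,
#' which observers enter when they lose sight of the animal) open an
#' unlabelled span. Events outside the stream's time range are dropped
#' with a warning.
#'
#' @param stream A [collar_stream()].
#' @param events Event tibble as produced by [emit_annotations()] or
#'   [read_annotations()]: at least `timestamp` (ms, same clock as the
#'   stream) and `label`; a single label set per call.
#' @return A `labelled_stream`: the input stream whose records gain
#'   `label` (character, `NA` = unlabelled) and `excluded` (logical,
#'   all `FALSE`) columns, with the events retained for later trimming.
#' @export
synchronize <- function(stream, events) {
  stopifnot(inherits(stream, "collar_stream"))
  ts <- stream$records$timestamp
  if (nrow(events) > 0 && length(ts) > 0) {
    outside <- events$timestamp < ts[1] | events$timestamp > ts[length(ts)]
    if (any(outside)) {
      warning(sum(outside), " event(s) outside the stream's time range; ",
              "ignored", call. = FALSE)
      events <- events[!outside, , drop = FALSE]
    }
  }
  events <- events[order(events$timestamp), , drop = FALSE]
  lab <- events$label
  lab[!is.na(lab) & lab == ""] <- NA_character_
  idx <- findInterval(ts, events$timestamp)
  stream$records$label <- c(NA_character_, lab)[idx + 1L]
  stream$records$excluded <- rep(FALSE, length(ts))
  stream$events <- events
  stream$label_set <- if ("label_set" %in% names(events) && nrow(events) > 0)
    events$label_set[1] else NA_character_
  class(stream) <- unique(c("labelled_stream", class(stream)))
  stream
}

#' Mask records shortly before each annotated action change
#'
#' Observers react with a delay, so sensor samples recorded up to
#' `horizon` seconds before an annotated action change may carry the
#' *next* action's behaviour under the previous label. Those records are
#' excluded (masked, labels preserved) from any training or calibration.
#' A record exactly `horizon` seconds before a change is excluded; one
#' sample earlier is retained. Idempotent.
#'
#' @param labelled A [synchronize()] result.
#' @param horizon Exclusion horizon before each change, seconds.
#' @return The labelled stream with its `excluded` mask updated.
#' @export
trim_pre_transition <- function(labelled, horizon = 120) {
  stopifnot(inherits(labelled, "labelled_stream"))
  ev <- labelled$events
  ts <- labelled$records$timestamp
  if (is.null(ev) || nrow(ev) < 2L || length(ts) == 0L) return(labelled)
  lab <- ev$label
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  changed <- c(FALSE, !same(lab[-length(lab)], lab[-1]))
  change_ms <- ev$timestamp[changed]
  excl <- labelled$records$excluded
  for (tc in change_ms) {
    lo <- findInterval(tc - horizon * 1000 - 1, ts) + 1L # first ts >= tc-h
    hi <- findInterval(tc - 1, ts)                       # last ts < tc
    if (lo <= hi) excl[lo:hi] <- TRUE
  }
  labelled$records$excluded <- excl
  labelled
}

#' Map general-behaviour labels onto postures
#'
#' Some general behaviours imply a posture: walking (`A4`) and
#' grazing/eating (`A1`) are performed standing, whereas ruminating
#' (`A2`) and neutral (`A3`) occur in both postures and therefore map to
#' unlabelled. The grazing mapping can be disabled for herds that are
#' fed lying down.
#'
#' @param labelled A [synchronize()] result carrying general labels.
#' @param grazing_standing Treat `A1` as standing (default `TRUE`).
#' @return The labelled stream re-expressed in the posture label set
#'   (`B1`/`B2`/`NA`). Posture-set input is returned unchanged with a
#'   warning.
#' @export
map_general_to_posture <- function(labelled, grazing_standing = TRUE) {
  stopifnot(inherits(labelled, "labelled_stream"))
  if (identical(labelled$label_set, "posture")) {
    warning("stream already carries posture labels; nothing to map",
            call. = FALSE)
    return(labelled)
  }
  map <- c(A1 = if (grazing_standing) "B1" else NA_character_,
           A2 = NA_character_, A3 = NA_character_, A4 = "B1")
  remap <- function(x) unname(map[x])
  labelled$records$label <- remap(labelled$records$label)
  if (!is.null(labelled$events) && nrow(labelled$events) > 0) {
    labelled$events$label <- remap(labelled$events$label)
    labelled$events$label_set <- "posture"
  }
  labelled$label_set <- "posture"
  labelled
}

#' Write annotation events to CSV
#'
#' Mirrors the export of the field annotation software: one row per
#' event with `timestamp` (ms), `cow_id`, `label_set`, `label`, `note`.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read annotation events from CSV
#'
#' @param path CSV written by [write_annotations()] or the annotation
#'   software.
#' @return Event tibble ordered by timestamp.
#' @export
read_annotations <- function(path) {
  ev <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("timestamp", "label") %in% names(ev)))
  ev[order(ev$timestamp), , drop = FALSE]
}
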