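## Record streams: ordered collar records plus gap accounting. The collar
## dumps one file per hour; a stream stitches the files back together.

#' Construct a collar record stream
#'
#' Bundles decoded records with their provenance: the 64-bit collar
#' identifier (kept as a string), the absolute epoch that anchors the
#' 32-bit millisecond timestamps (exchanged over BLE when the collar is
#' initialised; optional), and gap markers. A gap is any inter-sample
#' interval exceeding `gap_factor` nominal IMU periods; gaps are recorded,
#' never interpolated.
#'
#' @param records Tibble of decoded records (see [decode_records()]).
#' @param collar_id Collar identifier string.
#' @param epoch Optional `POSIXct` anchoring timestamp 0.
#' @param nominal_rate Nominal IMU sampling rate in Hz.
#' @param gap_factor Multiple of the nominal period beyond which an
#'   interval counts as a gap.
#' @param source_files Character vector of originating file paths.
#' @return An object of class `collar_stream`.
#' @export
collar_stream <- function(records, collar_id = NA_character_, epoch = NULL,
                          nominal_rate = 17.6, gap_factor = 3,
                          source_files = character(0)) {
  stopifnot(is.data.frame(records))
  dt <- diff(records$timestamp)
  gap_at <- which(dt > gap_factor * 1000 / nominal_rate)
  structure(
    list(
      records = tibble::as_tibble(records),
      collar_id = as.character(collar_id),
      epoch = epoch,
      nominal_rate = nominal_rate,
      gap_factor = gap_factor,
      gaps = tibble::tibble(after = gap_at, dt_ms = dt[gap_at]),
      source_files = source_files
    ),
    class = "collar_stream"
  )
}

#' @export
print.collar_stream <- function(x, ...) {
  n <- nrow(x$records)
  span <- if (n > 0) diff(range(x$records$timestamp)) / 1000 else 0
  cat(sprintf(
    "<collar_stream> collar %s: %d records, %.1f h, %d gap(s), %d file(s)\n",
    x$collar_id, n, span / 3600, nrow(x$gaps), length(x$source_files)
  ))
  invisible(x)
}

#' Read a collar stream from hourly binary log files
#'
#' Reads and concatenates the collar's hourly binary files. Files are
#' ordered by their first timestamp; a trailing partial record (the
#' firmware may lose power mid-write) is dropped with a warning, and
#' non-monotonic timestamps within a file are stably sorted with a
#' warning rather than rejected. Timestamp jumps between consecutive
#' samples larger than `gap_factor` nominal periods become gap markers.
#'
#' @param paths Character vector of file paths (any order).
#' @inheritParams collar_stream
#' @inheritParams decode_records
#' @return A [collar_stream()].
#' @export
read_collar_stream <- function(paths, collar_id = NA_character_, epoch = NULL,
                               nominal_rate = 17.6, gap_factor = 3,
                               plausibility_g = 8, endian = "little") {
  width <- collar_record_size()
  chunks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("cannot read collar file: ", p, call. = FALSE)
    bytes <- readBin(p, "raw", n = file.size(p))
    stray <- length(bytes) %% width
    if (stray > 0L) {
      warning(sprintf("%s: dropping %d trailing byte(s) (partial record)",
                      p, stray), call. = FALSE)
      bytes <- bytes[seq_len(length(bytes) - stray)]
    }
    recs <- decode_records(bytes, plausibility_g = plausibility_g,
                           endian = endian)
    if (is.unsorted(recs$timestamp)) {
      warning(sprintf("%s: non-monotonic timestamps; applying stable sort", p),
              call. = FALSE)
      recs <- recs[order(recs$timestamp), , drop = FALSE]
    }
    chunks[[i]] <- recs
  }
  first_ts <- vapply(chunks, function(r) {
    if (nrow(r) > 0) r$timestamp[1] else Inf
  }, numeric(1))
  ord <- order(first_ts)
  records <- do.call(rbind, chunks[ord])
  if (is.null(records)) {
    records <- decode_records(raw(0))
  }
  collar_stream(records, collar_id = collar_id, epoch = epoch,
                nominal_rate = nominal_rate, gap_factor = gap_factor,
                source_files = as.character(paths[ord]))
}

#' Write a collar stream as hourly binary log files
#'
#' Inverse of [read_collar_stream()]: splits the records on `rollover`
#' boundaries of the timestamp clock (the firmware starts a new file
#' every hour to bound data loss) and writes one binary file per
#' non-empty interval.
#'
#' @param stream A [collar_stream()].
#' @param dir Output directory (created if needed).
#' @param rollover File rollover interval in seconds.
#' @param prefix File name prefix; defaults to the collar id.
#' @param endian Byte order.
#' @return Invisibly, the character vector of files written (time order).
#' @export
write_collar_stream <- function(stream, dir, rollover = 3600,
                                prefix = NULL, endian = "little") {
  stopifnot(inherits(stream, "collar_stream"))
  recs <- stream$records
  if (is.null(prefix)) {
    prefix <- if (is.na(stream$collar_id)) "collar" else stream$collar_id
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot write to ", dir, call. = FALSE)
  if (nrow(recs) == 0L) return(invisible(character(0)))
  if (is.unsorted(recs$timestamp)) {
    stop("records must be time-ordered before writing", call. = FALSE)
  }
  bucket <- floor(recs$timestamp / (rollover * 1000))
  paths <- character(0)
  for (b in sort(unique(bucket))) {
    path <- file.path(dir, sprintf("%s_%06d.bin", prefix, b))
    writeBin(encode_records(recs[bucket == b, , drop = FALSE],
                            endian = endian), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Export a collar stream to CSV in physical units
#'
#' One column per record field. When the stream carries an absolute
#' epoch, an additional leading `time_utc` column gives the resolved
#' ISO-8601 timestamp; the raw millisecond counter is always kept.
#'
#' @param stream A [collar_stream()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
stream_to_csv <- function(stream, path) {
  stopifnot(inherits(stream, "collar_stream"))
  out <- stream$records
  if (!is.null(stream$epoch)) {
    abs_time <- stream$epoch + out$timestamp / 1000
    out <- cbind(
      time_utc = format(abs_time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
      out
    )
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
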