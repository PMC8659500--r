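## Fixed-width binary record format written by the collar firmware.
## 13 fields, 4 bytes each, in on-disk order. Integer fields carry the
## scale factor that converts the stored integer to physical units.

.collar_fields <- data.frame(
  name  = c("timestamp", "temp_imu", "temp_skin", "lon", "lat", "alt",
            "speed", "ax", "ay", "az", "gx", "gy", "gz"),
  what  = c("integer", "double", "double", "integer", "integer", "integer",
            "integer", "double", "double", "double", "double", "double",
            "double"),
  scale = c(1, 1, 1, 1e-7, 1e-7, 1e-3, 1e-3, 1, 1, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' Width of one binary collar record in bytes
#'
#' Thirteen fixed-width fields (one `int32` millisecond timestamp, two
#' `float32` temperatures, four scaled `int32` GNSS fields and six
#' `float32` inertial channels) of four bytes each.
#'
#' @return Integer scalar, `52L`.
#' @export
collar_record_size <- function() {
  nrow(.collar_fields) * 4L
}

#' Decode binary collar records
#'
#' Converts a raw vector holding whole fixed-width collar records into a
#' tibble with one row per record and all fields in physical units:
#' milliseconds (timestamp), degrees Celsius, degrees (longitude/latitude,
#' stored as degrees times 1e7), metres and metres/second (stored times
#' 1e3), acceleration in multiples of g and angular rate in degrees/s.
#'
#' Records whose inertial channels are non-finite, or whose acceleration
#' magnitude exceeds `plausibility_g`, are kept but flagged in the
#' `flagged` column rather than rejected: field devices glitch, and the
#' downstream pipeline decides what to do with implausible samples.
#'
#' @param bytes Raw vector; its length must be a multiple of
#'   [collar_record_size()].
#' @param plausibility_g Acceleration-magnitude bound (in g) above which a
#'   record is flagged.
#' @param endian Byte order of the stored fields; the collar's ARM core
#'   writes little-endian, but the dialect is configurable.
#' @return A tibble with the 13 record fields plus a logical `flagged`
#'   column.
#' @export
decode_records <- function(bytes, plausibility_g = 8, endian = "little") {
  stopifnot(is.raw(bytes))
  width <- collar_record_size()
  if (length(bytes) %% width != 0L) {
    stop(sprintf(
      "truncated record: %d stray byte(s) at offset %d",
      length(bytes) %% width, (length(bytes) %/% width) * width
    ), call. = FALSE)
  }
  n <- length(bytes) %/% width
  out <- vector("list", nrow(.collar_fields))
  names(out) <- .collar_fields$name
  if (n == 0L) {
    for (j in seq_len(nrow(.collar_fields))) out[[j]] <- numeric(0)
    res <- tibble::as_tibble(out)
    res$flagged <- logical(0)
    return(res)
  }
  mat <- matrix(bytes, nrow = width)
  for (j in seq_len(nrow(.collar_fields))) {
    rows <- (4L * (j - 1L) + 1L):(4L * j)
    vals <- readBin(as.vector(mat[rows, , drop = FALSE]),
                    what = .collar_fields$what[j], n = n, size = 4L,
                    endian = endian)
    out[[j]] <- as.numeric(vals) * .collar_fields$scale[j]
  }
  res <- tibble::as_tibble(out)
  amag <- sqrt(res$ax^2 + res$ay^2 + res$az^2)
  imu <- cbind(res$ax, res$ay, res$az, res$gx, res$gy, res$gz)
  res$flagged <- rowSums(!is.finite(imu)) > 0L |
    (is.finite(amag) & amag > plausibility_g)
  res
}

#' Encode collar records to binary form
#'
#' Inverse of [decode_records()]: writes each row of `records` as one
#' fixed-width binary record, rescaling the integer-backed fields
#' (longitude/latitude times 1e7, altitude/speed times 1e3) and rounding
#' them to the nearest stored integer. Float fields are stored as IEEE
#' `float32`; a value that is exactly representable in single precision
#' round-trips bit-for-bit.
#'
#' @param records Data frame with the 13 collar fields in physical units.
#' @param endian Byte order; see [decode_records()].
#' @return Raw vector of `nrow(records) * collar_record_size()` bytes.
#' @export
encode_records <- function(records, endian = "little") {
  miss <- setdiff(.collar_fields$name, names(records))
  if (length(miss) > 0L) {
    stop("records missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  width <- collar_record_size()
  if (n == 0L) return(raw(0))
  mat <- matrix(as.raw(0), nrow = width, ncol = n)
  for (j in seq_len(nrow(.collar_fields))) {
    fld <- .collar_fields$name[j]
    vals <- records[[fld]] / .collar_fields$scale[j]
    if (.collar_fields$what[j] == "integer") {
      vals <- round(vals)
      if (any(is.na(vals)) || any(abs(vals) > .Machine$integer.max)) {
        stop(sprintf("field '%s' out of int32 range", fld), call. = FALSE)
      }
      vals <- as.integer(vals)
    }
    rows <- (4L * (j - 1L) + 1L):(4L * j)
    mat[rows, ] <- matrix(writeBin(vals, raw(), size = 4L, endian = endian),
                          nrow = 4L)
  }
  as.vector(mat)
}
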