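#' Define how sensor XYZ channels map onto body-relative axes
#'
#' A leg-mounted accelerometer reports acceleration on its own XYZ axes; their
#' orientation depends on the manufacturer and on how the housing was strapped
#' to the metatarsus. Analysis works in body-relative directions defined for a
#' standing cow: *forward* (direction of view), *upward* (along the leg toward
#' the torso), and *right* (perpendicular to the sagittal plane). An axis map
#' is a signed bijection from `{X, Y, Z}` onto these three directions.
#'
#' @param fwd,up,right Source channel for each body axis, given as `"X"`,
#'   `"Y"`, or `"Z"`, optionally prefixed with a sign (`"-Z"` means the Z
#'   channel enters with flipped sign).
#'
#' @return An object of class `axis_map`: a list with elements `channel`
#'   (named character vector) and `sign` (named numeric vector of +1/-1).
#'
#' @examples
#' axis_map(fwd = "X", up = "Y", right = "Z")   # identity
#' axis_map(fwd = "-Y", up = "Z", right = "X")
#' @export
axis_map <- function(fwd = "X", up = "Y", right = "Z") {
  spec <- c(fwd = fwd, up = up, right = right)
  parse1 <- function(s) {
    m <- regmatches(s, regexec("^([+-]?)([XYZ])$", s))[[1]]
    if (length(m) == 0) {
      abort_input(sprintf(
        "Invalid axis specification '%s': use 'X', 'Y' or 'Z', optionally signed ('-Z').", s
      ))
    }
    list(sign = if (m[2] == "-") -1 else 1, channel = m[3])
  }
  parsed <- lapply(spec, parse1)
  channel <- vapply(parsed, `[[`, character(1), "channel")
  sign <- vapply(parsed, `[[`, numeric(1), "sign")
  if (anyDuplicated(channel)) {
    abort_input(sprintf(
      "Axis map must be a bijection: channel %s is used more than once.",
      channel[duplicated(channel)][1]
    ))
  }
  structure(list(channel = channel, sign = sign), class = "axis_map")
}

#' @export
print.axis_map <- function(x, ...) {
  cat("<axis_map>\n")
  for (ax in names(x$channel)) {
    cat(sprintf("  %-5s <- %s%s\n", ax, if (x$sign[[ax]] < 0) "-" else "+", x$channel[[ax]]))
  }
  invisible(x)
}

#' Describe the layout of raw accelerometer text files
#'
#' Generic loggers write delimiter-separated text with varying separators,
#' header lengths, column orders, timestamp formats, and decimal marks. An
#' `accel_format` collects these properties so the same description can be
#' used both to parse files and to write synthetic fixtures.
#'
#' @param sep Field separator. A single character is passed to the delimited
#'   reader; a longer string is treated as a regular expression.
#' @param skip Number of header lines to skip before data begin.
#' @param col_time,col_x,col_y,col_z 1-based column indices of the timestamp
#'   and the three acceleration channels. Must be distinct.
#' @param time_format `strptime()` format string for the timestamp column.
#'   Use `%OS` for fractional seconds.
#' @param decimal Decimal mark used in the acceleration columns.
#' @param id_pattern Optional regular expression applied to the file's base
#'   name to extract the cow id; the first capture group (or, failing that,
#'   the whole match) is used. When `NULL` the base name without extension is
#'   the id.
#'
#' @return An object of class `accel_format`.
#' @examples
#' accel_format(sep = ";", skip = 1, time_format = "%d.%m.%Y %H:%M:%OS")
#' @export
accel_format <- function(sep = ",", skip = 0,
                         col_time = 1, col_x = 2, col_y = 3, col_z = 4,
                         time_format = "%Y-%m-%d %H:%M:%OS",
                         decimal = ".", id_pattern = NULL) {
  idx <- c(time = col_time, x = col_x, y = col_y, z = col_z)
  if (any(idx < 1) || any(idx != round(idx))) {
    abort_input("Column indices must be positive integers.")
  }
  if (anyDuplicated(idx)) {
    abort_input("Timestamp and acceleration columns must have distinct indices.")
  }
  if (!is.character(sep) || length(sep) != 1L || nchar(sep) < 1L) {
    abort_input("`sep` must be a non-empty string.")
  }
  structure(
    list(sep = sep, skip = as.integer(skip), col_time = as.integer(col_time),
         col_x = as.integer(col_x), col_y = as.integer(col_y),
         col_z = as.integer(col_z), time_format = time_format,
         decimal = decimal, id_pattern = id_pattern),
    class = "accel_format"
  )
}

#' Parse one raw accelerometer file into a time + XYZ table
#'
#' Reads a delimiter-separated logger file according to an [accel_format()]
#' and returns the raw sensor channels, before any axis mapping. Timestamps
#' failing to parse under the stated format are an error naming the offending
#' line; non-monotone timestamps are rejected.
#'
#' @param path Path to the file.
#' @param format An [accel_format()].
#'
#' @return A tibble with columns `time` (POSIXct, UTC), `X`, `Y`, `Z` (g).
#' @seealso [map_axes()], [read_accel_files()]
#' @export
parse_accel_file <- function(path, format = accel_format()) {
  stopifnot(inherits(format, "accel_format"))
  if (!file.exists(path)) {
    abort_input(sprintf("File not found: %s", path))
  }
  fields <- read_fields(path, format)
  need <- max(format$col_time, format$col_x, format$col_y, format$col_z)
  width <- vapply(fields, length, integer(1))
  if (any(width < need)) {
    bad <- which(width < need)[1]
    abort_input(sprintf(
      "%s: line %d has %d field(s) but column index %d was requested.",
      path, bad + format$skip, width[bad], need
    ))
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  time_raw <- grab(format$col_time)
  time <- as.POSIXct(strptime(time_raw, format = format$time_format, tz = "UTC"))
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    abort_input(sprintf(
      "%s: line %d: timestamp '%s' does not match format '%s'.",
      path, bad + format$skip, time_raw[bad], format$time_format
    ))
  }
  num <- function(i) {
    v <- grab(i)
    if (format$decimal != ".") v <- gsub(format$decimal, ".", v, fixed = TRUE)
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      bad <- which(is.na(out))[1]
      abort_input(sprintf(
        "%s: line %d: '%s' in column %d is not a number.",
        path, bad + format$skip, v[bad], i
      ))
    }
    out
  }
  out <- tibble::tibble(time = time, X = num(format$col_x),
                        Y = num(format$col_y), Z = num(format$col_z))
  if (is.unsorted(out$time, strictly = TRUE)) {
    bad <- which(diff(as.numeric(out$time)) <= 0)[1]
    abort_input(sprintf(
      "%s: timestamps are not strictly increasing (first violation after line %d).",
      path, bad + format$skip
    ))
  }
  out
}

## Split data lines into fields. Single-character separators go through readr;
## anything longer is treated as a regex and split by hand (no installed
## reader supports regex delimiters).
read_fields <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format$skip > 0) lines <- lines[-seq_len(min(format$skip, length(lines)))]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort_input(sprintf("%s: no data lines after skipping %d header line(s).",
                        path, format$skip))
  }
  if (nchar(format$sep) == 1L) {
    strsplit(lines, format$sep, fixed = TRUE)
  } else {
    strsplit(lines, format$sep, perl = TRUE)
  }
}

#' Rename sensor channels to body-relative axes
#'
#' Applies an [axis_map()] to a raw XYZ table, producing the body-relative
#' acceleration columns used throughout the package. The mapping is a signed
#' permutation, so per-sample vector magnitude is preserved exactly.
#'
#' @param data A data frame with columns `X`, `Y`, `Z` (and any others, which
#'   pass through untouched).
#' @param map An [axis_map()].
#'
#' @return A tibble where `X`, `Y`, `Z` are replaced by `acc_fwd`, `acc_up`,
#'   `acc_right`.
#' @export
map_axes <- function(data, map = axis_map()) {
  stopifnot(inherits(map, "axis_map"))
  missing_ch <- setdiff(c("X", "Y", "Z"), names(data))
  if (length(missing_ch)) {
    abort_input(sprintf("`data` lacks channel column(s): %s",
                        paste(missing_ch, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  body <- c(fwd = "acc_fwd", up = "acc_up", right = "acc_right")
  for (ax in names(body)) {
    out[[body[[ax]]]] <- map$sign[[ax]] * data[[map$channel[[ax]]]]
  }
  out[c("X", "Y", "Z")] <- NULL
  front <- intersect(c("id", "time", unname(body)), names(out))
  out[c(front, setdiff(names(out), front))]
}

#' Invert an axis map
#'
#' @param map An [axis_map()].
#' @return An `axis_map`-like list mapping body axes back to channels,
#'   returned as a named list with `channel` (body axis feeding each of X, Y,
#'   Z) and `sign`.
#' @keywords internal
invert_axis_map <- function(map) {
  channel <- setNames(names(map$channel), map$channel)[c("X", "Y", "Z")]
  sign <- setNames(map$sign[channel], c("X", "Y", "Z"))
  list(channel = channel, sign = sign)
}

#' Import raw accelerometer files for one or several cows
#'
#' Parses each file with [parse_accel_file()], maps sensor channels to
#' body-relative axes, assigns a cow id per file, and validates the combined
#' series. One file per cow is assumed, following the one-logger-per-animal
#' convention.
#'
#' @param paths Character vector of file paths.
#' @param format An [accel_format()].
#' @param map An [axis_map()].
#'
#' @return A validated tibble with columns `id`, `time`, `acc_fwd`, `acc_up`,
#'   `acc_right` — the standard acceleration table accepted by [add_lying()]
#'   and friends.
#' @export
read_accel_files <- function(paths, format = accel_format(), map = axis_map()) {
  if (length(paths) == 0) abort_input("No input files given.")
  one <- function(path) {
    raw <- parse_accel_file(path, format)
    body <- map_axes(raw, map)
    body$id <- file_cow_id(path, format$id_pattern)
    body
  }
  out <- dplyr::bind_rows(lapply(paths, one))
  read_accel_table(out[c("id", "time", "acc_fwd", "acc_up", "acc_right")])
}

file_cow_id <- function(path, id_pattern) {
  base <- basename(path)
  if (is.null(id_pattern)) {
    return(sub("\\.[^.]*$", "", base))
  }
  m <- regmatches(base, regexec(id_pattern, base))[[1]]
  if (length(m) == 0) {
    abort_input(sprintf("id_pattern '%s' does not match file name '%s'.",
                        id_pattern, base))
  }
  if (length(m) >= 2 && nzchar(m[2])) m[2] else m[1]
}

#' Validate a prepared acceleration table
#'
#' Accepts data the user concatenated themselves, provided it carries exactly
#' the expected columns: `id`, `time`, `acc_fwd`, `acc_up`, `acc_right`.
#' Checks per-cow time monotonicity, finiteness of all acceleration values,
#' and warns about recording gaps larger than ten nominal sampling intervals
#' (processing continues, treating samples as contiguous).
#'
#' @param data A data frame with the five required columns. `time` may be
#'   POSIXct or numeric seconds.
#'
#' @return A tibble sorted by `id` then `time`.
#' @export
read_accel_table <- function(data) {
  required <- c("id", "time", "acc_fwd", "acc_up", "acc_right")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort_input(sprintf(
      "Missing column(s): %s. Expected exactly: %s.",
      paste(missing_cols, collapse = ", "), paste(required, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(data)
  out$id <- as.character(out$id)
  if (!inherits(out$time, "POSIXct") && !is.numeric(out$time)) {
    abort_input("`time` must be POSIXct or numeric seconds.")
  }
  for (col in c("acc_fwd", "acc_up", "acc_right")) {
    if (!is.numeric(out[[col]])) {
      abort_input(sprintf("`%s` must be numeric.", col))
    }
    if (!all(is.finite(out[[col]]))) {
      abort_input(sprintf("`%s` contains non-finite values.", col))
    }
  }
  if (nrow(out) == 0) abort_input("Table has no rows.")
  out <- dplyr::arrange(out, .data$id, .data$time)
  for (cow in unique(out$id)) {
    tt <- as.numeric(out$time[out$id == cow])
    d <- diff(tt)
    if (any(d == 0)) {
      abort_input(sprintf("Duplicate timestamps for cow '%s'.", cow))
    }
    if (any(d < 0)) {
      abort_input(sprintf("Non-monotone timestamps for cow '%s'.", cow))
    }
    if (length(d) > 0) {
      nominal <- median(d)
      gaps <- which(d > 10 * nominal)
      if (length(gaps)) {
        warn(sprintf(
          "Cow '%s': %d recording gap(s) longer than 10x the nominal interval (first at offset %.1f s); samples are treated as contiguous for filtering.",
          cow, length(gaps), tt[gaps[1]] - tt[1]
        ))
      }
    }
  }
  out
}

#' Nominal sampling interval of an acceleration series
#'
#' The nominal interval is the median of successive time differences, pooled
#' within cows, which is robust to isolated recording gaps. A warning is
#' emitted when more than 1% of the differences deviate from the median by
#' more than 10%, indicating drifting or irregular sampling.
#'
#' @param x An acceleration table (with `time`, optionally `id`), or a
#'   numeric/POSIXct vector of timestamps.
#'
#' @return The nominal sampling interval in seconds.
#' @export
infer_sampling_interval <- function(x) {
  if (is.data.frame(x)) {
    if (!"time" %in% names(x)) abort_input("`x` has no `time` column.")
    if ("id" %in% names(x)) {
      d <- unlist(lapply(split(as.numeric(x$time), x$id), diff), use.names = FALSE)
    } else {
      d <- diff(as.numeric(x$time))
    }
  } else {
    d <- diff(as.numeric(x))
  }
  if (length(d) < 1) abort_input("At least 2 samples are needed to infer a sampling interval.")
  nominal <- median(d)
  if (nominal <= 0) abort_input("Timestamps are not increasing.")
  frac_off <- mean(abs(d - nominal) > 0.1 * nominal)
  if (frac_off > 0.01) {
    warn(sprintf(
      "%.1f%% of sampling intervals deviate by more than 10%% from the nominal %.4g s.",
      100 * frac_off, nominal
    ))
  }
  nominal
}

#' Write an acceleration table to CSV
#'
#' Exports the standard five-column acceleration table (plus any added
#' analysis columns) with stable column names; missing values are written as
#' empty fields.
#'
#' @param data The table to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}
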