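#' Classify filtered upward acceleration into lying vs standing
#'
#' A standing cow's metatarsus is near-vertical, so the gravity component on
#' the upward axis is close to 1 g; when lying it is near-horizontal and the
#' component drops toward 0. Samples with a filtered upward value below
#' `crit_lie` are lying, at or above it standing. The default of 0.5 g
#' corresponds to a leg angle of `arccos(0.5 / 1) = 60` degrees from vertical.
#' Standing is the defined complement of lying, so a value exactly at the
#' threshold is standing.
#'
#' @param gravity_up Numeric vector: filtered upward acceleration (g).
#' @param crit_lie Threshold in g, in (0, 1]. Default 0.5.
#'
#' @return Logical vector: `TRUE` where lying.
#' @export
classify_posture <- function(gravity_up, crit_lie = 0.5) {
  if (!all(is.finite(gravity_up))) abort_input("`gravity_up` contains non-finite values.")
  if (crit_lie <= 0 || crit_lie > 1) abort_input("`crit_lie` must be in (0, 1].")
  gravity_up < crit_lie
}

#' Segment a per-sample posture sequence into bouts
#'
#' Run-length encodes a lying/standing sequence into maximal single-posture
#' bouts. A bout starts at the timestamp of its first sample and ends at the
#' timestamp of the first sample of the next bout; the last bout ends at the
#' final timestamp, so bout durations tile the recording span exactly. The
#' first and last bouts are not bounded by an observed transition and are
#' flagged incomplete at the recording edge.
#'
#' @param lying Logical vector (`TRUE` = lying).
#' @param time Timestamps aligned with `lying` (POSIXct or numeric seconds),
#'   strictly increasing.
#'
#' @return A tibble with one row per bout: `bout_nr`, `posture` ("lying" or
#'   "standing"), `start`, `end`, `duration` (s), `complete_start`,
#'   `complete_end`, and the sample row range `row_start`, `row_end`.
#' @export
segment_bouts <- function(lying, time) {
  n <- length(lying)
  if (n == 0) abort_input("Empty posture sequence.")
  if (length(time) != n) abort_input("`lying` and `time` must have the same length.")
  r <- rle(lying)
  k <- length(r$lengths)
  row_end <- cumsum(r$lengths)
  row_start <- row_end - r$lengths + 1L
  start <- time[row_start]
  end <- c(time[row_start[-1]], time[n])
  tibble::tibble(
    bout_nr = seq_len(k),
    posture = ifelse(r$values, "lying", "standing"),
    start = start,
    end = end,
    duration = as.numeric(end) - as.numeric(start),
    complete_start = seq_len(k) > 1L,
    complete_end = seq_len(k) < k,
    row_start = row_start,
    row_end = row_end
  )
}

#' Remove implausibly short bouts
#'
#' The third step of the posture algorithm: lying bouts shorter than
#' `minimum_duration_lying` seconds are reclassified as standing and merged
#' with their neighbors, removing false-positive lying episodes such as a
#' standing cow lifting the instrumented hind leg toward the horizontal
#' (self-grooming). Optionally the same correction is applied to short
#' standing bouts, though genuinely false standing detections are not
#' expected in practice and no standing minimum is set by default.
#'
#' Bouts truncated by the recording edge are never removed: their true
#' duration is unknown. Each pass is applied once (lying first), not iterated
#' to a fixed point.
#'
#' @param bouts A bout table from [segment_bouts()].
#' @param minimum_duration_lying Minimum lying-bout duration in seconds
#'   (default 30).
#' @param minimum_duration_standing Optional minimum standing-bout duration
#'   in seconds (default `NULL`: no correction).
#'
#' @return A corrected bout table in the same format, re-indexed.
#' @export
enforce_min_duration <- function(bouts, minimum_duration_lying = 30,
                                 minimum_duration_standing = NULL) {
  if (minimum_duration_lying < 0) abort_input("`minimum_duration_lying` must be >= 0.")
  out <- relabel_short(bouts, "lying", minimum_duration_lying)
  if (!is.null(minimum_duration_standing)) {
    if (minimum_duration_standing < 0) abort_input("`minimum_duration_standing` must be >= 0.")
    out <- relabel_short(out, "standing", minimum_duration_standing)
  }
  out
}

relabel_short <- function(bouts, posture, min_dur) {
  interior <- bouts$complete_start & bouts$complete_end
  drop <- bouts$posture == posture & interior & bouts$duration < min_dur
  other <- if (posture == "lying") "standing" else "lying"
  bouts$posture[drop] <- other
  merge_bouts(bouts)
}

## Merge adjacent bouts of equal posture after relabeling.
merge_bouts <- function(bouts) {
  grp <- cumsum(c(TRUE, bouts$posture[-1] != bouts$posture[-nrow(bouts)]))
  merged <- dplyr::summarise(
    dplyr::group_by(bouts, grp = grp),
    posture = .data$posture[1],
    start = .data$start[1],
    end = .data$end[dplyr::n()],
    row_start = .data$row_start[1],
    row_end = .data$row_end[dplyr::n()],
    .groups = "drop"
  )
  k <- nrow(merged)
  tibble::tibble(
    bout_nr = seq_len(k),
    posture = merged$posture,
    start = merged$start,
    end = merged$end,
    duration = as.numeric(merged$end) - as.numeric(merged$start),
    complete_start = seq_len(k) > 1L,
    complete_end = seq_len(k) < k,
    row_start = merged$row_start,
    row_end = merged$row_end
  )
}

#' Detect lying and standing posture
#'
#' Annotates an acceleration table with a per-sample lying flag and bout
#' numbers, using the three-step rule-based algorithm: (1) filter the upward
#' axis to its gravity component ([gravity_component()]), (2) threshold the
#' filtered values at `crit_lie` ([classify_posture()]), (3) reclassify
#' too-short lying bouts as standing ([enforce_min_duration()]). Lying and
#' standing are mutually exclusive and collectively exhaustive; standing
#' includes walking and any other upright activity.
#'
#' @param data An acceleration table with columns `id`, `time`, `acc_fwd`,
#'   `acc_up`, `acc_right` (see [read_accel_table()]).
#' @param crit_lie Posture threshold in g (default 0.5).
#' @param minimum_duration_lying Minimum lying-bout duration in seconds
#'   (default 30).
#' @param minimum_duration_standing Optional minimum standing-bout duration
#'   (default `NULL`; setting one is not recommended).
#' @inheritParams gravity_component
#'
#' @return The input tibble with two added columns: `lying` (logical) and
#'   `bout_nr` (integer, per cow, consecutive over both postures).
#' @seealso [bouts()] for the bout-level table, [add_side()] for laterality.
#' @examples
#' sim <- simulate_cows(n_days = 1, rate = 1, seed = 1)
#' lied <- add_lying(sim)
#' head(bouts(lied))
#' @export
add_lying <- function(data, crit_lie = 0.5,
                      minimum_duration_lying = 30,
                      minimum_duration_standing = NULL,
                      filter_method = c("median", "butterworth"),
                      window_size = 10, cutoff = 0.1, order = 1) {
  filter_method <- match.arg(filter_method)
  data <- check_accel_cols(data)
  out <- data
  out$lying <- NA
  out$bout_nr <- NA_integer_
  for (cow in unique(data$id)) {
    rows <- which(data$id == cow)
    sub <- data[rows, , drop = FALSE]
    g_up <- gravity_component(sub, axis = "up", filter_method = filter_method,
                              window_size = window_size, cutoff = cutoff,
                              order = order)
    lying <- classify_posture(g_up, crit_lie = crit_lie)
    b <- segment_bouts(lying, sub$time)
    b <- enforce_min_duration(b, minimum_duration_lying = minimum_duration_lying,
                              minimum_duration_standing = minimum_duration_standing)
    lab <- rep.int(b$posture == "lying", b$row_end - b$row_start + 1L)
    nr <- rep.int(b$bout_nr, b$row_end - b$row_start + 1L)
    out$lying[rows] <- lab
    out$bout_nr[rows] <- nr
  }
  out$lying <- as.logical(out$lying)
  out
}

#' Bout-level view of an annotated series
#'
#' Collapses the per-sample `lying`/`bout_nr` annotation produced by
#' [add_lying()] into one row per bout, carrying the lying side when
#' [add_side()] has been run.
#'
#' @param data A tibble annotated by [add_lying()] (and optionally
#'   [add_side()]).
#'
#' @return A tibble with columns `id`, `bout_nr`, `posture`, `start`, `end`,
#'   `duration` (s), `complete_start`, `complete_end`, and `side` (`"left"`,
#'   `"right"`, or `NA` for standing / before [add_side()]).
#' @export
bouts <- function(data) {
  data <- check_annotated(data)
  per_cow <- function(sub) {
    b <- segment_bouts(sub$lying, sub$time)
    b$side <- NA_character_
    if ("side" %in% names(sub)) {
      b$side <- vapply(seq_len(nrow(b)), function(i) {
        s <- sub$side[b$row_start[i]:b$row_end[i]]
        s <- s[!is.na(s)]
        if (length(s)) s[1] else NA_character_
      }, character(1))
    }
    b$row_start <- NULL
    b$row_end <- NULL
    b
  }
  out <- dplyr::group_modify(dplyr::group_by(data, .data$id),
                             function(sub, key) per_cow(sub))
  dplyr::ungroup(out)
}

check_accel_cols <- function(data) {
  required <- c("id", "time", "acc_fwd", "acc_up", "acc_right")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort_input(sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(data)
}

check_annotated <- function(data) {
  data <- check_accel_cols(data)
  if (!all(c("lying", "bout_nr") %in% names(data))) {
    abort_input("No posture annotation found; run add_lying() first.")
  }
  data
}
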