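#' Fraction of a bout overlapping an interval
#'
#' The weight a bout carries in an interval summary is the proportion of the
#' bout's duration that falls inside the interval: a bout completely inside
#' an interval weighs 1, a bout whose intersection with the interval covers
#' 30% of its duration weighs 0.3 there (and 0.7 in the adjacent interval).
#' Weighting bout counts and bout-duration means this way keeps interval
#' totals from being inflated by bouts that straddle interval boundaries.
#'
#' @param bout_start,bout_end Bout limits (POSIXct or numeric seconds);
#'   vectorized.
#' @param interval_start,interval_end Interval limits.
#'
#' @return Numeric weights in `[0, 1]`.
#' @examples
#' overlap_weight(0, 100, 70, 200)   # 0.3
#' @export
overlap_weight <- function(bout_start, bout_end, interval_start, interval_end) {
  bs <- as.numeric(bout_start); be <- as.numeric(bout_end)
  is <- as.numeric(interval_start); ie <- as.numeric(interval_end)
  if (any(be <= bs)) abort_input("Bout end must be after bout start.")
  if (any(ie <= is)) abort_input("Interval end must be after interval start.")
  ov <- pmax(0, pmin(be, ie) - pmax(bs, is))
  ov / (be - bs)
}

#' Summarize individual bouts
#'
#' One row per lying or standing bout with duration, lying side, and the
#' mean of every activity measure present in the data. The first and last
#' bouts of each cow are truncated by the recording edges, so their true
#' duration is unknown: duration is reported as `NA` unless
#' `calc_for_incomplete = TRUE`, which assumes the edge bouts are complete.
#'
#' @param data A tibble annotated by [add_lying()] (and optionally
#'   [add_side()] and [add_activity()]).
#' @param calc_for_incomplete Logical: report durations for edge-truncated
#'   bouts as if they were complete (default `FALSE`).
#'
#' @return A tibble with columns `id`, `bout_nr`, `posture`, `side`, `start`,
#'   `end`, `duration` (s), `complete_start`, `complete_end`, and one
#'   `mean_<measure>` column per activity measure in `data`.
#' @export
summarize_bouts <- function(data, calc_for_incomplete = FALSE) {
  data <- check_annotated(data)
  b <- bouts(data)
  acts <- intersect(c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk"), names(data))
  if (length(acts)) {
    means <- dplyr::summarise(
      dplyr::group_by(data, .data$id, .data$bout_nr),
      dplyr::across(dplyr::all_of(acts), ~ mean(.x, na.rm = TRUE),
                    .names = "mean_{.col}"),
      .groups = "drop"
    )
    b <- dplyr::left_join(b, means, by = c("id", "bout_nr"))
  }
  if (!calc_for_incomplete) {
    b$duration[!(b$complete_start & b$complete_end)] <- NA_real_
  }
  b[c("id", "bout_nr", "posture", "side", "start", "end", "duration",
      "complete_start", "complete_end",
      grep("^mean_", names(b), value = TRUE))]
}

#' Summarize lying behavior and activity over regular intervals
#'
#' Aggregates the annotated series per cow over consecutive, half-open
#' intervals `[start, end)` of fixed length — e.g., hourly or daily. Reported
#' per interval: total lying and standing durations, lying duration broken
#' down by side, weighted bout counts, weighted mean bout durations, and the
#' mean of each activity measure over the interval's samples.
#'
#' Bout counts and duration means use fractional-overlap weights (see
#' [overlap_weight()]). Quantities that depend on the duration of an
#' edge-truncated (incomplete) bout are reported as `NA` unless
#' `calc_for_incomplete = TRUE`; plain duration totals only use the observed
#' overlap and are always reported.
#'
#' @param data A tibble annotated by [add_lying()] (and optionally
#'   [add_side()], [add_activity()]).
#' @param interval Interval length: numeric seconds or a string understood by
#'   [lubridate::duration()] such as `"1 hour"` or `"1 day"`. Default 1 hour.
#' @param anchor Origin the interval grid is aligned to (POSIXct or numeric).
#'   Default: midnight (UTC) of the earliest day in the data.
#' @param calc_for_incomplete Logical: treat edge-truncated bouts as complete
#'   (default `FALSE`).
#'
#' @return A tibble with one row per cow and interval overlapping its
#'   recording: `id`, `interval_start`, `interval_end`, `duration_lying`,
#'   `duration_lying_left`, `duration_lying_right`, `duration_standing` (all
#'   seconds), `n_bouts_lying`, `n_bouts_standing` (weighted counts),
#'   `mean_duration_lying`, `mean_duration_standing` (weighted means, s), and
#'   `mean_<measure>` per activity column.
#' @examples
#' sim <- simulate_cows(n_days = 1, rate = 1, seed = 1)
#' sim |> add_lying() |> add_side(left_leg = TRUE) |>
#'   summarize_intervals(interval = "6 hours")
#' @export
summarize_intervals <- function(data, interval = "1 hour", anchor = NULL,
                                calc_for_incomplete = FALSE) {
  data <- check_annotated(data)
  dur <- parse_interval(interval)
  if (dur <= 0) abort_input("`interval` must be positive.")
  is_posix <- inherits(data$time, "POSIXct")
  if (is.null(anchor)) {
    t0 <- min(as.numeric(data$time))
    anchor <- if (is_posix) {
      as.numeric(lubridate::floor_date(min(data$time), "day"))
    } else {
      floor(t0 / 86400) * 86400
    }
  } else {
    anchor <- as.numeric(anchor)
  }
  b_all <- bouts(data)
  if (!calc_for_incomplete) {
    b_all$duration[!(b_all$complete_start & b_all$complete_end)] <- NA_real_
  }
  acts <- intersect(c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk"), names(data))
  res <- lapply(unique(data$id), function(cow) {
    sub <- data[data$id == cow, , drop = FALSE]
    b <- b_all[b_all$id == cow, , drop = FALSE]
    tt <- as.numeric(sub$time)
    t1 <- tt[1]; tn <- tt[length(tt)]
    first <- anchor + dur * floor((t1 - anchor) / dur)
    starts <- seq(first, tn - 1e-9, by = dur)
    rows <- lapply(starts, function(s) {
      summarize_one_interval(cow, s, s + dur, b, sub, tt, acts)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  if (is_posix) {
    out$interval_start <- as.POSIXct(out$interval_start, tz = "UTC",
                                     origin = "1970-01-01")
    out$interval_end <- as.POSIXct(out$interval_end, tz = "UTC",
                                   origin = "1970-01-01")
  }
  out
}

summarize_one_interval <- function(cow, is, ie, b, sub, tt, acts) {
  bs <- as.numeric(b$start); be <- as.numeric(b$end)
  ov <- pmax(0, pmin(be, ie) - pmax(bs, is))
  lying <- b$posture == "lying"
  side <- b$side
  posture_stats <- function(sel) {
    touch <- sel & ov > 0
    d <- b$duration[touch]
    if (!any(touch)) {
      return(list(n = 0, mean_dur = NA_real_))
    }
    if (anyNA(d)) {
      return(list(n = NA_real_, mean_dur = NA_real_))
    }
    w <- ov[touch] / d
    list(n = sum(w), mean_dur = sum(w * d) / sum(w))
  }
  st_ly <- posture_stats(lying)
  st_st <- posture_stats(!lying)
  in_int <- tt >= is & tt < ie
  row <- tibble::tibble(
    id = cow,
    interval_start = is,
    interval_end = ie,
    duration_lying = sum(ov[lying]),
    duration_lying_left = sum(ov[lying & !is.na(side) & side == "left"]),
    duration_lying_right = sum(ov[lying & !is.na(side) & side == "right"]),
    duration_standing = sum(ov[!lying]),
    n_bouts_lying = st_ly$n,
    n_bouts_standing = st_st$n,
    mean_duration_lying = st_ly$mean_dur,
    mean_duration_standing = st_st$mean_dur
  )
  for (m in acts) {
    v <- sub[[m]][in_int]
    row[[paste0("mean_", m)]] <- if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  row
}

parse_interval <- function(interval) {
  if (is.character(interval)) {
    as.numeric(lubridate::duration(interval))
  } else {
    as.numeric(interval)
  }
}
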