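#' Sample a daily standing/lying schedule with known ground truth
#'
#' Draws one day of alternating standing and lying episodes emulating the
#' lying behavior of lactating dairy cows: by default 9–11 lying bouts per
#' day with durations between 60 and 100 min and a total daily lying time
#' between 8 and 13 h. The day begins and ends with a standing episode, so
#' every lying bout is interior to the day. Optionally, very short "micro"
#' lying bouts (as observed on pasture, down to ~8 s) and side switches via a
#' short standing bout can be injected.
#'
#' @param n_bouts Integer range `c(lo, hi)` for the number of lying bouts
#'   (default `c(9, 11)`).
#' @param bout_minutes Range of lying-bout durations in minutes (default
#'   `c(60, 100)`).
#' @param total_hours Range for the total daily lying time in hours (default
#'   `c(8, 13)`). The draw is restricted to values jointly feasible with
#'   `n_bouts` and `bout_minutes`.
#' @param day_hours Length of the day in hours (default 24).
#' @param standing_min_minutes Minimum standing-episode duration in minutes
#'   (default 2).
#' @param micro_bouts Number of extra micro lying bouts to inject (default 0).
#' @param micro_seconds Duration of each micro bout in seconds (default 8).
#' @param side_switches Number of lying bouts to split in two by a brief
#'   standing episode with a side change (default 0).
#' @param switch_seconds Duration of the side-switch standing episode
#'   (default 20 s — long enough to beat the default 10 s gravity filter, as
#'   real side switches are).
#' @param p_left Probability a lying bout is on the left side (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble of episodes in order: `episode`, `posture`, `side`
#'   (`NA` for standing), `start_s`, `end_s`, `duration` (seconds from the
#'   start of the day).
#' @export
sample_schedule <- function(n_bouts = c(9, 11), bout_minutes = c(60, 100),
                            total_hours = c(8, 13), day_hours = 24,
                            standing_min_minutes = 2,
                            micro_bouts = 0, micro_seconds = 8,
                            side_switches = 0, switch_seconds = 20,
                            p_left = 0.5, seed = NULL) {
  run <- function() {
    day_s <- day_hours * 3600
    n <- if (n_bouts[1] == n_bouts[2]) n_bouts[1] else
      sample(seq(n_bouts[1], n_bouts[2]), 1)
    lo_b <- bout_minutes[1] * 60; hi_b <- bout_minutes[2] * 60
    lo_T <- max(total_hours[1] * 3600, n * lo_b)
    hi_T <- min(total_hours[2] * 3600, n * hi_b)
    if (lo_T > hi_T || hi_T >= day_s) {
      abort_input(sprintf(
        "Infeasible schedule: %d bouts of %g-%g min cannot total %g-%g h within a %g h day.",
        n, bout_minutes[1], bout_minutes[2], total_hours[1], total_hours[2], day_hours
      ))
    }
    total_lying <- stats::runif(1, lo_T, hi_T)
    lie_dur <- scale_to_sum(stats::runif(n, lo_b, hi_b), total_lying, lo_b, hi_b)
    min_stand <- standing_min_minutes * 60
    total_standing <- day_s - total_lying
    if (total_standing < (n + 1) * min_stand) {
      abort_input("Infeasible schedule: not enough standing time for the standing episodes.")
    }
    u <- stats::runif(n + 1)
    stand_dur <- min_stand + u / sum(u) * (total_standing - (n + 1) * min_stand)
    sides <- ifelse(stats::runif(n) < p_left, "left", "right")
    posture <- c(rbind(rep("standing", n), rep("lying", n)), "standing")
    side <- c(rbind(rep(NA_character_, n), sides), NA_character_)
    duration <- c(rbind(stand_dur[seq_len(n)], lie_dur), stand_dur[n + 1])
    ep <- tibble::tibble(posture = posture, side = side, duration = duration)
    if (side_switches > 0) {
      ep <- inject_side_switches(ep, side_switches, switch_seconds)
    }
    if (micro_bouts > 0) {
      ep <- inject_micro_bouts(ep, micro_bouts, micro_seconds, p_left)
    }
    ep$end_s <- cumsum(ep$duration)
    ep$start_s <- ep$end_s - ep$duration
    ep$episode <- seq_len(nrow(ep))
    ep[c("episode", "posture", "side", "start_s", "end_s", "duration")]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Rescale positive draws to a target sum while keeping each within [lo, hi]
## (water-filling; feasible iff n*lo <= target <= n*hi).
scale_to_sum <- function(d, target, lo, hi) {
  for (it in 1:50) {
    s <- sum(d)
    if (abs(s - target) < 1e-9) break
    free <- if (s > target) d > lo else d < hi
    if (!any(free)) break
    d[free] <- d[free] + (target - s) * d[free] / sum(d[free])
    d <- pmin(hi, pmax(lo, d))
  }
  d
}

inject_micro_bouts <- function(ep, k, micro_seconds, p_left) {
  for (i in seq_len(k)) {
    stand <- which(ep$posture == "standing" & ep$duration > micro_seconds + 240)
    if (!length(stand)) break
    j <- if (length(stand) == 1) stand else sample(stand, 1)
    d <- ep$duration[j]
    cut <- stats::runif(1, 120, d - micro_seconds - 120)
    side <- if (stats::runif(1) < p_left) "left" else "right"
    pieces <- tibble::tibble(
      posture = c("standing", "lying", "standing"),
      side = c(NA_character_, side, NA_character_),
      duration = c(cut, micro_seconds, d - micro_seconds - cut)
    )
    ep <- dplyr::bind_rows(ep[seq_len(j - 1), ], pieces,
                           ep[seq_len(nrow(ep)) > j, ])
  }
  ep
}

inject_side_switches <- function(ep, k, switch_seconds) {
  for (i in seq_len(k)) {
    lie <- which(ep$posture == "lying" & ep$duration > 4 * switch_seconds)
    if (!length(lie)) break
    j <- if (length(lie) == 1) lie else sample(lie, 1)
    d <- ep$duration[j]
    half <- (d - switch_seconds) / 2
    other <- if (identical(ep$side[j], "left")) "right" else "left"
    pieces <- tibble::tibble(
      posture = c("lying", "standing", "lying"),
      side = c(ep$side[j], NA_character_, other),
      duration = c(half, switch_seconds, half)
    )
    ep <- dplyr::bind_rows(ep[seq_len(j - 1), ], pieces,
                           ep[seq_len(nrow(ep)) > j, ])
  }
  ep
}

#' Sample leg-lift artifacts for a schedule
#'
#' A standing cow occasionally lifts the instrumented hind leg toward the
#' horizontal for several seconds up to half a minute or more, typically
#' during self-grooming — a classic false-lying confounder. This samples
#' non-overlapping artifact events inside standing episodes, away from
#' episode boundaries.
#'
#' @param schedule A schedule from [sample_schedule()].
#' @param n Number of artifacts to place.
#' @param duration_seconds Range of artifact durations in seconds (default
#'   `c(5, 25)`).
#' @param tilt_deg Range of leg tilt angles in degrees from vertical during
#'   the lift (default `c(60, 85)`; above 60 degrees the filtered upward
#'   component drops below the default posture threshold).
#' @param buffer_s Minimum distance from episode boundaries (default 60 s).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `start_s`, `duration`, `tilt_deg`.
#' @export
sample_leg_lifts <- function(schedule, n, duration_seconds = c(5, 25),
                             tilt_deg = c(60, 85), buffer_s = 60, seed = NULL) {
  run <- function() {
    stand <- schedule[schedule$posture == "standing", , drop = FALSE]
    stand$duration <- stand$end_s - stand$start_s
    out <- tibble::tibble(start_s = numeric(0), duration = numeric(0),
                          tilt_deg = numeric(0))
    tries <- 0
    while (nrow(out) < n && tries < 200 * n) {
      tries <- tries + 1
      d <- stats::runif(1, duration_seconds[1], duration_seconds[2])
      ok <- stand$duration > d + 2 * buffer_s
      if (!any(ok)) break
      cand <- which(ok)
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      s <- stats::runif(1, stand$start_s[j] + buffer_s,
                        stand$end_s[j] - buffer_s - d)
      if (nrow(out) == 0 ||
          all(s + d + buffer_s < out$start_s | s > out$start_s + out$duration + buffer_s)) {
        out <- dplyr::bind_rows(out, tibble::tibble(start_s = s, duration = d,
                                                    tilt_deg = stats::runif(1, tilt_deg[1], tilt_deg[2])))
      }
    }
    if (nrow(out) < n) {
      warn(sprintf("Could only place %d of %d leg-lift artifacts.", nrow(out), n))
    }
    dplyr::arrange(out, .data$start_s)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Render a schedule into an acceleration series with ground truth
#'
#' Converts a standing/lying schedule into a triaxial acceleration series the
#' way a leg-worn logger would see it. Standing places the gravity unit
#' vector on the upward axis; lying on the sensor side places it on the right
#' axis (sign depending on the mounting leg); lying on the opposite side
#' draws, once per bout, a direction from an arc between the right axis and
#' the forward axis, emulating the free hind leg being bent toward the head
#' and held there. Posture transitions are rendered as smooth rotations of
#' the gravity vector; leg-lift artifacts rotate it toward the horizontal for
#' their duration. Gaussian noise is added on top: band-limited "gait" noise
#' while standing and low-level noise while lying.
#'
#' @param schedule A tibble from [sample_schedule()] (or hand-built, with
#'   columns `posture`, `side`, `start_s`, `end_s`).
#' @param artifacts Optional tibble from [sample_leg_lifts()].
#' @param rate Sampling rate in Hz (default 1; typical loggers run 1–20 Hz).
#' @param id Cow id label.
#' @param start_time POSIXct timestamp of the first sample.
#' @param left_leg Logical: sensor on the left hind leg (default `TRUE`).
#' @param noise_standing Noise standard deviation while standing, in g
#'   (default 0.3; dominated by gait).
#' @param noise_lying Noise standard deviation while lying, in g (default
#'   0.05).
#' @param gait_band Passband in Hz for standing noise (default `c(0.5, 3)`;
#'   used only when the sampling rate resolves it, otherwise white noise).
#' @param transition_s Duration of the smooth gravity rotation at each
#'   posture transition, in seconds (default 5).
#' @param opposite_arc_deg Arc (degrees from the right-axis direction toward
#'   forward) the opposite-side lying direction is drawn from (default
#'   `c(5, 85)`).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `id`, `time`, `acc_fwd`, `acc_up`,
#'   `acc_right` plus per-sample ground truth `truth_lying` (logical) and
#'   `truth_side`.
#' @export
render_accel <- function(schedule, artifacts = NULL, rate = 1, id = "cow1",
                         start_time = as.POSIXct("2026-01-05 00:00:00", tz = "UTC"),
                         left_leg = TRUE, noise_standing = 0.3,
                         noise_lying = 0.05, gait_band = c(0.5, 3),
                         transition_s = 5, opposite_arc_deg = c(5, 85),
                         seed = NULL) {
  run <- function() {
    day_end <- max(schedule$end_s)
    n <- floor(day_end * rate)
    t_rel <- seq(0, by = 1 / rate, length.out = n)
    ep_idx <- findInterval(t_rel, schedule$start_s)
    s_right <- if (left_leg) 1 else -1

    ep_vec <- t(vapply(seq_len(nrow(schedule)), function(i) {
      episode_gravity(schedule$posture[i], schedule$side[i], left_leg,
                      opposite_arc_deg)
    }, numeric(3)))

    G <- ep_vec[ep_idx, , drop = FALSE]
    # smooth rotation into each new episode
    if (transition_s > 0 && nrow(schedule) > 1) {
      for (i in 2:nrow(schedule)) {
        tb <- schedule$start_s[i]
        ramp <- min(transition_s, (schedule$end_s[i] - tb) / 2)
        sel <- which(t_rel >= tb & t_rel < tb + ramp)
        if (length(sel)) {
          frac <- (t_rel[sel] - tb) / ramp
          G[sel, ] <- slerp_rows(ep_vec[i - 1, ], ep_vec[i, ], frac)
        }
      }
    }
    truth_lying <- schedule$posture[ep_idx] == "lying"
    truth_side <- schedule$side[ep_idx]

    if (!is.null(artifacts) && nrow(artifacts) > 0) {
      up <- c(0, 1, 0)
      for (i in seq_len(nrow(artifacts))) {
        a0 <- artifacts$start_s[i]
        a1 <- a0 + artifacts$duration[i]
        tilt <- artifacts$tilt_deg[i] * pi / 180
        tilted <- c(sin(tilt), cos(tilt), 0)
        ramp <- min(1, artifacts$duration[i] / 4)
        sel <- which(t_rel >= a0 & t_rel < a1)
        if (!length(sel)) next
        frac_in <- pmin(1, (t_rel[sel] - a0) / ramp)
        frac_out <- pmin(1, (a1 - t_rel[sel]) / ramp)
        frac <- pmin(frac_in, frac_out)
        G[sel, ] <- slerp_rows(up, tilted, frac)
      }
    }

    noise <- matrix(0, n, 3)
    if (noise_standing > 0 && any(!truth_lying)) {
      gn <- gait_noise(n, 3, rate, noise_standing, gait_band)
      noise[!truth_lying, ] <- gn[!truth_lying, ]
    }
    if (noise_lying > 0 && any(truth_lying)) {
      noise[truth_lying, ] <- stats::rnorm(sum(truth_lying) * 3, sd = noise_lying)
    }

    tibble::tibble(
      id = id,
      time = start_time + t_rel,
      acc_fwd = G[, 1] + noise[, 1],
      acc_up = G[, 2] + noise[, 2],
      acc_right = G[, 3] + noise[, 3],
      truth_lying = truth_lying,
      truth_side = truth_side
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Unit gravity vector (fwd, up, right) for one episode. Opposite-side lying
## directions are drawn here, once per bout.
episode_gravity <- function(posture, side, left_leg, opposite_arc_deg) {
  if (posture == "standing") return(c(0, 1, 0))
  s <- if (left_leg) 1 else -1
  sensor_side <- if (left_leg) "left" else "right"
  if (identical(side, sensor_side)) {
    c(0, 0, s)
  } else {
    phi <- stats::runif(1, opposite_arc_deg[1], opposite_arc_deg[2]) * pi / 180
    c(sin(phi), 0, -s * cos(phi))
  }
}

## Spherical interpolation between unit vectors a and b at fractions frac.
slerp_rows <- function(a, b, frac) {
  cosw <- sum(a * b)
  cosw <- max(-1, min(1, cosw))
  w <- acos(cosw)
  if (w < 1e-8) {
    return(matrix(rep(b, each = length(frac)), ncol = 3))
  }
  f1 <- sin((1 - frac) * w) / sin(w)
  f2 <- sin(frac * w) / sin(w)
  cbind(f1 * a[1] + f2 * b[1], f1 * a[2] + f2 * b[2], f1 * a[3] + f2 * b[3])
}

## Band-limited Gaussian noise, rescaled to the target sd after filtering.
gait_noise <- function(n, ncol, rate, sd_target, band) {
  w <- matrix(stats::rnorm(n * ncol), n, ncol)
  nyq <- rate / 2
  if (band[1] >= nyq || n < 20) {
    return(w * sd_target)
  }
  hi <- min(band[2], 0.95 * nyq)
  bf <- signal::butter(2, W = c(band[1] / nyq, hi / nyq), type = "pass")
  for (j in seq_len(ncol)) {
    v <- as.numeric(signal::filter(bf, w[, j]))
    w[, j] <- v / stats::sd(v)
  }
  w * sd_target
}

#' Simulate complete recordings for one or several cows
#'
#' Convenience wrapper chaining [sample_schedule()] and [render_accel()] over
#' `n_days` consecutive days per cow. Days are drawn independently and
#' concatenated; each day starts and ends standing.
#'
#' @param n_cows Number of cows (default 1).
#' @param n_days Days per cow (default 1).
#' @param rate Sampling rate in Hz (default 1).
#' @param seed Optional integer seed controlling everything.
#' @param left_leg Logical (default `TRUE`), passed to [render_accel()].
#' @param schedule_args List of extra arguments for [sample_schedule()].
#' @param render_args List of extra arguments for [render_accel()].
#'
#' @return A tibble stacking all cows' samples, with ground-truth columns
#'   `truth_lying` and `truth_side`.
#' @examples
#' sim <- simulate_cows(n_cows = 2, rate = 1, seed = 42)
#' dplyr::count(sim, id)
#' @export
simulate_cows <- function(n_cows = 1, n_days = 1, rate = 1, seed = NULL,
                          left_leg = TRUE, schedule_args = list(),
                          render_args = list()) {
  run <- function() {
    out <- lapply(seq_len(n_cows), function(ci) {
      days <- lapply(seq_len(n_days), function(d) {
        sch <- do.call(sample_schedule, schedule_args)
        t0 <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC") + (d - 1) * 86400
        do.call(render_accel, c(list(schedule = sch, rate = rate,
                                     id = sprintf("cow%02d", ci),
                                     start_time = t0, left_leg = left_leg),
                                render_args))
      })
      dplyr::bind_rows(days)
    })
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write synthetic fixture files in a raw logger format
#'
#' Serializes an acceleration series into one delimiter-separated file per
#' cow, exactly parseable by [parse_accel_file()] with the same
#' [accel_format()]. The body-relative axes are mapped back to sensor XYZ
#' channels with the inverse of the supplied [axis_map()], so a round trip
#' through [read_accel_files()] reproduces the series.
#'
#' @param data An acceleration table (`id`, `time`, `acc_fwd`, `acc_up`,
#'   `acc_right`; `time` must be POSIXct).
#' @param dir Output directory (created if needed).
#' @param format An [accel_format()]. Column indices must be a permutation of
#'   1–4 and the separator a single character.
#' @param map The [axis_map()] whose inverse converts body axes to channels
#'   (default identity).
#'
#' @return Character vector of the written file paths, invisibly.
#' @export
write_fixture_files <- function(data, dir, format = accel_format(),
                                map = axis_map()) {
  data <- check_accel_cols(data)
  if (!inherits(data$time, "POSIXct")) {
    abort_input("`time` must be POSIXct to write timestamped fixture files.")
  }
  idx <- c(format$col_time, format$col_x, format$col_y, format$col_z)
  if (!setequal(idx, 1:4)) {
    abort_input("Fixture writing needs column indices forming a permutation of 1..4.")
  }
  if (nchar(format$sep) != 1L) {
    abort_input("Fixture writing needs a single-character separator.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv <- invert_axis_map(map)
  body_col <- c(fwd = "acc_fwd", up = "acc_up", right = "acc_right")
  time_fmt <- sub("%OS(?![0-9])", "%OS6", format$time_format, perl = TRUE)
  paths <- vapply(unique(data$id), function(cow) {
    sub <- data[data$id == cow, , drop = FALSE]
    cols <- vector("list", 4)
    cols[[format$col_time]] <- format(sub$time, format = time_fmt, tz = "UTC")
    for (ch in c("X", "Y", "Z")) {
      v <- inv$sign[[ch]] * sub[[body_col[[inv$channel[[ch]]]]]]
      txt <- sprintf("%.9f", v)
      if (format$decimal != ".") txt <- gsub(".", format$decimal, txt, fixed = TRUE)
      cols[[format[[paste0("col_", tolower(ch))]]]] <- txt
    }
    lines <- do.call(paste, c(cols, sep = format$sep))
    header <- rep("# synthetic accelerometer fixture", format$skip)
    path <- file.path(dir, paste0(cow, ".txt"))
    writeLines(c(header, lines), path)
    path
  }, character(1))
  invisible(unname(paths))
}
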