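#' Dynamic body acceleration (DBA)
#'
#' DBA is the measured acceleration minus its static gravity component,
#' estimated per axis with the same filters (and defaults) as the posture
#' algorithm. It reflects movement of the animal rather than sensor
#' orientation.
#'
#' @param data An acceleration table (see [read_accel_table()]).
#' @inheritParams gravity_component
#'
#' @return A tibble with columns `dba_fwd`, `dba_up`, `dba_right` (g),
#'   aligned row-for-row with `data`.
#' @export
dynamic_body_acceleration <- function(data,
                                      filter_method = c("median", "butterworth"),
                                      window_size = 10, cutoff = 0.1, order = 1) {
  filter_method <- match.arg(filter_method)
  data <- check_accel_cols(data)
  out <- lapply(c(fwd = "fwd", up = "up", right = "right"), function(ax) {
    data[[paste0("acc_", ax)]] -
      gravity_component(data, axis = ax, filter_method = filter_method,
                        window_size = window_size, cutoff = cutoff, order = order)
  })
  tibble::tibble(dba_fwd = out$fwd, dba_up = out$up, dba_right = out$right)
}

#' Jerk: backward finite difference of raw acceleration
#'
#' Jerk, the time derivative of acceleration, is approximated per axis as the
#' difference to the previous sample divided by the elapsed time. Differencing
#' removes the static gravity component by construction (it does not change),
#' so jerk is computed on the raw signal. The first sample of each cow's
#' series has no predecessor and is `NA`.
#'
#' @param data An acceleration table.
#'
#' @return A tibble with columns `jerk_fwd`, `jerk_up`, `jerk_right`
#'   (g s^-1), aligned row-for-row with `data`.
#' @export
jerk <- function(data) {
  data <- check_accel_cols(data)
  n <- nrow(data)
  if (n < 2) abort_input("At least 2 samples are needed to compute jerk.")
  tt <- as.numeric(data$time)
  dt <- c(NA_real_, diff(tt))
  first <- !duplicated(data$id)
  one <- function(col) {
    d <- c(NA_real_, diff(data[[col]])) / dt
    d[first] <- NA_real_
    d
  }
  tibble::tibble(jerk_fwd = one("acc_fwd"), jerk_up = one("acc_up"),
                 jerk_right = one("acc_right"))
}

#' L1 and L2 norms of a per-sample 3-vector
#'
#' The L1 norm is the sum of absolute values over the forward, upward, and
#' right components; the L2 norm is the Euclidean magnitude. Applied to DBA
#' these are the classic ODBA and VeDBA activity proxies; applied to jerk
#' they give the corresponding jerk-based proxies. L2 is invariant under
#' rotations of the sensor frame, L1 is not.
#'
#' @param fwd,up,right Numeric vectors: vector components per sample.
#' @return Numeric vector of norms.
#' @examples
#' norm_l1(0.3, -0.4, 0)  # 0.7
#' norm_l2(0.3, -0.4, 0)  # 0.5
#' @export
norm_l1 <- function(fwd, up, right) abs(fwd) + abs(up) + abs(right)

#' @rdname norm_l1
#' @export
norm_l2 <- function(fwd, up, right) sqrt(fwd^2 + up^2 + right^2)

#' Add per-sample physical-activity proxies
#'
#' Computes the requested activity measures for every sample: L1/L2 norms of
#' the dynamic body acceleration vector (`L1DBA` aka ODBA, `L2DBA` aka VeDBA,
#' in g) and/or of the jerk vector (`L1Jerk`, `L2Jerk`, in g s^-1). By
#' default, samples inside lying bouts are adjusted to 0: lying periods are
#' considered inactive by definition. Unadjusted values during lying should
#' be interpreted with caution — the instrumented leg is physically
#' restricted when the cow lies on it, biasing the measured activity by lying
#' side.
#'
#' @param data A tibble annotated by [add_lying()] (required when `adjust =
#'   TRUE`), or a plain acceleration table when `adjust = FALSE`.
#' @param measures Character subset of `c("L1DBA", "L2DBA", "L1Jerk",
#'   "L2Jerk")`. Default `"L2DBA"`.
#' @param adjust Logical: zero out activity during lying bouts (default
#'   `TRUE`).
#' @inheritParams gravity_component
#'
#' @return The input tibble with one added column per requested measure.
#'   Jerk-based measures are `NA` at the first sample of each cow.
#' @examples
#' sim <- simulate_cows(n_days = 1, rate = 1, seed = 1)
#' sim |> add_lying() |> add_activity(measures = c("L1DBA", "L2DBA"))
#' @export
add_activity <- function(data, measures = "L2DBA", adjust = TRUE,
                         filter_method = c("median", "butterworth"),
                         window_size = 10, cutoff = 0.1, order = 1) {
  filter_method <- match.arg(filter_method)
  all_measures <- c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk")
  if (length(measures) == 0) abort_input("`measures` must not be empty.")
  bad <- setdiff(measures, all_measures)
  if (length(bad)) {
    abort_input(sprintf("Unknown measure(s): %s. Available: %s.",
                        paste(bad, collapse = ", "),
                        paste(all_measures, collapse = ", ")))
  }
  data <- check_accel_cols(data)
  if (adjust && !all(c("lying", "bout_nr") %in% names(data))) {
    abort_input("`adjust = TRUE` needs the posture annotation; run add_lying() first.")
  }
  if (!adjust) {
    inform(paste("Activity is not adjusted for lying bouts; non-zero values",
                 "during lying should be interpreted with caution."))
  }
  out <- data
  if (any(c("L1DBA", "L2DBA") %in% measures)) {
    dba <- dynamic_body_acceleration(data, filter_method = filter_method,
                                     window_size = window_size,
                                     cutoff = cutoff, order = order)
    if ("L1DBA" %in% measures) {
      out$L1DBA <- norm_l1(dba$dba_fwd, dba$dba_up, dba$dba_right)
    }
    if ("L2DBA" %in% measures) {
      out$L2DBA <- norm_l2(dba$dba_fwd, dba$dba_up, dba$dba_right)
    }
  }
  if (any(c("L1Jerk", "L2Jerk") %in% measures)) {
    jk <- jerk(data)
    if ("L1Jerk" %in% measures) {
      out$L1Jerk <- norm_l1(jk$jerk_fwd, jk$jerk_up, jk$jerk_right)
    }
    if ("L2Jerk" %in% measures) {
      out$L2Jerk <- norm_l2(jk$jerk_fwd, jk$jerk_up, jk$jerk_right)
    }
  }
  if (adjust) {
    for (m in intersect(measures, names(out))) {
      z <- out$lying & !is.na(out[[m]])
      out[[m]][z] <- 0
    }
  }
  out
}
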