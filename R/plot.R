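#' Plot the posture classification over the raw upward axis
#'
#' Shows the raw and gravity-filtered upward acceleration with the posture
#' threshold and shades detected lying bouts — the standard visual check of
#' the classification and of candidate `crit_lie` values.
#'
#' @param data A tibble annotated by [add_lying()].
#' @param id Cow to plot (default: the first).
#' @param crit_lie Threshold line to draw (default 0.5 g).
#' @inheritParams gravity_component
#'
#' @return A ggplot object.
#' @export
plot_posture <- function(data, id = NULL, crit_lie = 0.5,
                         filter_method = c("median", "butterworth"),
                         window_size = 10, cutoff = 0.1, order = 1) {
  filter_method <- match.arg(filter_method)
  data <- check_annotated(data)
  id <- id %||% data$id[1]
  sub <- data[data$id == id, , drop = FALSE]
  sub$gravity_up <- gravity_component(sub, axis = "up",
                                      filter_method = filter_method,
                                      window_size = window_size,
                                      cutoff = cutoff, order = order)
  b <- bouts(sub)
  lb <- b[b$posture == "lying", , drop = FALSE]
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$time))
  if (nrow(lb)) {
    p <- p + ggplot2::geom_rect(
      data = lb,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$acc_up), color = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gravity_up), color = "black") +
    ggplot2::geom_hline(yintercept = crit_lie, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "upward acceleration (g)",
                  title = sprintf("Posture classification, cow %s", id),
                  subtitle = "shaded: lying bouts; dashed: crit_lie") +
    ggplot2::theme_minimal()
}

#' Plot per-sample activity proxies
#'
#' @param data A tibble with activity columns from [add_activity()].
#' @param measures Which measures to plot (default: all present).
#' @param id Cow to plot (default: the first).
#'
#' @return A ggplot object.
#' @export
plot_activity <- function(data, measures = NULL, id = NULL) {
  present <- intersect(c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk"), names(data))
  if (!length(present)) abort_input("No activity columns found; run add_activity() first.")
  measures <- measures %||% present
  id <- id %||% data$id[1]
  sub <- data[data$id == id, , drop = FALSE]
  long <- tidyr::pivot_longer(sub[c("time", measures)],
                              cols = dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Physical activity, cow %s", id)) +
    ggplot2::theme_minimal()
}

#' Plot interval summaries of lying behavior
#'
#' Bar chart of lying duration per interval, filled by lying side when
#' available.
#'
#' @param summary A table from [summarize_intervals()].
#'
#' @return A ggplot object.
#' @export
plot_intervals <- function(summary) {
  need <- c("id", "interval_start", "duration_lying")
  if (!all(need %in% names(summary))) {
    abort_input("`summary` does not look like summarize_intervals() output.")
  }
  has_sides <- all(c("duration_lying_left", "duration_lying_right") %in% names(summary)) &&
    any(summary$duration_lying_left + summary$duration_lying_right > 0)
  if (has_sides) {
    long <- tidyr::pivot_longer(
      summary[c("id", "interval_start", "duration_lying_left", "duration_lying_right")],
      cols = dplyr::starts_with("duration_lying_"),
      names_to = "side", values_to = "seconds", names_prefix = "duration_lying_"
    )
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$interval_start,
                                            y = .data$seconds / 3600,
                                            fill = .data$side)) +
      ggplot2::geom_col()
  } else {
    p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$interval_start,
                                               y = .data$duration_lying / 3600)) +
      ggplot2::geom_col(fill = "steelblue")
  }
  p +
    ggplot2::facet_wrap(~id) +
    ggplot2::labs(x = NULL, y = "lying time (h)") +
    ggplot2::theme_minimal()
}
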