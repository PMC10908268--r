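#' Moving-median gravity filter
#'
#' Estimates the static (gravity) component of one acceleration channel as
#' the running median over a centered window. The window is specified in
#' seconds and converted to an odd number of samples; at the series edges the
#' window shrinks to the samples actually available, so the output always has
#' the length of the input.
#'
#' @param values Numeric vector of acceleration samples (g).
#' @param window_size Window length in seconds (default 10).
#' @param sampling_interval Sampling interval in seconds.
#'
#' @return Numeric vector of gravity estimates, same length as `values`.
#' @details The window length in samples is `round(window_size /
#'   sampling_interval)`, bumped to the next odd integer when even so the
#'   window has an unambiguous center.
#' @export
moving_median <- function(values, window_size = 10, sampling_interval = 1) {
  if (length(values) == 0) abort_input("`values` is empty.")
  if (window_size <= 0 || sampling_interval <= 0) {
    abort_input("`window_size` and `sampling_interval` must be positive.")
  }
  k <- round(window_size / sampling_interval)
  if (k < 1) {
    abort_input(sprintf(
      "Window of %g s spans less than one sample at a %g s sampling interval.",
      window_size, sampling_interval
    ))
  }
  if (k %% 2 == 0) k <- k + 1
  n <- length(values)
  if (k == 1 || n == 1) return(values)
  h <- (k - 1) / 2
  if (n >= k) {
    out <- stats::runmed(values, k, endrule = "keep")
    edge <- seq_len(h)
  } else {
    out <- values
    edge <- seq_len(n)
  }
  # asymmetric shrink: window [i-h, i+h] clipped to the series
  for (i in edge) {
    out[i] <- median(values[max(1, i - h):min(n, i + h)])
  }
  for (i in (n - rev(edge) + 1)) {
    out[i] <- median(values[max(1, i - h):min(n, i + h)])
  }
  as.numeric(out)
}

#' Zero-phase Butterworth low-pass gravity filter
#'
#' Applies a Butterworth low-pass filter forward and then backward over the
#' series, cancelling the phase shift so the gravity estimate stays aligned
#' with the raw signal. Edge transients are controlled by extending the series
#' with an odd-symmetric reflection before filtering and trimming it after.
#'
#' @param values Numeric vector of acceleration samples (g).
#' @param cutoff Cutoff frequency in Hz (default 0.1). Must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 1).
#' @param sampling_rate Sampling rate in Hz.
#'
#' @return Numeric vector, same length as `values`.
#' @details Filter coefficients come from [signal::butter()]. The extension
#'   length is `max(3 * (order + 1), ceiling(4 * sampling_rate / cutoff))`
#'   samples per end (capped at `length(values) - 1`), long enough for the
#'   zero-state transient to decay to numerical noise before the data begin.
#' @export
butter_zerophase <- function(values, cutoff = 0.1, order = 1, sampling_rate = 1) {
  if (length(values) == 0) abort_input("`values` is empty.")
  if (order < 1 || order != round(order)) abort_input("`order` must be a positive integer.")
  nyq <- sampling_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    abort_input(sprintf(
      "`cutoff` (%g Hz) must lie strictly between 0 and the Nyquist frequency (%g Hz).",
      cutoff, nyq
    ))
  }
  n <- length(values)
  if (n < 2) return(values)
  bf <- signal::butter(order, W = cutoff / nyq, type = "low")
  pad <- min(n - 1, max(3 * (order + 1), ceiling(4 * sampling_rate / cutoff)))
  left <- 2 * values[1] - values[seq(pad + 1, 2)]
  right <- 2 * values[n] - values[seq(n - 1, n - pad)]
  x <- c(left, values, right)
  y <- signal::filter(bf, x)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Gravity component of one body axis
#'
#' Dispatches to the moving-median (default) or zero-phase Butterworth filter
#' using the sampling interval inferred from the series' timestamps. This is
#' the first step of the posture algorithm and the subtraction baseline for
#' dynamic body acceleration.
#'
#' @param data An acceleration table (see [read_accel_table()]).
#' @param axis One of `"up"`, `"fwd"`, `"right"`.
#' @param filter_method `"median"` or `"butterworth"`.
#' @param window_size Median window in seconds (default 10).
#' @param cutoff Butterworth cutoff in Hz (default 0.1).
#' @param order Butterworth order (default 1).
#'
#' @return Numeric vector of gravity estimates aligned with `data`'s rows
#'   (computed per cow when an `id` column is present).
#' @export
gravity_component <- function(data, axis = c("up", "fwd", "right"),
                              filter_method = c("median", "butterworth"),
                              window_size = 10, cutoff = 0.1, order = 1) {
  axis <- match.arg(axis)
  filter_method <- match.arg(filter_method)
  col <- paste0("acc_", axis)
  if (!col %in% names(data)) abort_input(sprintf("Column `%s` not found.", col))
  run <- function(v, tt) {
    if (length(v) == 1) return(v)
    dt <- infer_sampling_interval(tt)
    switch(filter_method,
      median = moving_median(v, window_size = window_size, sampling_interval = dt),
      butterworth = butter_zerophase(v, cutoff = cutoff, order = order,
                                     sampling_rate = 1 / dt)
    )
  }
  if ("id" %in% names(data)) {
    idx <- split(seq_len(nrow(data)), data$id)
    out <- numeric(nrow(data))
    for (rows in idx) {
      out[rows] <- run(data[[col]][rows], data$time[rows])
    }
    out
  } else {
    run(data[[col]], data$time)
  }
}
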