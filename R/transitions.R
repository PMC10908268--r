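#' Extract raw-data windows around posture transitions
#'
#' Returns the annotated samples surrounding each detected posture
#' transition: `extract_liedown()` around standing-to-lying transitions,
#' `extract_standup()` around lying-to-standing. The transition time is the
#' timestamp of the first sample in the new posture (the same convention used
#' for bout boundaries), and a window spans `[time - sec_before, time +
#' sec_after]`, closed on both ends at sample resolution. Recording edges are
#' not transitions; windows running past an edge are truncated and flagged.
#'
#' Such windows are the raw material for characterizing lying-down and
#' standing-up movements, e.g. as input regions for downstream classifiers.
#'
#' @param data A tibble annotated by [add_lying()].
#' @param sec_before,sec_after Non-negative window extent in seconds before
#'   and after the transition.
#'
#' @return A tibble of samples, one block per transition, with columns
#'   `transition_id` (`"<id>#<bout_nr>"` of the new bout), `kind`
#'   (`"liedown"` or `"standup"`), `transition_time`, `truncated_start`,
#'   `truncated_end`, followed by all columns of `data`.
#' @examples
#' sim <- simulate_cows(n_days = 1, rate = 1, seed = 1)
#' lied <- add_lying(sim)
#' ld <- extract_liedown(lied, sec_before = 30, sec_after = 30)
#' @export
extract_liedown <- function(data, sec_before = 0, sec_after = 0) {
  extract_transitions(data, kind = "liedown", sec_before, sec_after)
}

#' @rdname extract_liedown
#' @export
extract_standup <- function(data, sec_before = 0, sec_after = 0) {
  extract_transitions(data, kind = "standup", sec_before, sec_after)
}

extract_transitions <- function(data, kind, sec_before, sec_after) {
  data <- check_annotated(data)
  if (sec_before < 0 || sec_after < 0) {
    abort_input("`sec_before` and `sec_after` must be >= 0.")
  }
  res <- list()
  for (cow in unique(data$id)) {
    sub <- data[data$id == cow, , drop = FALSE]
    b <- bouts(sub)
    target <- if (kind == "liedown") "lying" else "standing"
    sel <- b$posture == target & b$complete_start
    tt <- as.numeric(sub$time)
    for (i in which(sel)) {
      t0 <- as.numeric(b$start[i])
      lo <- t0 - sec_before
      hi <- t0 + sec_after
      rows <- which(tt >= lo - 1e-9 & tt <= hi + 1e-9)
      block <- sub[rows, , drop = FALSE]
      block <- tibble::add_column(
        block,
        transition_id = paste0(cow, "#", b$bout_nr[i]),
        kind = kind,
        transition_time = b$start[i],
        truncated_start = lo < tt[1] - 1e-9,
        truncated_end = hi > tt[length(tt)] + 1e-9,
        .before = 1
      )
      res[[length(res) + 1L]] <- block
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble())
  }
  dplyr::bind_rows(res)
}
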