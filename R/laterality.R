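#' Assign lying laterality (left/right side) to lying bouts
#'
#' For each lying bout, the cow's lying side is inferred from the raw
#' right-axis acceleration. When the cow lies on the side where the sensor is
#' mounted, the gravity component loads close to +1 g (left hind leg) or -1 g
#' (right hind leg) on the right axis; on the opposite side the free leg can
#' be bent toward the head, shifting gravity onto the forward axis and pulling
#' the right-axis value toward 0. The threshold `crit_left` is therefore
#' offset toward the sensor side: +0.5 g for a left-leg sensor, -0.5 g for a
#' right-leg one.
#'
#' The rule asks whether the majority of the bout's raw right-axis values lie
#' above (left side) or below (right side) the threshold, which is equivalent
#' to comparing the bout median with the threshold. One side is assigned to
#' the entire bout: a cow changes side via a short standing bout, which splits
#' the lying period in two.
#'
#' @param data A tibble annotated by [add_lying()].
#' @param left_leg Logical: is the accelerometer on the left hind leg?
#'   Required unless `crit_left` is given.
#' @param crit_left Threshold in g, in `[-1, 1]`. Defaults to `0.5` when
#'   `left_leg = TRUE` and `-0.5` when `left_leg = FALSE`.
#'
#' @return The input tibble with an added `side` column (`"left"`/`"right"`
#'   on lying samples, `NA` on standing samples).
#' @details A bout median exactly equal to `crit_left` is ambiguous; the side
#'   away from the sensor is assigned and a warning is raised.
#' @examples
#' sim <- simulate_cows(n_days = 1, rate = 1, seed = 1)
#' sim |> add_lying() |> add_side(left_leg = TRUE) |> bouts()
#' @export
add_side <- function(data, left_leg = NULL, crit_left = NULL) {
  data <- check_annotated(data)
  if (is.null(crit_left)) {
    if (is.null(left_leg)) {
      abort_input("Specify `left_leg` (TRUE/FALSE) or supply `crit_left` directly.")
    }
    crit_left <- if (isTRUE(left_leg)) 0.5 else -0.5
  }
  if (crit_left < -1 || crit_left > 1) abort_input("`crit_left` must be in [-1, 1].")
  tie_side <- if (is.null(left_leg) || isTRUE(left_leg)) "right" else "left"
  out <- data
  out$side <- NA_character_
  grp <- interaction(data$id, data$bout_nr, drop = TRUE)
  for (rows in split(seq_len(nrow(data)), grp)) {
    if (!data$lying[rows[1]]) next
    med <- median(data$acc_right[rows])
    side <- if (med > crit_left) {
      "left"
    } else if (med < crit_left) {
      "right"
    } else {
      warn(sprintf(
        "Bout median on the right axis equals crit_left (%g g); assigning side '%s'.",
        crit_left, tie_side
      ))
      tie_side
    }
    out$side[rows] <- side
  }
  out
}
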