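test_that("threshold rule: below lying, above standing, equality standing", {
  expect_false(classify_posture(0.9))
  expect_true(classify_posture(0.1))
  expect_false(classify_posture(0.5))  # standing is the complement of lying
  expect_equal(classify_posture(c(0.49, 0.51)), c(TRUE, FALSE))
})

test_that("default threshold corresponds to a 60 degree leg angle", {
  crit_lie <- formals(add_lying)$crit_lie
  expect_equal(acos(crit_lie / 1) * 180 / pi, 60)
})

test_that("segmentation run-length arithmetic on small patterns", {
  t0 <- 0:5
  b <- segment_bouts(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), t0)
  expect_equal(nrow(b), 3)
  expect_equal(b$posture, c("standing", "lying", "standing"))
  expect_equal(b$duration[2], 3)
  expect_equal(b$complete_start, c(FALSE, TRUE, TRUE))
  expect_equal(b$complete_end, c(TRUE, TRUE, FALSE))

  one <- segment_bouts(rep(FALSE, 10), 1:10)
  expect_equal(nrow(one), 1)
  expect_false(one$complete_start | one$complete_end)
})

test_that("segmentation matches a linear-scan oracle on random sequences", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(c(100, 1000, 10000), 1)
    lying <- rbinom(n, 1, 0.5) == 1
    tt <- cumsum(c(0, rep(1, n - 1)))
    got <- segment_bouts(lying, tt)
    want <- naive_segment(lying, tt)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$posture, want$posture)
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)
    expect_equal(got$row_start, want$row_start)
  }
})

test_that("minimum-duration correction removes short interior lying bouts", {
  lying <- c(rep(FALSE, 100), rep(TRUE, 20), rep(FALSE, 100))
  b <- segment_bouts(lying, seq_along(lying) - 1)
  fixed <- enforce_min_duration(b, minimum_duration_lying = 30)
  expect_equal(nrow(fixed), 1)
  expect_equal(fixed$posture, "standing")
  expect_equal(fixed$duration, 219)  # 220 samples spanning 219 s

  lying45 <- c(rep(FALSE, 100), rep(TRUE, 45), rep(FALSE, 100))
  b45 <- segment_bouts(lying45, seq_along(lying45) - 1)
  expect_equal(enforce_min_duration(b45, 30)$posture,
               c("standing", "lying", "standing"))
})

test_that("edge bouts are exempt from removal and standing pass is optional", {
  # short lying bout at the recording edge survives
  lying <- c(rep(TRUE, 10), rep(FALSE, 100), rep(TRUE, 10), rep(FALSE, 100))
  b <- segment_bouts(lying, seq_along(lying) - 1)
  fixed <- enforce_min_duration(b, 30)
  expect_equal(fixed$posture[1], "lying")       # edge bout kept
  expect_equal(sum(fixed$posture == "lying"), 1)  # interior 10 s bout removed

  # standing minimum merges a short interior standing bout into lying
  lying2 <- c(rep(FALSE, 60), rep(TRUE, 60), rep(FALSE, 5), rep(TRUE, 60),
              rep(FALSE, 60))
  b2 <- segment_bouts(lying2, seq_along(lying2) - 1)
  nopass <- enforce_min_duration(b2, 30)
  expect_equal(nrow(nopass), 5)
  pass <- enforce_min_duration(b2, 30, minimum_duration_standing = 10)
  expect_equal(pass$posture, c("standing", "lying", "standing"))
})

test_that("correction equals the relabel-and-rescan oracle on random bout lists", {
  set.seed(32)
  for (i in 1:20) {
    n <- 2000
    # random run lengths so short and long bouts both occur
    runs <- pmax(1, rgeom(200, 1 / 40))
    lying <- rep(rep(c(FALSE, TRUE), length.out = length(runs)), runs)[1:n]
    lying <- lying[!is.na(lying)]
    tt <- seq_along(lying) - 1
    got <- enforce_min_duration(segment_bouts(lying, tt), 30)
    want <- naive_min_duration(lying, tt, 30)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$posture, want$posture)
    expect_equal(as.numeric(got$start), want$start)
  }
})

test_that("add_lying recovers a clean synthetic day of >=2 min bouts", {
  sch <- sample_schedule(seed = 101)
  sim <- render_accel(sch, rate = 1, seed = 102)
  lied <- add_lying(sim)
  b <- bouts(lied)
  truth_lying <- sch[sch$posture == "lying", ]
  got_lying <- b[b$posture == "lying", ]
  expect_equal(nrow(got_lying), nrow(truth_lying))
  # boundaries within half a filter window + ramp of the truth
  t0 <- as.numeric(sim$time[1])
  tol <- 10 / 2 + 1 + 5  # window/2 + one sample + transition ramp
  expect_true(all(abs(as.numeric(got_lying$start) - t0 - truth_lying$start_s) <= tol))
  expect_true(all(abs(as.numeric(got_lying$end) - t0 - truth_lying$end_s) <= tol))
})

test_that("standing leg-lift artifacts do not create false lying bouts", {
  sch <- tibble::tibble(posture = "standing", side = NA_character_,
                        start_s = 0, end_s = 7200)
  art <- sample_leg_lifts(sch, n = 6, duration_seconds = c(5, 25), seed = 33)
  expect_equal(nrow(art), 6)
  sim <- render_accel(sch, artifacts = art, rate = 1, seed = 34)
  b <- bouts(add_lying(sim))
  expect_equal(sum(b$posture == "lying"), 0)
  # sanity: without the minimum-duration step the artifacts do look like lying
  raw <- bouts(add_lying(sim, minimum_duration_lying = 0))
  expect_gt(sum(raw$posture == "lying"), 0)
})

test_that("an 8 s micro-bout is dropped by default but found at a 5 s minimum", {
  sch <- tibble::tibble(
    posture = c("standing", "lying", "standing"),
    side = c(NA, "left", NA),
    start_s = c(0, 600, 608), end_s = c(600, 608, 1200)
  )
  sim <- render_accel(sch, rate = 1, noise_standing = 0.05, noise_lying = 0.02,
                      transition_s = 1, seed = 35)
  default_b <- bouts(add_lying(sim))
  expect_equal(sum(default_b$posture == "lying"), 0)
  sensitive_b <- bouts(add_lying(sim, minimum_duration_lying = 5))
  expect_equal(sum(sensitive_b$posture == "lying"), 1)
})

test_that("posture is exhaustive and bouts tile the recording", {
  sim <- simulate_cows(n_cows = 2, rate = 1, seed = 36,
                       schedule_args = list(day_hours = 6, n_bouts = c(2, 3),
                                            bout_minutes = c(20, 40),
                                            total_hours = c(1, 2)))
  lied <- add_lying(sim)
  expect_false(anyNA(lied$lying))
  b <- bouts(lied)
  for (cow in unique(b$id)) {
    bc <- b[b$id == cow, ]
    span <- diff(range(as.numeric(sim$time[sim$id == cow])))
    expect_equal(sum(bc$duration), span)
    expect_equal(as.numeric(bc$start[-1]), as.numeric(bc$end[-nrow(bc)]))
    expect_true(all(bc$posture[-1] != bc$posture[-nrow(bc)]))
    # no interior lying bout below the default minimum
    interior <- bc$complete_start & bc$complete_end
    expect_true(all(bc$duration[interior & bc$posture == "lying"] >= 30))
  }
})

test_that("raising the lying minimum never increases the lying-bout count", {
  sim <- simulate_cows(rate = 1, seed = 37,
                       schedule_args = list(micro_bouts = 3, side_switches = 1))
  counts <- vapply(c(0, 5, 30, 120, 600), function(m) {
    b <- bouts(add_lying(sim, minimum_duration_lying = m))
    sum(b$posture == "lying")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
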