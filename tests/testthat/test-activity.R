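static_series <- function(n = 200, up = 1) {
  tibble::tibble(
    id = "c1",
    time = as.POSIXct("2026-01-05", tz = "UTC") + seq_len(n),
    acc_fwd = 0, acc_up = up, acc_right = 0
  )
}

test_that("DBA is zero for a static series and equals raw minus gravity", {
  d <- static_series()
  dba <- dynamic_body_acceleration(d)
  expect_equal(dba$dba_fwd, rep(0, 200))
  expect_equal(dba$dba_up, rep(0, 200))
  expect_equal(dba$dba_right, rep(0, 200))

  d2 <- d
  d2$acc_up[100] <- 1.2   # single excursion, gravity estimate stays 1
  dba2 <- dynamic_body_acceleration(d2)
  expect_equal(dba2$dba_up[100], 0.2)
})

test_that("DBA recovers an injected dynamic component on a standing trace", {
  sch <- tibble::tibble(posture = "standing", side = NA_character_,
                        start_s = 0, end_s = 1800)
  sim <- render_accel(sch, rate = 10, noise_standing = 0, seed = 51)
  t <- as.numeric(sim$time) - as.numeric(sim$time[1])
  injected <- 0.2 * sin(2 * pi * 1.5 * t)   # 1.5 Hz, well above the filters
  sim$acc_fwd <- sim$acc_fwd + injected
  dba <- dynamic_body_acceleration(sim)
  mid <- seq(100, nrow(sim) - 100)
  rmse <- sqrt(mean((dba$dba_fwd[mid] - injected[mid])^2))
  expect_lt(rmse, 0.01)
})

test_that("jerk is the backward difference over the actual time step", {
  d <- static_series(100)
  j <- jerk(d)
  expect_true(is.na(j$jerk_up[1]))
  expect_equal(j$jerk_up[-1], rep(0, 99))

  # 1.0 -> 0.5 g across one 0.05 s interval: -10 g/s
  d2 <- tibble::tibble(
    id = "c1",
    time = as.POSIXct("2026-01-05", tz = "UTC") + seq(0, by = 0.05, length.out = 10),
    acc_fwd = 0, acc_up = c(rep(1, 5), rep(0.5, 5)), acc_right = 0
  )
  expect_equal(jerk(d2)$jerk_up[6], -10, tolerance = 1e-4)

  # linear ramp of slope k is exact
  k <- 0.3
  d3 <- static_series(50)
  d3$acc_fwd <- k * seq_len(50)
  expect_equal(jerk(d3)$jerk_fwd[-1], rep(k, 49))

  # first sample of every cow is NA, not just the first row
  d4 <- dplyr::bind_rows(d, dplyr::mutate(d, id = "c2"))
  j4 <- jerk(d4)
  expect_equal(which(is.na(j4$jerk_up)), c(1L, 101L))
})

test_that("norms satisfy the textbook identities and inequalities", {
  expect_equal(norm_l1(1, 0, 0), 1)
  expect_equal(norm_l2(1, 0, 0), 1)
  expect_equal(norm_l1(0.3, -0.4, 0), 0.7)
  expect_equal(norm_l2(0.3, -0.4, 0), 0.5)
  set.seed(52)
  v <- matrix(rnorm(300 * 3, sd = 2), ncol = 3)
  l1 <- norm_l1(v[, 1], v[, 2], v[, 3])
  l2 <- norm_l2(v[, 1], v[, 2], v[, 3])
  expect_true(all(l2 <= l1 + 1e-12))
  expect_true(all(l1 <= sqrt(3) * l2 + 1e-12))
})

test_that("add_activity computes requested measures and validates input", {
  sim <- simulate_cows(rate = 1, seed = 53,
                       schedule_args = list(day_hours = 4, n_bouts = c(2, 2),
                                            bout_minutes = c(20, 30),
                                            total_hours = c(0.7, 1)))
  expect_error(add_activity(sim, measures = character(0)), "empty")
  expect_error(add_activity(sim, measures = "ODBA"), "Unknown measure")
  expect_error(add_activity(sim, adjust = TRUE), "add_lying")

  lied <- add_lying(sim)
  out <- add_activity(lied, measures = c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk"))
  expect_true(all(c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk") %in% names(out)))
  ok <- !is.na(out$L1Jerk)
  expect_true(all(out$L1DBA >= 0) && all(out$L1Jerk[ok] >= 0))
})

test_that("lying adjustment zeroes lying samples and leaves the rest unchanged", {
  sim <- simulate_cows(rate = 1, seed = 54,
                       schedule_args = list(day_hours = 4, n_bouts = c(2, 2),
                                            bout_minutes = c(20, 30),
                                            total_hours = c(0.7, 1)))
  lied <- add_lying(sim)
  adj <- add_activity(lied, measures = c("L2DBA", "L2Jerk"))
  raw <- suppressMessages(
    add_activity(lied, measures = c("L2DBA", "L2Jerk"), adjust = FALSE)
  )
  lying <- adj$lying & !is.na(adj$L2Jerk)
  expect_true(all(adj$L2DBA[adj$lying] == 0))
  expect_true(all(adj$L2Jerk[lying] == 0))
  expect_equal(adj$L2DBA[!adj$lying], raw$L2DBA[!adj$lying])
  expect_equal(adj$L2Jerk[!adj$lying], raw$L2Jerk[!adj$lying])
  # unadjusted noise jerk during lying is nonzero
  expect_gt(mean(raw$L2Jerk[lying]), 0)
})

test_that("L2 activity proxies are invariant under sensor rotation, L1 is not", {
  sch <- tibble::tibble(
    posture = c("standing", "lying", "standing"),
    side = c(NA, "left", NA),
    start_s = c(0, 900, 2700), end_s = c(900, 2700, 3600)
  )
  sim <- render_accel(sch, rate = 2, seed = 55)
  set.seed(56)
  for (i in 1:3) {
    R <- random_rotation()
    rot <- rotate_series(sim, R)
    # linear (Butterworth) gravity filter commutes with the rotation
    a <- dynamic_body_acceleration(sim, filter_method = "butterworth")
    b <- dynamic_body_acceleration(rot, filter_method = "butterworth")
    l2a <- norm_l2(a$dba_fwd, a$dba_up, a$dba_right)
    l2b <- norm_l2(b$dba_fwd, b$dba_up, b$dba_right)
    expect_lt(max(abs(l2a - l2b)), 1e-9)
    ja <- jerk(sim); jb <- jerk(rot)
    l2ja <- norm_l2(ja$jerk_fwd, ja$jerk_up, ja$jerk_right)
    l2jb <- norm_l2(jb$jerk_fwd, jb$jerk_up, jb$jerk_right)
    expect_lt(max(abs(l2ja - l2jb), na.rm = TRUE), 1e-9)
    l1a <- norm_l1(a$dba_fwd, a$dba_up, a$dba_right)
    l1b <- norm_l1(b$dba_fwd, b$dba_up, b$dba_right)
    expect_gt(max(abs(l1a - l1b)), 1e-6)
  }
})

test_that("L1 and L2 proxies are highly correlated on mixed behavior", {
  sch <- tibble::tibble(
    posture = c("standing", "lying", "standing", "lying", "standing"),
    side = c(NA, "left", NA, "right", NA),
    start_s = c(0, 600, 1500, 2100, 3000),
    end_s = c(600, 1500, 2100, 3000, 3600)
  )
  sim <- render_accel(sch, rate = 5, seed = 57)
  lied <- add_lying(sim)
  act <- add_activity(lied, measures = c("L1DBA", "L2DBA", "L1Jerk", "L2Jerk"))
  ok <- !act$lying & !is.na(act$L1Jerk)
  expect_gt(cor(act$L1DBA[ok], act$L2DBA[ok]), 0.9)
  expect_gt(cor(act$L1Jerk[ok], act$L2Jerk[ok]), 0.9)
})
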