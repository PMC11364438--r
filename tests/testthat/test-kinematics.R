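test_that("speed is displacement times frame rate", {
  # stationary
  tr0 <- traj_from_steps(rep(0, 10), rep(0, 10))
  expect_equal(compute_kinematics(tr0)$speed, rep(0, 10))
  # 0.1 mm per frame at 60 fps = 6 mm/s
  tr1 <- traj_from_steps(rep(0, 10), rep(0.1, 10))
  expect_equal(compute_kinematics(tr1)$speed, rep(6, 10))
  # 3-4-5 triangle: 0.5 mm in one frame = 30 mm/s
  tr2 <- traj_from_steps(0.3, 0.4)
  expect_equal(compute_kinematics(tr2)$speed, 30)
  expect_error(compute_kinematics(
    trajectory_set(matrix(1, 2, 1), matrix(1, 2, 1))), "2 frames")
})

test_that("heading uses 0 = up, +90 = right, undefined below min_disp", {
  k_up <- compute_kinematics(traj_from_steps(0, 0.1))
  expect_equal(k_up$heading, 0)
  k_right <- compute_kinematics(traj_from_steps(0.1, 0))
  expect_equal(k_right$heading, 90)
  k_left <- compute_kinematics(traj_from_steps(-0.1, 0))
  expect_equal(k_left$heading, -90)
  k_down <- compute_kinematics(traj_from_steps(0, -0.1))
  expect_equal(k_down$heading, 180) # wrapped into (-180, 180]
  k_small <- compute_kinematics(traj_from_steps(0.001, 0))
  expect_true(is.na(k_small$heading))
  expect_equal(k_small$speed, 0.001 * 60)
})

test_that("speed is translation invariant, heading is speed-scale invariant", {
  set.seed(21)
  dx <- rnorm(50, 0, 0.2); dy <- rnorm(50, 0.2, 0.2)
  t1 <- traj_from_steps(dx, dy, x0 = 100, y0 = 100)
  t2 <- traj_from_steps(dx, dy, x0 = 400, y0 = 700)
  expect_equal(compute_kinematics(t1)$speed, compute_kinematics(t2)$speed)
  t3 <- traj_from_steps(3 * dx, 3 * dy)
  expect_equal(compute_kinematics(t1)$heading, compute_kinematics(t3)$heading)
})

test_that("abnormal fraction is 0 for straight-up flight, 1 outside the cone", {
  up <- traj_from_steps(rep(0, 300), rep(0.1, 300))
  r0 <- abnormal_direction_fraction(compute_kinematics(up))
  expect_equal(r0$accumulated, 0)
  expect_equal(unname(r0$per_second), rep(0, 3))
  diag45 <- traj_from_steps(rep(0.1, 300), rep(0.1, 300))
  expect_equal(abnormal_direction_fraction(compute_kinematics(diag45))$accumulated, 1)
})

test_that("simulator with zero heading dispersion has zero abnormal fraction", {
  tr <- simulate_trial(det_params(mean_speed = 5), n_flies = 8, seed = 6)
  kin <- compute_kinematics(tr)
  expect_equal(abnormal_direction_fraction(kin)$accumulated, 0)
})

test_that("uniform headings give abnormal fraction 1 - 60/360", {
  set.seed(77)
  theta <- runif(5000, -180, 180) * pi / 180
  tr <- traj_from_steps(0.1 * sin(theta), 0.1 * cos(theta),
                        x0 = 500, y0 = 500)
  kin <- compute_kinematics(tr)
  frac <- abnormal_direction_fraction(kin, window = 5000 / 60)$accumulated
  expect_equal(frac, 5 / 6, tolerance = 0.03)
})

test_that("fraction is monotone nonincreasing in the normal-range half-width", {
  set.seed(13)
  theta <- runif(2000, -180, 180) * pi / 180
  tr <- traj_from_steps(0.1 * sin(theta), 0.1 * cos(theta), x0 = 500, y0 = 500)
  kin <- compute_kinematics(tr)
  widths <- c(10, 30, 60, 90, 150)
  fr <- vapply(widths, function(w) {
    abnormal_direction_fraction(kin, window = 40,
                                normal_range = c(-w, w))$accumulated
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("mean estimated speed recovers the preset within 5%", {
  p <- default_params("male_sham")
  trials <- simulate_trials(p, n_trials = 8, n_flies = 15, seed = 31)
  sp <- unlist(lapply(trials, function(tr) {
    k <- compute_kinematics(tr)
    # restrict to moving frames before flies reach the top
    k$speed[k$time_s <= 3 & k$speed > 1]
  }))
  expect_equal(mean(sp), p$mean_speed, tolerance = 0.05)
})

test_that("histograms normalize to 1 and align bins to the +/-30 deg edges", {
  v <- traj_from_steps(rep(0, 99), rep(0.21, 99)) # 12.6 mm/s, off bin edges
  kin <- compute_kinematics(v)
  sh <- speed_histogram(kin, bin_width = 2)
  expect_equal(sum(sh$frequency), 1)
  expect_equal(sh$frequency[sh$lower <= 12.6 & sh$upper > 12.6], 1)

  set.seed(3)
  theta <- runif(1000, -180, 180) * pi / 180
  tr <- traj_from_steps(0.2 * sin(theta), 0.2 * cos(theta), x0 = 500, y0 = 500)
  kk <- compute_kinematics(tr)
  ah <- angular_histogram(kk, bin_width = 15, window = 20)
  expect_equal(sum(ah$frequency), 1)
  expect_true(30 %in% ah$lower && -30 %in% ah$upper)
  expect_error(angular_histogram(kk, bin_width = 20), "bin_width")

  lr <- traj_from_steps(c(0.1, -0.1, 0.1, -0.1), rep(0, 4))
  ahl <- angular_histogram(compute_kinematics(lr), bin_width = 15)
  expect_equal(sum(ahl$frequency[ahl$mid > 0]), 0.5)
  expect_equal(sum(ahl$frequency[ahl$mid < 0]), 0.5)
})

test_that("empty windows are flagged", {
  still <- traj_from_steps(rep(0, 10), rep(0, 10))
  kin <- compute_kinematics(still)
  expect_error(abnormal_direction_fraction(kin), "no defined-heading")
  h <- angular_histogram(kin)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "n"), 0L)
})
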