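test_that("velocity model obeys its limits and derivative relation", {
  expect_equal(model_velocity(0, v_f = 12.34, tau = 1.27), 0)
  expect_equal(model_velocity(1.27, v_f = 12.34, tau = 1.27),
               12.34 * (1 - exp(-1)))
  # approaches the peak velocity
  expect_lt(abs(model_velocity(9.43, v_f = 12.34, tau = 1.27) - 12.34) /
              12.34, 0.001)
  # acceleration is the time derivative of velocity (central differences)
  h <- 1e-4
  for (t in c(0.5, 1, 2.7, 6)) {
    num <- (model_velocity(t + h, 12.34, 1.27) -
            model_velocity(t - h, 12.34, 1.27)) / (2 * h)
    expect_equal(model_acceleration(t, 12.34, 1.27), num, tolerance = 1e-6)
  }
  expect_equal(model_acceleration(0, 12.34, 1.27), 12.34 / 1.27)
  expect_lt(model_acceleration(60, 12.34, 1.27), 1e-10)
  expect_error(model_velocity(-1, 12.34, 1.27), "non-negative")
})

test_that("split tables validate their invariants", {
  expect_error(split_table(c(10, 20), c(2, 3)), "at least 3")
  expect_error(split_table(c(10, 20, 15), c(2, 3, 4)), "increasing")
  expect_error(split_table(c(10, 20, 30), c(2, 3, 2.5)), "increasing")
  expect_error(split_table(c(10, 20, 30), c(0.1, 3, 4),
                           reaction_time = 0.15), "exceed the reaction")
  expect_error(split_table(c(10, 20, 30), c(2, 3, 4),
                           total_distance = 40), "last distance mark")
  st <- split_table(c(10, 20, 30), c(2, 3, 4))
  expect_s3_class(st, "split_table")
  expect_equal(st$finish_time, 4)
})

test_that("noiseless midpoint-consistent splits recover the generating parameters", {
  spec <- fixture_spec(tau = 1.5, v_f = 10, total_distance = 100,
                       finish_time = NULL)
  st <- make_split_table(spec, times = "midpoint_consistent")
  fit <- fit_acceleration(st)
  expect_equal(fit$tau, 1.5, tolerance = 1e-6)
  expect_equal(fit$v_f, 10, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-7)
})

test_that("path-timed pure-acceleration splits recover parameters closely", {
  spec <- fixture_spec(tau = 1.27, v_f = 12.34, total_distance = 100,
                       finish_time = NULL)
  fit <- fit_acceleration(make_split_table(spec))
  # chord-average velocities differ from midpoint values over wide
  # early intervals, biasing the time constant by several percent
  expect_lt(abs(fit$tau - 1.27), 0.12)
  expect_equal(fit$v_f, 12.34, tolerance = 0.01)
})

test_that("noisy split fitting stays near the generating time constant", {
  taus <- vapply(1:50, function(s) {
    spec <- fixture_spec(tau = 1.34, v_f = 10.58, total_distance = 100,
                         finish_time = 11.2, noise_sd = 0.1, seed = s)
    fit_acceleration(make_split_table(spec))$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 1.34), 0.1)
})

test_that("peak-velocity adjustment never lowers the fitted value", {
  st <- berlin_splits()
  fit <- fit_acceleration(st)
  iv <- split_intervals(st)

  low <- fit
  low$v_f <- 11.9
  expect_equal(adjust_peak_velocity(low, st)$v_f, max(iv$v_avg))

  high <- fit
  high$v_f <- 12.9
  expect_equal(adjust_peak_velocity(high, st)$v_f, 12.9)

  # measured instantaneous maximum takes precedence when present
  st$max_velocity <- 12.42
  low$v_f <- 11.9
  expect_equal(adjust_peak_velocity(low, st)$v_f, 12.42)
  expect_equal(adjust_peak_velocity(low, st)$tau, low$tau)
})

test_that("velocity profiles are continuous with a linear deceleration tail", {
  st <- berlin_splits()
  fit <- adjust_peak_velocity(fit_acceleration(st), st)
  pr <- build_velocity_profile(fit, st)
  # continuity at the phase boundary
  i_peak <- max(which(pr$time <= pr$t_peak + 1e-12))
  expect_lt(abs(pr$velocity[i_peak] -
                model_velocity(pr$time[i_peak], fit = fit)), 1e-9)
  # linear, non-increasing deceleration segment
  post <- pr$time > pr$t_peak
  expect_true(all(diff(pr$velocity[post]) <= 1e-12))
  accel_post <- pr$acceleration[post]
  expect_lt(max(accel_post) - min(accel_post), 1e-12)
  expect_true(all(pr$velocity >= 0))
  # analytic acceleration on the rise phase
  pre <- pr$time <= pr$t_peak
  expect_equal(pr$acceleration[pre],
               model_acceleration(pr$time[pre], fit = fit),
               tolerance = 1e-12)
})

test_that("profile distance integrates to the closed form", {
  # pure acceleration: distance = v_f (T - tau (1 - exp(-T/tau)))
  pr <- sprint_velocity_profile(12.34, 1.27, duration = 9.43,
                                distance = NULL, dt = 0.01)
  closed <- 12.34 * (9.43 - 1.27 * (1 - exp(-9.43 / 1.27)))
  expect_equal(integrate_distance(pr), closed, tolerance = 1e-4)
  # near-instant rise approximates a constant-velocity run (the single
  # rest-to-speed step costs half a grid cell of distance)
  flat <- sprint_velocity_profile(10, 1e-6, duration = 10, distance = NULL)
  expect_equal(integrate_distance(flat), 100, tolerance = 1e-3)
})

test_that("full-race profiles reproduce their race distance", {
  for (event in c("100", "200", "400")) {
    pr <- berlin_profile("male", event)
    expect_equal(integrate_distance(pr), as.numeric(event),
                 tolerance = 1e-3)
  }
  # women's 100 m parameters cannot cover the full line in the race
  # time; the profile undershoots (as the modelled race does)
  prw <- berlin_profile("female", "100")
  expect_lt(integrate_distance(prw), 100)
  expect_gt(integrate_distance(prw), 95)
  # degenerate deceleration: v_final equals peak velocity
  pr <- sprint_velocity_profile(10, 1.3, duration = 12,
                                distance = NULL)
  expect_equal(pr$v_final, model_velocity(12, 10, 1.3))
})

test_that("split table CSV round trips", {
  st <- berlin_splits()
  f <- tempfile(fileext = ".csv")
  write_split_table(st, f)
  st2 <- read_split_table(f, reaction_time = st$reaction_time)
  expect_equal(st2$distance_marks, st$distance_marks)
  expect_equal(st2$cumulative_times, st$cumulative_times)
  unlink(f)
})
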