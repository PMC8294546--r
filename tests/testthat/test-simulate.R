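test_that("footfall schedule is an exact direct construction with zero jitter", {
  p <- gait_params(stride_duration = 1, duty_factor = c(LF = .66, RF = .66, LH = .66, RH = .66),
                   phase_offset = c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75),
                   n_strides = 3, timing_jitter_sd = 0)
  ff <- simulate_footfalls(p)
  expect_equal(ff$LH$claw_on, c(0, 1, 2))
  expect_equal(ff$LH$claw_off, c(0.66, 1.66, 2.66))
  expect_equal(ff$RF$claw_on, c(0.75, 1.75, 2.75))
  # stance/stride ratio equals the programmed duty factor exactly
  for (l in c("LF", "RF", "LH", "RH"))
    expect_equal(ff[[l]]$claw_off - ff[[l]]$claw_on, rep(0.66, 3))
})

test_that("quarter-offset walk alternates tripedal and bipedal support", {
  p <- gait_params(stride_duration = 1,
                   duty_factor = c(LF = .68, RF = .69, LH = .64, RH = .64),
                   n_strides = 6, timing_jitter_sd = 0)
  ff <- simulate_footfalls(p)
  st <- segment_strides(ff)
  # interval-intersection oracle: count limbs in stance at elementary intervals
  scf <- cowgait:::support_count_fun(ff)
  # interior stride, sweep its event boundaries
  i <- 3
  b <- sort(unlist(lapply(ff, function(e) c(e$claw_on, e$claw_off))))
  b <- c(st$start[i], b[b > st$start[i] & b < st$end[i]], st$end[i])
  counts <- unname(scf((b[-1] + b[-length(b)]) / 2))
  expect_equal(counts, c(3, 2, 3, 2, 3, 2, 3, 2))
})

test_that("destructive jitter is rejected after bounded retries", {
  p <- gait_params(stride_duration = 1, n_strides = 4, timing_jitter_sd = 0.5)
  expect_error(simulate_footfalls(p, seed = 1), "retries")
})

test_that("parameter validation rejects out-of-range gait parameters", {
  expect_error(gait_params(duty_factor = c(LF = 1.1, RF = .6, LH = .6, RH = .6)), "duty")
  expect_error(gait_params(phase_offset = c(LF = .25, RF = .75, LH = .1, RH = .5)), "LH")
  expect_error(gait_params(retraction_max = c(LF = 5, RF = -46, LH = -29, RH = -30)),
               "retraction")
  expect_error(gait_params(protraction_max = c(LF = -2, RF = 26, LH = 24, RH = 23)),
               "protraction")
})

test_that("limb angle trajectory spans the programmed range and integrates back", {
  p <- gait_params(n_strides = 8, timing_jitter_sd = 0,
                   protraction_max = c(LF = 25, RF = 25, LH = 25, RH = 25),
                   retraction_max = c(LF = -45, RF = -45, LH = -45, RH = -45))
  sim <- simulate_limb_streams(p, quiet_noise(3))
  for (l in c("LF", "LH")) {
    a <- sim$truth$angle[[l]]
    expect_gte(diff(range(a)), 70 - 0.01)  # sampled extrema, grid resolution
    expect_equal(max(a), 25, tolerance = 1e-3)
    expect_equal(min(a), -45, tolerance = 1e-3)
    # numerical integration oracle: trapezoid over the emitted gyro channel
    gy <- sim$streams[[l]]$gyro[, 2]
    rate <- sim$streams[[l]]$rate
    th <- cumsum(c(0, (gy[-1] + gy[-length(gy)]) / 2)) / rate
    expect_lt(max(abs(th - a)), 0.1)
  }
})

test_that("limb angle is zero at every stance midpoint", {
  sim <- default_trial_quiet()
  for (l in c("LF", "RH")) {
    e <- sim$truth$events[[l]]
    mids <- (e$claw_on + e$claw_off) / 2
    idx <- round(mids * 200) + 1
    idx <- idx[idx <= length(sim$truth$angle[[l]])]
    expect_lt(max(abs(sim$truth$angle[[l]][idx])), 0.6)
  }
})

test_that("upper-body harmonics peak at the programmed stride phases", {
  p <- gait_params(n_strides = 6, timing_jitter_sd = 0)
  # pure second harmonic at the sacrum default phase -> peaks at 25% and 75%
  ub <- upper_body_params(list(sacrum = list(h1 = 0, h2 = 0.025)))
  sim <- simulate_upper_body_streams(p, ub, quiet_noise(2), locations = "sacrum")
  z <- sim$truth$vdisp$sacrum
  tt <- sim$truth$time
  s0 <- sim$truth$events$LH$claw_on[4]
  T <- diff(sim$truth$events$LH$claw_on[4:5])
  ph <- (tt - s0) / T
  stride <- which(ph >= 0 & ph < 1)
  pk <- ph[stride][which.max(z[stride])]
  expect_equal(pk, 0.25, tolerance = 0.01)
  trough <- ph[stride][which.min(z[stride])]
  expect_true(abs(trough - 0) < 0.01 || abs(trough - 0.5) < 0.01)
})

test_that("tuber coxae first peak is strictly higher than the second", {
  p <- gait_params(n_strides = 6, timing_jitter_sd = 0)
  ub <- upper_body_params(list(LTC = list(h1 = 0.03, h2 = 0.02)))
  sim <- simulate_upper_body_streams(p, ub, quiet_noise(2), locations = "LTC")
  z <- sim$truth$vdisp$LTC
  tt <- sim$truth$time
  s0 <- sim$truth$events$LH$claw_on[4]
  T <- diff(sim$truth$events$LH$claw_on[4:5])
  ph <- (tt - s0) / T
  p1 <- max(z[ph >= 0.1 & ph < 0.4])
  p2 <- max(z[ph >= 0.6 & ph < 0.9])
  expect_gt(p1, p2)
  # analytic oracle: evaluate the two-harmonic sum at its candidate peaks
  f <- function(p) 0.03 * cos(2 * pi * (p - 0.25)) + 0.02 * cos(4 * pi * (p - 0.25))
  expect_equal(p1, max(f(seq(0.1, 0.4, by = 1e-4))), tolerance = 1e-3)
})

test_that("zero amplitudes give a constant-gravity accelerometer", {
  p <- gait_params(n_strides = 4, timing_jitter_sd = 0)
  ub <- upper_body_params(lapply(
    stats::setNames(nm = c("sacrum", "withers", "back", "LTC", "RTC", "head", "collar")),
    function(l) list(h1 = 0, h2 = 0, wander_sd = 0)))
  sim <- simulate_upper_body_streams(p, ub, quiet_noise(2), locations = "sacrum")
  expect_equal(max(abs(sim$streams$sacrum$accel[, 3] - 9.80665)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sim$streams$sacrum$accel[, 1])), 0, tolerance = 1e-9)
})

test_that("emitted vertical acceleration is the second derivative of true displacement", {
  sim <- default_trial_quiet()
  for (loc in c("sacrum", "withers", "head")) {
    z <- sim$truth$vdisp[[loc]]
    az <- sim$trial$streams[[loc]]$accel[, 3] - 9.80665
    d2 <- diff(z, differences = 2) * 200^2
    # away from the piecewise-phase kinks the identity holds to O(dt^2)
    err <- abs(az[2:(length(az) - 1)] - d2)
    expect_lt(stats::quantile(err, 0.95), 0.05)
    expect_lt(max(err), 2)
  }
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_trial(gait_params(n_strides = 4), noise = noise_params(seed = 9))
  b <- simulate_trial(gait_params(n_strides = 4), noise = noise_params(seed = 9))
  expect_identical(a$trial$streams$LF$accel, b$trial$streams$LF$accel)
  expect_identical(a$truth$events, b$truth$events)
})
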