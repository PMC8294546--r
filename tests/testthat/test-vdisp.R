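sine_stream <- function(A = 0.025, f = 1.5, rate = 200, n_cycles = 8,
                        calib_s = 5, g = 9.80665) {
  t_end <- calib_s + n_cycles / f
  t <- seq(0, t_end, by = 1 / rate)
  a <- ifelse(t >= calib_s, -A * (2 * pi * f)^2 * sin(2 * pi * f * (t - calib_s)), 0)
  list(stream = sensor_stream("sacrum", rate, t, cbind(0, 0, a + g),
                              matrix(0, length(t), 3)),
       z = ifelse(t >= calib_s, A * sin(2 * pi * f * (t - calib_s)), 0),
       t = t)
}

cycle_strides <- function(f = 1.5, n_cycles = 8, calib_s = 5) {
  on <- calib_s + (0:(n_cycles - 1)) / f
  data.frame(stride_id = seq_len(n_cycles - 1), start = on[-n_cycles],
             end = on[-1], included = TRUE, exclusion_reason = "")
}

test_that("a known sinusoid is recovered within 5% amplitude", {
  sm <- sine_stream()
  st <- cycle_strides()
  d <- vertical_displacement(sm$stream, st, load_config(), c(0, 5))
  sel <- !is.na(d)
  expect_equal(max(d[sel]), 0.025, tolerance = 0.05)
  expect_equal(diff(range(d[sel])), 0.05, tolerance = 0.05)
  expect_gt(cor(d[sel], sm$z[sel]), 0.999)
})

test_that("zero acceleration gives identically zero displacement", {
  sm <- sine_stream(A = 0)
  d <- vertical_displacement(sm$stream, cycle_strides(), load_config(), c(0, 5))
  expect_equal(max(abs(d[!is.na(d)])), 0, tolerance = 1e-9)
})

test_that("out-of-range stride durations are skipped with a warning", {
  sm <- sine_stream()
  st <- cycle_strides()
  st$end[2] <- st$start[2] + 0.2   # 0.2 s < 0.3 s minimum
  expect_warning(d <- vertical_displacement(sm$stream, st, load_config(), c(0, 5)),
                 "skipped")
  sel2 <- sm$t >= st$start[2] & sm$t < st$end[2]
  expect_true(all(is.na(d[sel2])))
})

test_that("recovered sacrum displacement matches simulator truth per stride", {
  sim <- default_trial_quiet()
  cfg <- load_config()
  ev <- detected_events(sim)
  st <- regularity_screen(segment_strides(ev), ev, cfg)
  tt <- sim$trial$streams$sacrum$time
  d <- vertical_displacement(sim$trial$streams$sacrum, st, cfg, c(0, 5))
  cors <- vapply(which(st$included)[-1], function(i) {
    sel <- which(tt >= st$start[i] & tt < st$end[i])
    if (anyNA(d[sel])) return(NA_real_)
    cor(d[sel], sim$truth$vdisp$sacrum[sel])
  }, numeric(1))
  # first stride carries the stand-to-walk ramp; steady-state strides only
  expect_gt(min(cors, na.rm = TRUE), 0.99)
})

test_that("amplitude linearity: doubling the input doubles the recovery", {
  p <- gait_params(n_strides = 8, timing_jitter_sd = 0)
  ptp <- vapply(c(1, 2), function(k) {
    ub <- upper_body_params(list(sacrum = list(h1 = 0, h2 = 0.02 * k)))
    sim <- simulate_upper_body_streams(p, ub, quiet_noise(4), locations = "sacrum")
    lh <- sim$truth$events$LH$claw_on
    st <- data.frame(stride_id = seq_len(length(lh) - 1), start = lh[-length(lh)],
                     end = lh[-1], included = TRUE, exclusion_reason = "")
    d <- vertical_displacement(sim$streams$sacrum, st, load_config(), c(0, 5))
    sel <- sim$streams$sacrum$time >= lh[3] & sim$streams$sacrum$time < lh[6]
    diff(range(d[sel]))
  }, numeric(1))
  expect_equal(ptp[2] / ptp[1], 2, tolerance = 0.02)
})

test_that("stride cutting yields zero-mean 100-sample curves with padding blocks", {
  sm <- sine_stream()
  st <- cycle_strides()
  cfg <- load_config()
  d <- vertical_displacement(sm$stream, st, cfg, c(0, 5))
  cs <- cut_and_normalize(d, sm$t, st, cfg)
  expect_equal(ncol(cs$curves), 100)
  expect_equal(nrow(cs$curves), sum(st$included))
  expect_lt(max(abs(rowMeans(cs$curves))), 1e-6)
  expect_equal(ncol(cs$pad_pre), 10)
  expect_equal(ncol(cs$pad_post), 10)
})

test_that("resampling is exact on degree-1 signals and length-stable", {
  t <- seq(0, 1, by = 1 / 200)
  ramp <- 3 * t - 1
  out <- resample_curve(t, ramp, 0, 1, 100)
  expect_equal(out, 3 * seq(0, 1, length.out = 100) - 1, tolerance = 1e-12)
  # two strides of different raw lengths cut from one sinusoid agree
  f <- 1.25
  tt <- seq(0, 10, by = 1 / 200)
  z <- sin(2 * pi * f * tt)
  c1 <- resample_curve(tt, z, 1 / f, 2 / f, 100)
  c2 <- resample_curve(tt, z, 3 / f, 4 / f, 100)
  expect_equal(c1, c2, tolerance = 1e-3)
})

test_that("recovered sacrum peak locations stay within 2 samples at default noise", {
  sim <- default_trial_noisy()
  cfg <- load_config()
  ev <- detected_events(sim)
  st <- regularity_screen(segment_strides(ev), ev, cfg)
  tt <- sim$trial$streams$sacrum$time
  d <- vertical_displacement(sim$trial$streams$sacrum, st, cfg, c(0, 5))
  mm <- median_mad_curves(cut_and_normalize(d, tt, st, cfg))
  pk1 <- which.max(mm$median_curve[1:50])
  pk2 <- 50 + which.max(mm$median_curve[51:100])
  expect_lt(abs(pk1 - 25.75), 2.5)   # peak at 25% of stride ~ sample 25.75
  expect_lt(abs(pk2 - 75.25), 2.5)
})
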