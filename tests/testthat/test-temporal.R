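quarter_walk_events <- function(T = 1, n = 8,
                                duty = c(LF = .68, RF = .69, LH = .64, RH = .64),
                                jitter = 0, seed = 1) {
  p <- gait_params(stride_duration = T, duty_factor = duty, n_strides = n,
                   timing_jitter_sd = jitter)
  simulate_footfalls(p, seed = seed)
}

test_that("stance and stride durations follow the event arithmetic", {
  ev <- list(LH = list(claw_on = c(1.0, 2.34), claw_off = c(1.86, 3.2)))
  st <- segment_strides(ev)
  rec <- stance_stride_durations(ev, st)
  expect_equal(rec$duration[rec$parameter == "stride"], 1.34)
  expect_equal(rec$duration[rec$parameter == "stance LH"], 0.86)
  rec <- speed_normalize(rec, st)
  expect_equal(rec$duty[rec$parameter == "stance LH"], 0.86 / 1.34)
  expect_equal(rec$duty[rec$parameter == "stride"], 1)
})

test_that("programmed duty factors are reproduced exactly without jitter", {
  ev <- quarter_walk_events()
  st <- segment_strides(ev)
  rec <- speed_normalize(stance_stride_durations(ev, st), st)
  for (limb in c("LF", "RF", "LH", "RH")) {
    d <- rec$duty[rec$parameter == paste0("stance ", limb) & rec$included]
    expect_equal(d, rep(c(LF = .68, RF = .69, LH = .64, RH = .64)[[limb]],
                        length(d)), tolerance = 1e-12)
  }
})

test_that("support durations match the published walk structure", {
  ev <- quarter_walk_events(n = 8)
  st <- segment_strides(ev)
  sup <- support_durations(ev, st)
  ok <- sup[sup$stride_id %in% 3:6, ]   # interior strides, no boundary effects
  med <- function(p) median(ok$duration[ok$parameter == p])
  expect_equal(med("RF-LH"), 0.11, tolerance = 1e-9)
  expect_equal(med("LF-RH"), 0.11, tolerance = 1e-9)
  expect_equal(med("LF-LH"), 0.06, tolerance = 1e-9)
  expect_equal(med("RF-RH"), 0.07, tolerance = 1e-9)
  expect_equal(med("no LH"), 0.18, tolerance = 1e-9)
  expect_equal(med("no RH"), 0.19, tolerance = 1e-9)
  expect_equal(med("no LF"), 0.14, tolerance = 1e-9)
  expect_equal(med("no RF"), 0.14, tolerance = 1e-9)
  # overall tripedal median = 0.16 of the stride
  tri <- ok$duration[ok$parameter %in% c("no LF", "no RF", "no LH", "no RH")]
  expect_equal(median(tri), 0.16, tolerance = 1e-9)
})

test_that("all limbs grounded throughout yields quadrupedal support only", {
  ev <- lapply(c(LF = 1, RF = 1, LH = 1, RH = 1), function(i)
    list(claw_on = c(0, 4), claw_off = c(3.9, 8)))
  st <- data.frame(stride_id = 1:2, start = c(0, 4), end = c(4, 8),
                   included = TRUE, exclusion_reason = "")
  sup <- support_durations(ev, st)
  expect_true(all(sup$parameter == "quadrupedal"))
  expect_false(any(sup$included))
})

test_that("interval sweep agrees with 1 ms rasterization on random walks", {
  set.seed(202)
  worst <- 0
  for (r in 1:100) {
    duty <- stats::setNames(runif(4, 0.55, 0.75), c("LF", "RF", "LH", "RH"))
    T <- runif(1, 0.9, 1.6)
    ev <- quarter_walk_events(T = T, n = 5, duty = duty,
                              jitter = runif(1, 0, 0.02), seed = r)
    st <- segment_strides(ev)
    a <- support_durations(ev, st)
    b <- support_durations_raster(ev, st, step = 0.001)
    m <- merge(a[, c("stride_id", "parameter", "duration")], b,
               by = c("stride_id", "parameter"), suffixes = c("_sweep", "_raster"))
    worst <- max(worst, max(abs(m$duration_sweep - m$duration_raster)))
  }
  expect_lte(worst, 0.002)
})

test_that("support configuration durations conserve total limb stance time", {
  for (seed in 1:5) {
    ev <- quarter_walk_events(n = 6, jitter = 0.015, seed = seed)
    st <- segment_strides(ev)
    sup <- support_durations(ev, st)
    # per interior stride: 2*bipedal + 3*tripedal + 4*quadrupedal (+1*single)
    # equals the summed per-limb stance time inside the stride
    for (i in 3:4) {
      s <- sup[sup$stride_id == i, ]
      w <- ifelse(s$parameter %in% c("LF-RH", "RF-LH", "LF-LH", "RF-RH"), 2,
           ifelse(startsWith(s$parameter, "no "), 3,
           ifelse(s$parameter == "quadrupedal", 4, 1)))
      lhs <- sum(w * s$duration)
      stance_time <- 0
      for (l in c("LF", "RF", "LH", "RH")) {
        iv <- cowgait:::stance_intervals(ev[[l]])
        lo <- pmax(iv[, 1], st$start[i]); hi <- pmin(iv[, 2], st$end[i])
        stance_time <- stance_time + sum(pmax(hi - lo, 0))
      }
      expect_equal(lhs, stance_time, tolerance = 1e-6)
    }
  }
})

test_that("speed normalization flags out-of-range fractions and orphans", {
  st <- data.frame(stride_id = 1L, start = 0, end = 1,
                   included = TRUE, exclusion_reason = "")
  rec <- rbind(
    cowgait:::temporal_record(1L, "stance LF", 1.5),  # duty 1.5 -> excluded
    cowgait:::temporal_record(1L, "stance LH", 0.6),
    cowgait:::temporal_record(2L, "stance RH", 0.6))  # no stride 2 -> excluded
  out <- speed_normalize(rec, st)
  expect_false(out$included[1])
  expect_match(out$exclusion_reason[1], "duty outside")
  expect_true(out$included[2])
  expect_equal(out$duty[2], 0.6)
  expect_false(out$included[3])
  expect_match(out$exclusion_reason[3], "no matching LH stride")
})

test_that("negative durations from corrupted events are excluded, not dropped", {
  ev <- list(LH = list(claw_on = c(1, 2), claw_off = c(0.9, 2.9)))
  st <- data.frame(stride_id = 1L, start = 1, end = 2,
                   included = TRUE, exclusion_reason = "")
  rec <- stance_stride_durations(ev, st)
  # the LH stance pairs claw-on 1 with the first later claw-off (2.9):
  # positive but > stride; craft the negative case directly instead
  rec2 <- cowgait:::temporal_record(1L, "stance LH", -0.1,
                                    included = -0.1 > 0,
                                    reason = "negative duration")
  expect_false(rec2$included)
  expect_equal(rec2$exclusion_reason, "negative duration")
  # stride of non-positive duration flagged by the pipeline path
  st2 <- data.frame(stride_id = 1L, start = 2, end = 2,
                    included = TRUE, exclusion_reason = "")
  r3 <- stance_stride_durations(list(LH = list(claw_on = numeric(0),
                                               claw_off = numeric(0))), st2)
  expect_false(r3$included[r3$parameter == "stride"])
})
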