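#' Gait parameters for the synthetic walk simulator
#'
#' Defaults reproduce the published group medians for sound walking dairy
#' cows: per-limb duty factors 0.68/0.69 (front) and 0.64/0.64 (hind), a
#' left-hind stride duration of 1.34 s (so that stance = duty x stride
#' matches the reported 0.86-0.92 s), quarter-cycle lateral-sequence phase
#' offsets LH 0, LF 0.25, RH 0.5, RF 0.75, and distal-limb angle maxima of
#' +25/+26 deg protraction and -46 deg retraction for the front limbs versus
#' +24/+23 and -29/-30 deg for the hind limbs.
#'
#' @param stride_duration Stride duration T in seconds (> 0).
#' @param duty_factor Named fraction in (0,1) per limb (LF, RF, LH, RH).
#' @param phase_offset Named stride fraction in [0,1) per limb; LH must be 0
#'   (the reference limb).
#' @param n_strides Number of strides to generate.
#' @param timing_jitter_sd SD (s) of independent Gaussian jitter added to
#'   every claw-on/claw-off boundary.
#' @param protraction_max Named degrees (> 0) per limb.
#' @param retraction_max Named degrees (< 0) per limb.
#' @return Validated list of class `gait_params`.
#' @export
gait_params <- function(stride_duration = 1.34,
                        duty_factor = c(LF = 0.68, RF = 0.69, LH = 0.64, RH = 0.64),
                        phase_offset = c(LF = 0.25, RF = 0.75, LH = 0, RH = 0.5),
                        n_strides = 20L,
                        timing_jitter_sd = 0.01,
                        protraction_max = c(LF = 25, RF = 26, LH = 24, RH = 23),
                        retraction_max = c(LF = -46, RF = -46, LH = -29, RH = -30)) {
  stopifnot(stride_duration > 0, n_strides >= 1, timing_jitter_sd >= 0)
  for (nm in c("duty_factor", "phase_offset", "protraction_max", "retraction_max")) {
    v <- get(nm)
    if (!all(LIMBS %in% names(v)))
      stop("gait_params: ", nm, " must be named for all of ",
           paste(LIMBS, collapse = ", "))
  }
  if (any(duty_factor <= 0) || any(duty_factor >= 1))
    stop("gait_params: duty factors must lie strictly in (0,1)")
  if (phase_offset[["LH"]] != 0)
    stop("gait_params: LH phase offset must be 0 (reference limb)")
  if (any(phase_offset < 0) || any(phase_offset >= 1))
    stop("gait_params: phase offsets must lie in [0,1)")
  if (anyDuplicated(phase_offset[LIMBS]))
    stop("gait_params: phase offsets must be distinct")
  if (any(protraction_max <= 0))
    stop("gait_params: protraction maxima must be positive degrees")
  if (any(retraction_max >= 0))
    stop("gait_params: retraction maxima must be negative degrees")
  structure(list(stride_duration = stride_duration,
                 duty_factor = duty_factor[LIMBS],
                 phase_offset = phase_offset[LIMBS],
                 n_strides = as.integer(n_strides),
                 timing_jitter_sd = timing_jitter_sd,
                 protraction_max = protraction_max[LIMBS],
                 retraction_max = retraction_max[LIMBS]),
            class = "gait_params")
}

#' Upper-body vertical motion parameters
#'
#' Vertical displacement of every upper-body location is modelled as two
#' stride-locked harmonics: z(p) = h1 cos(2 pi (p - p1)) + h2 cos(4 pi (p - p2)),
#' with p the stride phase (0 = LH claw-on). Defaults phase the
#' double-stride-frequency harmonic so the sacrum peaks at 25% and 75% of the
#' stride (midstance of the two hind limbs), the withers at 0% and 50%
#' (front-limb midstances), and the back just before both; the tuber coxae
#' add a stride-frequency harmonic so the first LTC peak (left-hind
#' midstance) is the higher one, mirrored for the RTC. Amplitudes follow the
#' reported excursions: about 0.045 m peak-to-peak for sacrum and withers,
#' 0.025 m for the back, about 0.1 m for the tuber coxae. Head and collar
#' carry an additional low-frequency wander term emulating non-stride head
#' motion.
#'
#' @param locations Optional named list overriding per-location entries
#'   `list(h1 =, h2 =, p1 =, p2 =, wander_sd =)` (amplitudes in meters,
#'   phases in stride fractions).
#' @return List of class `upper_body_params`, one entry per location.
#' @export
upper_body_params <- function(locations = list()) {
  def <- list(
    sacrum = list(h1 = 0,     h2 = 0.0225, p1 = 0,    p2 = 0.25, wander_sd = 0),
    withers = list(h1 = 0,    h2 = 0.0225, p1 = 0,    p2 = 0.00, wander_sd = 0),
    back   = list(h1 = 0,     h2 = 0.0125, p1 = 0,    p2 = 0.97, wander_sd = 0),
    LTC    = list(h1 = 0.03,  h2 = 0.02,   p1 = 0.25, p2 = 0.25, wander_sd = 0),
    RTC    = list(h1 = 0.03,  h2 = 0.02,   p1 = 0.75, p2 = 0.25, wander_sd = 0),
    head   = list(h1 = 0.01,  h2 = 0.02,   p1 = 0.50, p2 = 0.00, wander_sd = 0.02),
    collar = list(h1 = 0.005, h2 = 0.0125, p1 = 0.50, p2 = 0.00, wander_sd = 0.03))
  bad <- setdiff(names(locations), names(def))
  if (length(bad))
    stop("upper_body_params: unknown location(s): ", paste(bad, collapse = ", "))
  for (loc in names(locations)) def[[loc]] <- utils::modifyList(def[[loc]], locations[[loc]])
  for (loc in names(def)) {
    p <- def[[loc]]
    if (p$h1 < 0 || p$h2 < 0 || p$wander_sd < 0)
      stop("upper_body_params: amplitudes must be >= 0 (", loc, ")")
    if (p$p1 < 0 || p$p1 >= 1 || p$p2 < 0 || p$p2 >= 1)
      stop("upper_body_params: phases must lie in [0,1) (", loc, ")")
  }
  structure(def, class = "upper_body_params")
}

#' Sensor noise parameters
#'
#' @param accel_noise_sd Additive white accelerometer noise SD, m/s^2.
#' @param gyro_noise_sd Additive white gyroscope noise SD, deg/s.
#' @param seed Integer seed governing all randomness of a simulation.
#' @export
noise_params <- function(accel_noise_sd = 0.5, gyro_noise_sd = 2, seed = 1L) {
  stopifnot(accel_noise_sd >= 0, gyro_noise_sd >= 0)
  structure(list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 seed = as.integer(seed)), class = "noise_params")
}

#' Generate per-limb footfall event times for a lateral-sequence walk
#'
#' Stance k of each limb occupies `[ (k + phi) T, (k + phi + d) T ]` with
#' independent Gaussian jitter on every boundary (T = stride duration, phi =
#' phase offset, d = duty factor). Jitter draws that would invert an on/off
#' pair are resampled a bounded number of times before failing.
#'
#' @param params A [gait_params()].
#' @param seed Optional integer seed (jitter only).
#' @param max_retries Resampling attempts before giving up.
#' @return Named list per limb with numeric vectors `claw_on` and `claw_off`
#'   (seconds, t = 0 at the first nominal LH claw-on).
#' @export
simulate_footfalls <- function(params, seed = NULL, max_retries = 20L) {
  stopifnot(inherits(params, "gait_params"))
  if (!is.null(seed)) set.seed(seed)
  T <- params$stride_duration
  out <- list()
  for (limb in LIMBS) {
    phi <- params$phase_offset[[limb]]
    d <- params$duty_factor[[limb]]
    k <- seq_len(params$n_strides) - 1
    on0 <- (k + phi) * T
    off0 <- (k + phi + d) * T
    sd <- params$timing_jitter_sd
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      on <- on0 + stats::rnorm(length(k), 0, sd)
      off <- off0 + stats::rnorm(length(k), 0, sd)
      ev <- as.vector(rbind(on, off))
      if (all(diff(ev) > 0)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("simulate_footfalls: jitter sd ", sd, " repeatedly inverted ",
           "on/off ordering for ", limb, " after ", max_retries, " retries")
    out[[limb]] <- list(claw_on = on, claw_off = off)
  }
  out
}

deg2rad <- function(x) x * pi / 180

# Sagittal limb-angle trajectory with exact programmed extrema.
# Stance: smooth monotone descent prot -> ret that passes through 0 at the
# temporal stance midpoint with zero end slopes; swing: raised cosine
# ret -> prot. The trajectory is C1, its only gyro sign changes are at
# claw-on (+ -> -) and claw-off (- -> +).
limb_angle_fun <- function(on, off, prot, ret, ramp_s = 0.5) {
  stopifnot(length(on) == length(off), all(off > on))
  n <- length(on)
  mid <- (prot + ret) / 2
  half <- (prot - ret) / 2
  c0 <- -mid                        # midstance-zero correction coefficient
  stance_val <- function(s) mid + half * cos(pi * s) + c0 * sin(pi * s)^2
  stance_d <- function(s, dur)      # d/dt, s in [0,1] over duration dur
    (-half * pi * sin(pi * s) + c0 * pi * sin(2 * pi * s)) / dur
  rc_val <- function(s, a, b) a + (b - a) * (1 - cos(pi * s)) / 2
  rc_d <- function(s, a, b, dur) (b - a) * pi * sin(pi * s) / (2 * dur)
  function(t) {
    th <- numeric(length(t))
    om <- numeric(length(t))
    ramp0 <- max(on[1] - ramp_s, 0)
    i <- t >= ramp0 & t < on[1]
    if (any(i)) {
      s <- (t[i] - ramp0) / (on[1] - ramp0)
      th[i] <- rc_val(s, 0, prot); om[i] <- rc_d(s, 0, prot, on[1] - ramp0)
    }
    for (k in seq_len(n)) {
      dur <- off[k] - on[k]
      i <- t >= on[k] & t < off[k]
      if (any(i)) {
        s <- (t[i] - on[k]) / dur
        th[i] <- stance_val(s); om[i] <- stance_d(s, dur)
      }
      nxt <- if (k < n) on[k + 1] else off[k] + ramp_s
      tgt <- if (k < n) prot else 0
      dur2 <- nxt - off[k]
      i <- t >= off[k] & t < nxt
      if (any(i)) {
        s <- (t[i] - off[k]) / dur2
        th[i] <- rc_val(s, ret, tgt); om[i] <- rc_d(s, ret, tgt, dur2)
      }
    }
    list(angle = th, rate = om)
  }
}

impact_burst <- function(time, at, amp = 40, freq = 40, tau = 0.02) {
  out <- numeric(length(time))
  for (t0 in at) {
    i <- time >= t0 & time <= t0 + 5 * tau
    dt <- time[i] - t0
    out[i] <- out[i] + amp * exp(-dt / tau) * sin(2 * pi * freq * dt)
  }
  out
}

#' Synthesize distal-limb IMU streams with ground truth
#'
#' Builds, per limb, a smooth periodic sagittal angle trajectory whose
#' per-stride extrema are exactly the programmed protraction/retraction
#' maxima and which is zero at every stance midpoint, emits the mediolateral
#' gyroscope channel as its analytic derivative and the accelerometer as
#' gravity rotated by the same angle plus a short decaying impact burst at
#' every claw-on, and prepends a standing-still calibration window.
#'
#' @param params A [gait_params()].
#' @param noise A [noise_params()].
#' @param rate Sampling rate, Hz.
#' @param calibration_s Length of the zero-motion calibration prefix, s.
#' @param lead_in_s Quiet gap between calibration end and the first nominal
#'   LH claw-on.
#' @param footfalls Optional precomputed [simulate_footfalls()] schedule
#'   (t = 0 frame), so limb and upper-body streams can share one schedule.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param impact_amp Impact transient amplitude, m/s^2 (0 disables).
#' @return List with `streams` (named list of [sensor_stream()], limbs),
#'   `truth` (list: `events`, `time`, `angle`) and `span` (trial end time).
#' @export
simulate_limb_streams <- function(params, noise = noise_params(), rate = 200,
                                  calibration_s = 5, lead_in_s = 1,
                                  footfalls = NULL, gravity = 9.80665,
                                  impact_amp = 40) {
  stopifnot(inherits(params, "gait_params"))
  set.seed(noise$seed)
  if (is.null(footfalls)) footfalls <- simulate_footfalls(params)
  shift <- calibration_s + lead_in_s
  ev <- lapply(footfalls, function(e)
    list(claw_on = e$claw_on + shift, claw_off = e$claw_off + shift))
  t_end <- max(vapply(ev, function(e) max(e$claw_off), numeric(1))) + 0.3
  time <- seq(0, t_end, by = 1 / rate)
  streams <- list()
  angle_truth <- list()
  for (limb in LIMBS) {
    f <- limb_angle_fun(ev[[limb]]$claw_on, ev[[limb]]$claw_off,
                        params$protraction_max[[limb]],
                        params$retraction_max[[limb]])
    tr <- f(time)
    th <- deg2rad(tr$angle)
    accel <- cbind(-gravity * sin(th), 0, gravity * cos(th))
    if (impact_amp > 0) {
      burst <- impact_burst(time, ev[[limb]]$claw_on, amp = impact_amp)
      accel[, 1] <- accel[, 1] + burst
      accel[, 3] <- accel[, 3] + 0.5 * burst
    }
    gyro <- cbind(0, tr$rate, 0)
    n <- length(time)
    accel <- accel + matrix(stats::rnorm(3 * n, 0, noise$accel_noise_sd), n, 3)
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, noise$gyro_noise_sd), n, 3)
    streams[[limb]] <- sensor_stream(limb, rate, time, accel, gyro)
    angle_truth[[limb]] <- tr$angle
  }
  list(streams = streams,
       truth = list(events = ev, time = time, angle = angle_truth),
       span = t_end)
}

# Piecewise-linear stride phase: p(t) = k + (t - s_k)/T_k on [s_k, s_{k+1});
# extended with the first/last stride duration outside the event range.
stride_phase_fun <- function(lh_on) {
  n <- length(lh_on)
  stopifnot(n >= 2)
  durs <- diff(lh_on)
  function(t) {
    k <- findInterval(t, lh_on)
    k0 <- pmin(pmax(k, 1L), n - 1L)
    p <- (k0 - 1) + (t - lh_on[k0]) / durs[k0]
    dp <- 1 / durs[k0]
    list(p = p, dp = dp)
  }
}

#' Synthesize upper-body IMU streams with ground truth
#'
#' Vertical displacement per location is the two-harmonic stride-locked model
#' of [upper_body_params()], evaluated on the (possibly jittered) LH stride
#' phase, ramped in over the first stride after the standing-still
#' calibration window; head and collar add low-frequency sinusoidal wander.
#' The vertical accelerometer channel is the analytic second derivative plus
#' gravity plus noise; gyroscope channels carry noise only.
#'
#' @inheritParams simulate_limb_streams
#' @param ub An [upper_body_params()].
#' @param locations Locations to synthesize (default all seven).
#' @return List with `streams`, `truth` (list: `events`, `time`, `vdisp`) and
#'   `span`.
#' @export
simulate_upper_body_streams <- function(params, ub = upper_body_params(),
                                        noise = noise_params(), rate = 200,
                                        calibration_s = 5, lead_in_s = 1,
                                        footfalls = NULL, gravity = 9.80665,
                                        locations = UPPER_LOCATIONS) {
  stopifnot(inherits(params, "gait_params"), inherits(ub, "upper_body_params"))
  set.seed(noise$seed + 1L)
  if (is.null(footfalls)) footfalls <- simulate_footfalls(params)
  shift <- calibration_s + lead_in_s
  ev <- lapply(footfalls, function(e)
    list(claw_on = e$claw_on + shift, claw_off = e$claw_off + shift))
  lh_on <- ev$LH$claw_on
  t_end <- max(lh_on) + 0.3
  time <- seq(0, t_end, by = 1 / rate)
  phase <- stride_phase_fun(lh_on)
  ph <- phase(time)
  p <- ph$p; dp <- ph$dp
  # raised-cosine amplitude envelope over the first stride after calibration
  t_r0 <- lh_on[1]; t_r1 <- lh_on[2]
  env <- rep(1, length(time))
  envd <- envdd <- numeric(length(time))
  i <- time < t_r0
  env[i] <- 0
  i <- time >= t_r0 & time < t_r1
  u <- (time[i] - t_r0) / (t_r1 - t_r0)
  env[i] <- (1 - cos(pi * u)) / 2
  envd[i] <- pi * sin(pi * u) / (2 * (t_r1 - t_r0))
  envdd[i] <- pi^2 * cos(pi * u) / (2 * (t_r1 - t_r0)^2)
  streams <- list()
  vtruth <- list()
  for (loc in locations) {
    par <- ub[[loc]]
    z <- par$h1 * cos(2 * pi * (p - par$p1)) + par$h2 * cos(4 * pi * (p - par$p2))
    zd <- -par$h1 * 2 * pi * dp * sin(2 * pi * (p - par$p1)) -
      par$h2 * 4 * pi * dp * sin(4 * pi * (p - par$p2))
    zdd <- -par$h1 * (2 * pi * dp)^2 * cos(2 * pi * (p - par$p1)) -
      par$h2 * (4 * pi * dp)^2 * cos(4 * pi * (p - par$p2))
    if (par$wander_sd > 0) {
      fw <- stats::runif(3, 0.1, 0.4)
      phw <- stats::runif(3, 0, 2 * pi)
      aw <- rep(par$wander_sd * sqrt(2 / 3), 3)
      for (j in 1:3) {
        z <- z + aw[j] * sin(2 * pi * fw[j] * time + phw[j])
        zd <- zd + aw[j] * 2 * pi * fw[j] * cos(2 * pi * fw[j] * time + phw[j])
        zdd <- zdd - aw[j] * (2 * pi * fw[j])^2 * sin(2 * pi * fw[j] * time + phw[j])
      }
    }
    # apply envelope with product rule so truth and emitted accel agree
    ztot <- env * z
    zddtot <- envdd * z + 2 * envd * zd + env * zdd
    n <- length(time)
    accel <- cbind(0, 0, zddtot + gravity) +
      matrix(stats::rnorm(3 * n, 0, noise$accel_noise_sd), n, 3)
    gyro <- matrix(stats::rnorm(3 * n, 0, noise$gyro_noise_sd), n, 3)
    streams[[loc]] <- sensor_stream(loc, rate, time, accel, gyro)
    vtruth[[loc]] <- ztot
  }
  list(streams = streams,
       truth = list(events = ev, time = time, vdisp = vtruth),
       span = t_end)
}

#' Simulate a complete multi-sensor walking trial
#'
#' Generates one footfall schedule and synthesizes the four limb streams and
#' the seven upper-body streams against it, returning a [gait_trial()] plus
#' full ground truth (event times and true angle/displacement trajectories).
#'
#' @inheritParams simulate_limb_streams
#' @param ub An [upper_body_params()].
#' @param cow_id,measurement_id Provenance identifiers.
#' @param locations Upper-body locations to include.
#' @return List with `trial` (a [gait_trial()]) and `truth`.
#' @export
simulate_trial <- function(params = gait_params(), ub = upper_body_params(),
                           noise = noise_params(), rate = 200,
                           calibration_s = 5, lead_in_s = 1,
                           cow_id = "simcow", measurement_id = "m1",
                           locations = UPPER_LOCATIONS, impact_amp = 40) {
  set.seed(noise$seed)
  ff <- simulate_footfalls(params)
  lb <- simulate_limb_streams(params, noise, rate, calibration_s, lead_in_s,
                              footfalls = ff, impact_amp = impact_amp)
  ubs <- simulate_upper_body_streams(params, ub, noise, rate, calibration_s,
                                     lead_in_s, footfalls = ff,
                                     locations = locations)
  streams <- c(lb$streams, ubs$streams)
  # trim to common span
  n <- min(vapply(streams, function(s) length(s$time), integer(1)))
  streams <- lapply(streams, function(s)
    sensor_stream(s$location, s$rate, s$time[1:n], s$accel[1:n, , drop = FALSE],
                  s$gyro[1:n, , drop = FALSE], s$meta))
  trial <- gait_trial(streams, cow_id, measurement_id,
                      calibration_window = c(0, calibration_s))
  truth <- list(events = lb$truth$events, time = lb$truth$time[1:n],
                angle = lapply(lb$truth$angle, function(a) a[1:n]),
                vdisp = lapply(ubs$truth$vdisp, function(v) v[1:n]),
                params = params)
  list(trial = trial, truth = truth)
}

#' Write simulator ground truth as sidecar tables
#'
#' Two tab-separated files next to the trial: `truth_events.txt`
#' (limb, event, time_s) and `truth_trajectories.txt` (channel, location,
#' sample, time_s, value — angle in degrees, displacement in meters).
#'
#' @param truth `truth` element from [simulate_trial()].
#' @param path Output directory.
#' @export
write_sim_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  evs <- do.call(rbind, lapply(names(truth$events), function(l) {
    e <- truth$events[[l]]
    rbind(data.frame(limb = l, event = "claw_on", time_s = e$claw_on),
          data.frame(limb = l, event = "claw_off", time_s = e$claw_off))
  }))
  utils::write.table(evs[order(evs$limb, evs$time_s), ],
                     file.path(path, "truth_events.txt"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  traj <- rbind(
    do.call(rbind, lapply(names(truth$angle), function(l)
      data.frame(channel = "angle_deg", location = l,
                 sample = seq_along(truth$time), time_s = truth$time,
                 value = truth$angle[[l]]))),
    do.call(rbind, lapply(names(truth$vdisp), function(l)
      data.frame(channel = "vdisp_m", location = l,
                 sample = seq_along(truth$time), time_s = truth$time,
                 value = truth$vdisp[[l]]))))
  utils::write.table(traj, file.path(path, "truth_trajectories.txt"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
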