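cumtrapz1 <- function(dt, x) {
  # cumulative trapezoidal integral on a uniform grid, starting at 0
  c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))
}

# cyclic endpoint-matching correction: remove the line through the first and
# last sample, so the series takes equal values at the cycle boundaries.
# For a stride-periodic signal this removes integration drift exactly,
# whereas a least-squares detrend would not (a sinusoid over a whole number
# of periods regresses on time with non-zero slope).
detrend_cyclic <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  x - x[1] - (x[n] - x[1]) / (n - 1) * (seq_len(n) - 1)
}

#' Upper-body vertical displacement by cyclic double integration
#'
#' Rotates the accelerometer into the gravity-aligned world frame using the
#' complementary filter, subtracts gravity, and double-integrates the
#' vertical component stride cycle by stride cycle: within every stride the
#' integrated velocity receives a cyclic endpoint-matching drift correction
#' (equal velocity at the cycle boundaries), is integrated again, and the
#' displacement receives the same correction and is zero-meaned. For
#' stride-periodic motion this removes integration drift without distorting
#' the within-stride shape. Strides shorter than `min_stride_s` or longer
#' than `max_stride_s` are skipped with a warning.
#'
#' @param stream An upper-body [sensor_stream()].
#' @param strides Stride index (LH claw-on boundaries).
#' @param config Configuration list.
#' @param calibration_window Standing-still window for the orientation filter.
#' @return Numeric vector (meters) aligned to `stream$time`; NA outside
#'   processed strides.
#' @export
vertical_displacement <- function(stream, strides, config = load_config(),
                                  calibration_window = c(0, 5)) {
  qs <- complementary_filter(stream, config, calibration_window)
  n <- length(stream$time)
  # world-frame vertical specific acceleration minus gravity
  az <- numeric(n)
  for (i in seq_len(n)) {
    q <- qs[i, ]
    a <- stream$accel[i, ]
    az[i] <- 2 * (q[2] * q[4] - q[1] * q[3]) * a[1] +
      2 * (q[3] * q[4] + q[1] * q[2]) * a[2] +
      (1 - 2 * (q[2]^2 + q[3]^2)) * a[3]
  }
  az <- az - config$gravity
  dt <- 1 / stream$rate
  disp <- rep(NA_real_, n)
  for (i in seq_len(nrow(strides))) {
    dur <- strides$end[i] - strides$start[i]
    if (dur < config$min_stride_s || dur > config$max_stride_s) {
      warning("vertical_displacement: stride ", strides$stride_id[i],
              " duration ", signif(dur, 3), " s outside [",
              config$min_stride_s, ", ", config$max_stride_s, "] s, skipped")
      next
    }
    sel <- which(stream$time >= strides$start[i] & stream$time < strides$end[i])
    if (length(sel) < 4) next
    v <- detrend_cyclic(cumtrapz1(dt, az[sel]))
    z <- detrend_cyclic(cumtrapz1(dt, v))
    disp[sel] <- z - mean(z)
  }
  disp
}

#' Resample one segment of a trajectory to a fixed number of points
#'
#' Linear interpolation at equally spaced phases of `[t0, t1]` (endpoints
#' included); exact on piecewise-linear (degree-1) inputs.
#'
#' @param time,values Trajectory samples.
#' @param t0,t1 Segment boundaries in seconds.
#' @param n Number of output samples.
#' @export
resample_curve <- function(time, values, t0, t1, n = 100L) {
  stats::approx(time, values, xout = seq(t0, t1, length.out = n),
                rule = 2)$y
}

#' Cut a displacement trajectory into stride-normalized curves
#'
#' The core stride (LH claw-on to next LH claw-on) is linearly interpolated
#' to `n_curve_samples` points on the 0-100% stride scale; leading and
#' trailing padding blocks of `pad_fraction` of the stride duration are
#' interpolated separately to `n_pad_samples` points each and kept outside
#' the 0-100 scale. Curves are zero-meaned over the core stride.
#'
#' @param disp Displacement vector aligned to `time` (NA outside strides).
#' @param time Sample times.
#' @param strides Stride index; only included strides are cut.
#' @param config Configuration list.
#' @return List of class `curve_set`: `curves` (m x 100 matrix, one row per
#'   stride), `pad_pre`/`pad_post` matrices, `stride_id`.
#' @export
cut_and_normalize <- function(disp, time, strides, config = load_config()) {
  nc <- config$n_curve_samples
  np <- config$n_pad_samples
  rows <- list(); pre <- list(); post <- list(); ids <- integer(0)
  for (i in seq_len(nrow(strides))) {
    if (!strides$included[i]) next
    s0 <- strides$start[i]; s1 <- strides$end[i]
    pad <- config$pad_fraction * (s1 - s0)
    sel <- time >= s0 & time < s1
    if (!any(sel) || anyNA(disp[sel])) next
    core <- resample_curve(time[sel], disp[sel], s0, s1, nc)
    core <- core - mean(core)
    ok <- !is.na(disp)
    padsel <- ok & time >= s0 - pad - 0.01 & time <= s1 + pad + 0.01
    rows[[length(rows) + 1L]] <- core
    pre[[length(pre) + 1L]] <-
      resample_curve(time[padsel], disp[padsel], s0 - pad, s0, np)
    post[[length(post) + 1L]] <-
      resample_curve(time[padsel], disp[padsel], s1, s1 + pad, np)
    ids <- c(ids, strides$stride_id[i])
  }
  structure(list(curves = do.call(rbind, rows),
                 pad_pre = do.call(rbind, pre),
                 pad_post = do.call(rbind, post),
                 stride_id = ids),
            class = "curve_set")
}
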