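# Quaternion utilities (w, x, y, z), Hamilton convention, q maps sensor -> world.
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(c(1, v / 2))
  c(cos(ang / 2), sin(ang / 2) * v / ang)
}

quat_rotate <- function(q, v) {
  # R(q) %*% v without forming R
  t <- 2 * c(q[3] * v[3] - q[4] * v[2],
             q[4] * v[1] - q[2] * v[3],
             q[2] * v[2] - q[3] * v[1])
  v + q[1] * t + c(q[3] * t[3] - q[4] * t[2],
                   q[4] * t[1] - q[2] * t[3],
                   q[2] * t[2] - q[3] * t[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# Rotation matrix sensor -> world
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_from_two_vectors <- function(a, b) {
  # smallest rotation taking unit vector a onto unit vector b
  d <- sum(a * b)
  ax <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (d > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0))  # antiparallel: 180 deg about x
  }
  ang <- atan2(s, d)
  quat_from_rotvec(ax / s * ang)
}

#' Quaternion-based complementary-filter orientation estimation
#'
#' Fuses gyroscope integration (high frequency) with the accelerometer
#' gravity direction (low frequency): each sample the quaternion is
#' propagated by the body angular rate and then rotated a fraction
#' `1 - alpha` of the way towards agreement with the measured gravity
#' direction. The correction is skipped when the accelerometer magnitude is
#' far from 1 g (impacts, strong linear acceleration). The initial
#' orientation is taken from the mean accelerometer reading over the
#' standing-still calibration window.
#'
#' @param stream A [sensor_stream()].
#' @param config Configuration list (`filter_alpha`, `accel_gate`, `gravity`).
#' @param calibration_window Length-2 window in seconds; required.
#' @return n x 4 matrix of unit quaternions (sensor to world).
#' @export
complementary_filter <- function(stream, config = load_config(),
                                 calibration_window = c(0, 5)) {
  if (is.null(calibration_window) || diff(calibration_window) <= 0)
    stop("complementary_filter: missing calibration window")
  tt <- stream$time
  cal <- tt >= calibration_window[1] & tt <= calibration_window[2]
  if (!any(cal))
    stop("complementary_filter: calibration window outside recording")
  g <- config$gravity
  a0 <- colMeans(stream$accel[cal, , drop = FALSE])
  a0 <- a0 / sqrt(sum(a0^2))
  q <- quat_from_two_vectors(a0, c(0, 0, 1))
  alpha <- config$filter_alpha
  gate <- config$accel_gate
  dt <- 1 / stream$rate
  gyr <- stream$gyro * pi / 180
  acc <- stream$accel
  n <- length(tt)
  out <- matrix(0, n, 4)
  out[1, ] <- q
  up <- c(0, 0, 1)
  for (i in 2:n) {
    w <- (gyr[i - 1, ] + gyr[i, ]) / 2
    q <- quat_mul(q, quat_from_rotvec(w * dt))
    an <- sqrt(sum(acc[i, ]^2))
    if (abs(an - g) / g < gate) {
      vg <- quat_rotate(q, acc[i, ] / an)  # measured gravity in world frame
      ax <- c(vg[2] * up[3] - vg[3] * up[2], vg[3] * up[1] - vg[1] * up[3],
              vg[1] * up[2] - vg[2] * up[1])
      s <- sqrt(sum(ax^2))
      if (s > 1e-12) {
        ang <- atan2(s, sum(vg * up))
        q <- quat_mul(quat_from_rotvec(ax / s * ang * (1 - alpha)), q)
      }
    }
    q <- quat_normalize(q)
    out[i, ] <- q
  }
  out
}

#' Sagittal distal-limb angle from a limb IMU stream
#'
#' Runs the complementary filter and extracts the rotation about the
#' mediolateral (y) axis; protraction (forward angulation) is positive.
#'
#' @inheritParams complementary_filter
#' @return Numeric vector of angles in degrees, one per sample.
#' @export
complementary_filter_angle <- function(stream, config = load_config(),
                                       calibration_window = c(0, 5)) {
  qs <- complementary_filter(stream, config, calibration_window)
  # pitch about y: R[3,1] = -sin(psi) for a pure y rotation
  r31 <- 2 * (qs[, 2] * qs[, 4] - qs[, 1] * qs[, 3])
  asin(pmin(pmax(-r31, -1), 1)) * 180 / pi
}

#' Per-stride distal-limb angle extrema with exclusion rules
#'
#' For every included stride the angle trajectory is re-zeroed at that
#' limb's midstance (temporal midpoint of its stance phase inside the
#' stride); maximal protraction is the maximum and maximal retraction the
#' minimum of the re-zeroed angle over the stride. Strides whose maximal
#' retraction is positive or maximal protraction negative are flagged
#' excluded (not deleted); strides without a stance for the limb are
#' flagged `"no stance"`.
#'
#' @param angle Angle trajectory in degrees (one value per sample).
#' @param time Sample times of `angle`.
#' @param strides Stride index from [segment_strides()].
#' @param events Per-limb event list.
#' @param limb Which limb the trajectory belongs to.
#' @return data.frame with per-stride extrema and inclusion flags; raw
#'   per-stride angle segments attached as attribute `"curves"`.
#' @export
extract_angle_extrema <- function(angle, time, strides, events, limb) {
  iv <- stance_intervals(events[[limb]])
  out <- list()
  curves <- list()
  for (i in seq_len(nrow(strides))) {
    if (!strides$included[i]) next
    s0 <- strides$start[i]; s1 <- strides$end[i]
    sel <- which(time >= s0 & time < s1)
    if (!length(sel)) next
    row <- iv[iv[, 1] >= s0 & iv[, 1] < s1, , drop = FALSE]
    if (nrow(row) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        limb = limb, stride_id = strides$stride_id[i],
        max_protraction = NA_real_, max_retraction = NA_real_,
        included = FALSE, exclusion_reason = "no stance")
      next
    }
    mid <- (row[1, 1] + row[1, 2]) / 2
    imid <- which.min(abs(time - mid))
    a <- angle[sel] - angle[imid]
    prot <- max(a); ret <- min(a)
    ok <- prot > 0 && ret < 0
    out[[length(out) + 1L]] <- data.frame(
      limb = limb, stride_id = strides$stride_id[i],
      max_protraction = prot, max_retraction = ret,
      included = ok,
      exclusion_reason = if (ok) "" else "sign rule")
    curves[[as.character(strides$stride_id[i])]] <-
      list(time = time[sel], angle = a)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(limb = character(0), stride_id = integer(0),
               max_protraction = numeric(0), max_retraction = numeric(0),
               included = logical(0), exclusion_reason = character(0))
  attr(res, "curves") <- curves
  res
}
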