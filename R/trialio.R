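UPPER_LOCATIONS <- c("head", "withers", "back", "sacrum", "LTC", "RTC", "collar")
LIMBS <- c("LF", "RF", "LH", "RH")
ALL_LOCATIONS <- c(UPPER_LOCATIONS, LIMBS)

#' Construct a single-location 6-axis IMU stream
#'
#' A sensor stream holds one anatomical location's synchronized 3-axis
#' accelerometer and 3-axis gyroscope time series sampled on a uniform grid.
#' Internal units are fixed: seconds, m/s^2 and deg/s.
#'
#' @param location One of `head, withers, back, sacrum, LTC, RTC, collar`
#'   (upper body) or `LF, RF, LH, RH` (distal limbs).
#' @param rate Sampling rate in Hz.
#' @param time Strictly increasing, uniformly spaced time stamps in seconds.
#' @param accel n x 3 numeric matrix, m/s^2 (columns: x cranial, y left, z up).
#' @param gyro n x 3 numeric matrix, deg/s, body frame.
#' @param meta Named list of sensor metadata (accelerometer ranges in g,
#'   gyroscope range in deg/s); sensible defaults filled per location class.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(location, rate, time, accel, gyro, meta = list()) {
  location <- match.arg(location, ALL_LOCATIONS)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  dimnames(accel) <- NULL
  dimnames(gyro) <- NULL
  n <- length(time)
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("sensor_stream: channel lengths differ (time ", n, ", accel ",
         nrow(accel), ", gyro ", nrow(gyro), ")")
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("sensor_stream: accel and gyro must each have 3 columns")
  if (n >= 2) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - 1 / rate)) >= 1e-6)
      stop("sensor_stream: non-uniform sampling (expected dt = ", 1 / rate, ")")
  }
  if (!all(is.finite(time)) || !all(is.finite(accel)) || !all(is.finite(gyro)))
    stop("sensor_stream: non-finite values")
  defaults <- if (location %in% LIMBS) {
    list(accel_range_low_g = 16, accel_range_high_g = 200, gyro_range_dps = 2000)
  } else {
    list(accel_range_low_g = 8, accel_range_high_g = 100, gyro_range_dps = 2000)
  }
  meta <- utils::modifyList(defaults, meta)
  structure(list(location = location, rate = rate, time = as.numeric(time),
                 accel = accel, gyro = gyro, meta = meta),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples @ %g Hz [%.3f, %.3f] s\n",
              x$location, length(x$time), x$rate,
              x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' Assemble a multi-sensor trial
#'
#' @param streams Named list of [sensor_stream()] objects (names = locations).
#' @param cow_id,measurement_id Provenance identifiers carried through all
#'   downstream tables.
#' @param calibration_window Length-2 numeric, the standing-still window in
#'   seconds used as orientation/gravity reference (>= 5 s recommended).
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(streams, cow_id = "cow", measurement_id = "m1",
                       calibration_window = c(0, 5)) {
  if (length(streams) == 0) stop("gait_trial: no streams")
  locs <- vapply(streams, function(s) s$location, character(1))
  names(streams) <- locs
  if (anyDuplicated(locs)) stop("gait_trial: duplicated locations")
  rates <- vapply(streams, function(s) s$rate, numeric(1))
  if (length(unique(rates)) != 1) stop("gait_trial: streams differ in rate")
  t0 <- vapply(streams, function(s) s$time[1], numeric(1))
  if (max(t0) - min(t0) > 1e-9)
    stop("gait_trial: streams do not share a common time base")
  if (diff(calibration_window) < 0)
    stop("gait_trial: invalid calibration window")
  structure(list(cow_id = cow_id, measurement_id = measurement_id,
                 streams = streams,
                 calibration_window = as.numeric(calibration_window)),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> cow %s / %s: %d streams (%s)\n", x$cow_id,
              x$measurement_id, length(x$streams),
              paste(names(x$streams), collapse = ", ")))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trial as per-sensor delimited text files
#'
#' One tab-separated file per stream, with a `# key: value` metadata header
#' followed by columns `t ax ay az gx gy gz`. Numbers are written with 17
#' significant digits so that a write/read round trip is bit exact.
#'
#' @param trial A [gait_trial()].
#' @param path Output directory (created if absent).
#' @param force Overwrite existing stream files.
#' @export
write_trial <- function(trial, path, force = FALSE) {
  stopifnot(inherits(trial, "gait_trial"))
  if (length(trial$streams) == 0) stop("write_trial: empty trial")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in trial$streams) {
    f <- file.path(path, paste0(s$location, ".txt"))
    if (file.exists(f) && !force)
      stop("write_trial: ", f, " exists (use force = TRUE)")
    hdr <- c(
      paste0("# location: ", s$location),
      paste0("# rate: ", fmt17(s$rate)),
      paste0("# cow_id: ", trial$cow_id),
      paste0("# measurement_id: ", trial$measurement_id),
      paste0("# calibration_window: ", fmt17(trial$calibration_window[1]),
             " ", fmt17(trial$calibration_window[2])),
      "# accel_units: m/s2",
      "# gyro_units: deg/s",
      paste0("# accel_range_low_g: ", s$meta$accel_range_low_g),
      paste0("# accel_range_high_g: ", s$meta$accel_range_high_g),
      paste0("# gyro_range_dps: ", s$meta$gyro_range_dps),
      "t\tax\tay\taz\tgx\tgy\tgz")
    body <- paste(fmt17(s$time),
                  fmt17(s$accel[, 1]), fmt17(s$accel[, 2]), fmt17(s$accel[, 3]),
                  fmt17(s$gyro[, 1]), fmt17(s$gyro[, 2]), fmt17(s$gyro[, 3]),
                  sep = "\t")
    writeLines(c(hdr, body), f)
  }
  invisible(path)
}

parse_stream_file <- function(f) {
  lines <- readLines(f)
  hd <- grep("^#", lines)
  if (length(hd) == 0 || any(diff(hd) != 1) || hd[1] != 1)
    stop("parse error in ", f, ": malformed header block")
  meta <- list()
  for (i in hd) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) stop("parse error in ", f, ", line ", i,
                             ": malformed header line")
    meta[[trimws(m[2])]] <- trimws(m[3])
  }
  need <- c("location", "rate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("parse error in ", f, ": missing header key(s) ",
         paste(miss, collapse = ", "))
  colline <- length(hd) + 1L
  cols <- strsplit(lines[colline], "\t")[[1]]
  if (!identical(cols, c("t", "ax", "ay", "az", "gx", "gy", "gz")))
    stop("parse error in ", f, ", line ", colline, ": unexpected columns")
  dat <- utils::read.table(text = lines[-seq_len(colline)], sep = "\t",
                           col.names = cols, colClasses = "numeric")
  list(meta = meta, data = dat)
}

#' Read a trial directory written by [write_trial()]
#'
#' Missing optional upper-body locations are tolerated; acceleration in g is
#' converted to m/s^2 at ingest when the header declares `accel_units: g`.
#'
#' @param path Trial directory.
#' @param config Optional configuration list (see [load_config()]).
#' @return A [gait_trial()].
#' @export
read_trial <- function(path, config = load_config()) {
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  files <- files[sub("\\.txt$", "", basename(files)) %in% ALL_LOCATIONS]
  if (length(files) == 0) stop("read_trial: no stream files under ", path)
  streams <- list()
  cow_id <- measurement_id <- NULL
  calib <- c(0, 5)
  for (f in files) {
    p <- parse_stream_file(f)
    meta <- p$meta
    d <- p$data
    rate <- as.numeric(meta$rate)
    accel <- as.matrix(d[, c("ax", "ay", "az")])
    if (identical(meta$accel_units, "g")) accel <- accel * config$gravity
    n <- nrow(d)
    if (n >= 2) {
      dt <- diff(d$t)
      if (any(dt <= 0) || max(abs(dt - 1 / rate)) >= 1e-6)
        stop("parse error in ", f, ": non-uniform sampling")
    }
    smeta <- list()
    for (k in c("accel_range_low_g", "accel_range_high_g", "gyro_range_dps"))
      if (!is.null(meta[[k]])) smeta[[k]] <- as.numeric(meta[[k]])
    streams[[meta$location]] <-
      sensor_stream(meta$location, rate, d$t, accel,
                    as.matrix(d[, c("gx", "gy", "gz")]), smeta)
    if (!is.null(meta$cow_id)) cow_id <- meta$cow_id
    if (!is.null(meta$measurement_id)) measurement_id <- meta$measurement_id
    if (!is.null(meta$calibration_window))
      calib <- as.numeric(strsplit(meta$calibration_window, "\\s+")[[1]])
  }
  gait_trial(streams, cow_id %||% "cow", measurement_id %||% "m1", calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cowgait_defaults <- function() list(
  # global
  sample_rate = 200,          # Hz
  gravity = 9.80665,          # m/s^2
  seed = 1L,
  # event detection
  gyro_axis = 2L,             # mediolateral gyro column (y)
  lowpass_hz = 10,            # zero-phase low-pass for swing-span detection
  refine_hz = 50,             # lighter low-pass for zero-crossing refinement
  swing_threshold_frac = 0.10,# fraction of local envelope peak
  envelope_window_s = 2.5,    # window for the adaptive envelope
  min_peak_rate = 20,         # deg/s; below this no gait is declared
  min_swing_s = 0.10,
  min_stance_s = 0.10,
  impact_snap_s = 0.05,       # claw-on snapped to jerk peak within +- this
  impact_jerk_min = 500,      # m/s^3; jerk peak must exceed this to snap
  # regularity screen
  stance_tolerance = 0.25,    # relative deviation from running median
  runmed_k = 7L,
  support_gap_tol_s = 0.05,   # tolerated 0- or 4-limb support per stride
  max_intervals = 4L,
  # orientation filter
  filter_alpha = 0.99,        # per-sample gyro weight
  accel_gate = 0.5,           # skip tilt correction if | |a|-g |/g exceeds this
  # vertical displacement
  min_stride_s = 0.3,
  max_stride_s = 3.0,
  pad_fraction = 0.10,
  n_curve_samples = 100L,
  n_pad_samples = 10L,
  displacement_unit = "mm",
  # curve statistics
  curve_metric = "rms",       # or "mae"
  # inference
  bootstrap_reps = 2000L,
  ci_level = 0.95,
  bootstrap_cluster = "stride" # or "cow"
)

#' Load and validate a run configuration
#'
#' Reads a YAML file of analysis parameters and merges it over the documented
#' defaults. Unknown keys raise an error so that typos cannot silently fall
#' back to defaults. `load_config()` with no arguments returns the defaults.
#'
#' @param path Optional path to a YAML config file.
#' @return Named list with the full parameter set.
#' @export
load_config <- function(path = NULL) {
  cfg <- cowgait_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("load_config: unknown key(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
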