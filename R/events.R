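# Rolling-maximum envelope via block maxima: for every sample the maximum
# over roughly +- window/2 neighbouring samples, O(n).
block_envelope <- function(x, window) {
  n <- length(x)
  B <- max(1L, as.integer(window %/% 2))
  nb <- ceiling(n / B)
  idx <- rep(seq_len(nb), each = B)[1:n]
  bm <- tapply(x, idx, max)
  bmp <- c(bm[1], bm, bm[nb])           # padded
  env <- pmax(bmp[idx], bmp[idx + 1L], bmp[idx + 2L])
  as.numeric(env)
}

runs_above <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect claw-on and claw-off events from a distal-limb IMU stream
#'
#' The mediolateral gyroscope channel is low-pass filtered (zero phase);
#' swing phases are the spans where the protraction rate exceeds an adaptive
#' threshold (a fraction of the local envelope peak) for a minimum duration.
#' Claw-off is the last upward zero crossing of the filtered rate before the
#' swing, claw-on the first downward zero crossing after it, refined by
#' snapping to the nearest accelerometer jerk peak within a small window
#' (the hoof-impact landmark); ties snap to the earlier peak. Events are
#' timestamped on the sampling grid; stance is the closed-open interval
#' [claw-on, claw-off).
#'
#' @param stream A limb [sensor_stream()].
#' @param config Configuration list, see [load_config()].
#' @param calibration_window Standing-still window excluded from detection.
#' @return List with `claw_on` and `claw_off` (seconds); empty (with a
#'   warning) when no gait is detectable.
#' @export
detect_claw_events <- function(stream, config = load_config(),
                               calibration_window = c(0, 5)) {
  rate <- stream$rate
  w <- stream$gyro[, config$gyro_axis]
  # zero-phase band limiting
  bf <- signal::butter(2, config$lowpass_hz / (rate / 2), type = "low")
  wf <- signal::filtfilt(bf, w)
  # lightly filtered copy for zero-crossing refinement (less corner smear)
  br <- signal::butter(2, min(config$refine_hz / (rate / 2), 0.9), type = "low")
  wr <- signal::filtfilt(br, w)
  tt <- stream$time
  active <- tt >= calibration_window[2]
  env <- block_envelope(ifelse(active, wf, 0),
                        round(config$envelope_window_s * rate))
  if (max(env) < config$min_peak_rate) {
    warning("detect_claw_events(", stream$location, "): no detectable gait")
    return(list(claw_on = numeric(0), claw_off = numeric(0)))
  }
  thr <- pmax(config$swing_threshold_frac * env, 0.5 * config$min_peak_rate)
  spans <- runs_above(wf > thr & active)
  if (nrow(spans)) {
    keep <- (spans[, 2] - spans[, 1] + 1) >= config$min_swing_s * rate
    spans <- spans[keep, , drop = FALSE]
  }
  if (nrow(spans) == 0) {
    warning("detect_claw_events(", stream$location, "): no detectable gait")
    return(list(claw_on = numeric(0), claw_off = numeric(0)))
  }
  n <- length(wf)
  jerk <- c(0, sqrt(rowSums(apply(stream$accel, 2, diff)^2))) * rate
  snapw <- round(config$impact_snap_s * rate)
  claw_off <- rep(NA_real_, nrow(spans))
  claw_on <- rep(NA_real_, nrow(spans))
  for (k in seq_len(nrow(spans))) {
    i1 <- spans[k, 1]; i2 <- spans[k, 2]
    # claw-off: walk back to the last non-positive sample, interpolate the crossing
    j <- i1
    while (j > 1 && wr[j - 1] > 0) j <- j - 1
    if (j > 1) {
      # extrapolate the steep (swing-side) branch through samples j, j+1
      # down to zero; the rate curve has a corner at the event, so plain
      # interpolation across it is biased towards the shallow stance branch
      t_off <- if (j < n && wr[j + 1] > wr[j])
        tt[j] - wr[j] / (wr[j + 1] - wr[j]) / rate
      else tt[j - 1] + wr[j - 1] / (wr[j - 1] - wr[j]) / rate
      claw_off[k] <- t_off
    }
    # claw-on: walk forward to the first non-positive sample
    j <- i2
    while (j < n && wr[j + 1] > 0) j <- j + 1
    if (j < n - snapw) {   # guard against filter edge transients at the end
      t_on <- if (j > 1 && wr[j - 1] > wr[j])
        tt[j] + wr[j] / (wr[j - 1] - wr[j]) / rate
      else tt[j] + wr[j] / (wr[j] - wr[j + 1]) / rate
      i_on <- min(max(round((t_on - tt[1]) * rate) + 1L, 1L), n)
      lo <- max(1L, i_on - snapw); hi <- min(n, i_on + snapw)
      jw <- abs(jerk[lo:hi])
      pk <- lo + which.max(jw) - 1L         # which.max: earliest tie wins
      if (jw[pk - lo + 1L] > max(config$impact_jerk_min,
                                 4 * stats::median(abs(jerk)))) {
        # refine to the burst onset: the earliest interval in the window
        # whose jerk exceeds 20% of the peak; jerk[j] spans (j-1, j], so
        # the onset lies in that interval -- pick the end closer to the
        # rate zero crossing (an unbiased onset estimate)
        j <- lo + which(jw > 0.2 * jw[pk - lo + 1L])[1] - 1L
        i_on <- if (j > 1 && abs(tt[j - 1] - t_on) < abs(tt[j] - t_on))
          j - 1L else j
      }
      claw_on[k] <- tt[i_on]
    }
  }
  # snap claw-off to grid as well (events are sample-timestamped)
  claw_off <- tt[pmin(pmax(round(claw_off * rate - tt[1] * rate) + 1L, 1L), n)[!is.na(claw_off)]]
  claw_on <- claw_on[!is.na(claw_on)]
  # enforce minimum stance duration: stance k = [on_k, off_{k+1})
  if (length(claw_on) && length(claw_off)) {
    off_after <- vapply(claw_on, function(t0) {
      nx <- claw_off[claw_off > t0]
      if (length(nx)) nx[1] else NA_real_
    }, numeric(1))
    short <- !is.na(off_after) & (off_after - claw_on) < config$min_stance_s
    claw_on <- claw_on[!short]
  }
  list(claw_on = claw_on, claw_off = claw_off)
}

#' Validate and merge per-limb event lists
#'
#' @param events Named list per limb of `claw_on`/`claw_off` vectors.
#' @return The input, invisibly, after checking strict ordering and
#'   on/off alternation per limb.
#' @export
validate_events <- function(events) {
  for (limb in names(events)) {
    e <- events[[limb]]
    ev <- sort(c(e$claw_on, e$claw_off))
    typ <- c(rep("on", length(e$claw_on)),
             rep("off", length(e$claw_off)))[order(c(e$claw_on, e$claw_off))]
    if (any(diff(ev) <= 0))
      stop("validate_events: non-increasing events for ", limb)
    if (any(typ[-1] == typ[-length(typ)]))
      stop("validate_events: events do not alternate on/off for ", limb)
  }
  invisible(events)
}

#' Segment strides on the left-hind claw-on
#'
#' One stride per consecutive LH claw-on pair. Strides lacking a claw-on of
#' every limb inside their window (typically at recording boundaries) are
#' flagged excluded with reason `"incomplete limb coverage"`.
#'
#' @param events Named per-limb event list (must include LH).
#' @return data.frame: stride_id, start, end, included, exclusion_reason.
#' @export
segment_strides <- function(events) {
  lh <- sort(events$LH$claw_on)
  if (length(lh) < 2)
    return(data.frame(stride_id = integer(0), start = numeric(0),
                      end = numeric(0), included = logical(0),
                      exclusion_reason = character(0)))
  st <- data.frame(stride_id = seq_len(length(lh) - 1),
                   start = lh[-length(lh)], end = lh[-1],
                   included = TRUE, exclusion_reason = "")
  for (i in seq_len(nrow(st))) {
    for (limb in intersect(LIMBS, names(events))) {
      on <- events[[limb]]$claw_on
      on_in <- on[on >= st$start[i] & on < st$end[i]]
      ok <- length(on_in) > 0 &&
        any(events[[limb]]$claw_off > on_in[1])
      if (!ok) {
        st$included[i] <- FALSE
        st$exclusion_reason[i] <- "incomplete limb coverage"
        break
      }
    }
  }
  st
}

stance_intervals <- function(e) {
  # stance k = [on_k, first off after on_k)
  if (!length(e$claw_on)) return(cbind(on = numeric(0), off = numeric(0)))
  off <- vapply(e$claw_on, function(t0) {
    nx <- e$claw_off[e$claw_off > t0]
    if (length(nx)) nx[1] else NA_real_
  }, numeric(1))
  cbind(on = e$claw_on[!is.na(off)], off = off[!is.na(off)])
}

support_count_fun <- function(events) {
  ints <- lapply(events[LIMBS], stance_intervals)
  function(t) {
    cnt <- integer(length(t))
    for (limb in LIMBS) {
      iv <- ints[[limb]]
      for (r in seq_len(nrow(iv)))
        cnt <- cnt + (t >= iv[r, 1] & t < iv[r, 2])
    }
    cnt
  }
}

#' Screen segmented strides for stride-by-stride regularity
#'
#' Operationalizes the visual interval-selection rule: a stride is
#' excluded when any limb's stance duration within it deviates from that
#' limb's running median by more than a relative tolerance, or when the
#' instantaneous support count reaches 0 or 4 limbs for longer than a
#' tolerated duration. Contiguous included runs are reported as intervals
#' and capped at a configurable count per measurement (longest kept).
#'
#' @param strides Output of [segment_strides()].
#' @param events Per-limb event list.
#' @param config Configuration list.
#' @return `strides` with updated flags; the kept intervals (data.frame
#'   first/last stride_id) are attached as attribute `"intervals"`.
#' @export
regularity_screen <- function(strides, events, config = load_config()) {
  if (!nrow(strides)) return(strides)
  tol <- config$stance_tolerance
  for (limb in intersect(LIMBS, names(events))) {
    iv <- stance_intervals(events[[limb]])
    if (!nrow(iv)) next
    dur <- iv[, 2] - iv[, 1]
    k <- min(config$runmed_k, length(dur) - (length(dur) + 1) %% 2)
    ref <- if (length(dur) >= 3 && k >= 3) stats::runmed(dur, k) else
      rep(stats::median(dur), length(dur))
    for (r in seq_len(nrow(iv))) {
      if (abs(dur[r] - ref[r]) / ref[r] <= tol) next
      hit <- which(strides$start <= iv[r, 1] & strides$end > iv[r, 1])
      if (length(hit) && strides$included[hit]) {
        strides$included[hit] <- FALSE
        strides$exclusion_reason[hit] <-
          paste0("irregular stance (", limb, ")")
      }
    }
  }
  # support-count anomaly: time at 0 or 4 limbs beyond tolerance
  bounds <- sort(unique(unlist(lapply(events[LIMBS], function(e)
    c(e$claw_on, e$claw_off)))))
  scf <- support_count_fun(events)
  for (i in which(strides$included)) {
    b <- sort(unique(c(strides$start[i],
                       bounds[bounds > strides$start[i] & bounds < strides$end[i]],
                       strides$end[i])))
    mid <- (b[-1] + b[-length(b)]) / 2
    cnt <- scf(mid)
    bad <- sum((b[-1] - b[-length(b)])[cnt == 0L | cnt == 4L])
    if (bad > config$support_gap_tol_s) {
      strides$included[i] <- FALSE
      strides$exclusion_reason[i] <- "support anomaly"
    }
  }
  # contiguous included runs -> intervals, keep at most max_intervals (longest)
  r <- rle(strides$included)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(first = strides$stride_id[starts[r$values]],
                     last = strides$stride_id[ends[r$values]])
  if (nrow(runs) > config$max_intervals) {
    len <- runs$last - runs$first + 1L
    keep <- order(len, decreasing = TRUE)[seq_len(config$max_intervals)]
    drop <- setdiff(seq_len(nrow(runs)), keep)
    for (d in drop) {
      sel <- strides$stride_id >= runs$first[d] & strides$stride_id <= runs$last[d]
      strides$included[sel] <- FALSE
      strides$exclusion_reason[sel] <- "interval cap"
    }
    runs <- runs[sort(keep), , drop = FALSE]
  }
  attr(strides, "intervals") <- runs
  strides
}

#' Footfall chart table
#'
#' Per stride and limb, stance start/end as a fraction of the stride (the
#' tabular equivalent of a footfall bar chart).
#'
#' @param events Per-limb event list.
#' @param strides Stride index from [segment_strides()].
#' @return data.frame: stride_id, limb, start_frac, end_frac.
#' @export
footfall_chart <- function(events, strides) {
  out <- list()
  for (limb in intersect(LIMBS, names(events))) {
    iv <- stance_intervals(events[[limb]])
    for (i in seq_len(nrow(strides))) {
      s0 <- strides$start[i]; s1 <- strides$end[i]; d <- s1 - s0
      for (r in seq_len(nrow(iv))) {
        if (iv[r, 2] <= s0 || iv[r, 1] >= s1) next
        out[[length(out) + 1L]] <- data.frame(
          stride_id = strides$stride_id[i], limb = limb,
          start_frac = (max(iv[r, 1], s0) - s0) / d,
          end_frac = (min(iv[r, 2], s1) - s0) / d)
      }
    }
  }
  if (!length(out)) return(data.frame(stride_id = integer(0), limb = character(0),
                                      start_frac = numeric(0), end_frac = numeric(0)))
  do.call(rbind, out)
}
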