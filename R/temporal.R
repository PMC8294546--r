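BIPEDAL_PAIRS <- list("LF-RH" = c("LF", "RH"), "RF-LH" = c("RF", "LH"),
                      "LF-LH" = c("LF", "LH"), "RF-RH" = c("RF", "RH"))
TRIPEDAL_SETS <- list("no LF" = c("RF", "LH", "RH"), "no RF" = c("LF", "LH", "RH"),
                      "no LH" = c("LF", "RF", "RH"), "no RH" = c("LF", "RF", "LH"))

config_name <- function(limbs) {
  limbs <- sort(limbs)
  if (length(limbs) == 2) {
    for (nm in names(BIPEDAL_PAIRS))
      if (identical(sort(BIPEDAL_PAIRS[[nm]]), limbs)) return(nm)
  }
  if (length(limbs) == 3) {
    for (nm in names(TRIPEDAL_SETS))
      if (identical(sort(TRIPEDAL_SETS[[nm]]), limbs)) return(nm)
  }
  if (length(limbs) == 4) return("quadrupedal")
  if (length(limbs) == 1) return(paste0("single ", limbs))
  "none"
}

temporal_record <- function(stride_id, parameter, duration,
                            included = TRUE, reason = "") {
  data.frame(stride_id = stride_id, parameter = parameter,
             duration = duration, duty = NA_real_,
             included = included, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-stride stance and stride durations
#'
#' One stance record per limb per stride — the stance whose claw-on falls
#' inside the stride window; limbs without a claw-on in the window yield no
#' record (unequal stride counts between limbs then surface as missing
#' records, the same mechanism by which irregular epochs shed normalized
#' stance durations). One stride-duration record per stride. Negative
#' computed durations are flagged excluded, not dropped.
#'
#' @param events Per-limb event list.
#' @param strides Stride index from [segment_strides()].
#' @return data.frame of temporal records (stride_id, parameter, duration,
#'   duty placeholder, inclusion flag).
#' @export
stance_stride_durations <- function(events, strides) {
  out <- list()
  for (i in seq_len(nrow(strides))) {
    s0 <- strides$start[i]; s1 <- strides$end[i]
    sid <- strides$stride_id[i]
    dur <- s1 - s0
    out[[length(out) + 1L]] <- temporal_record(
      sid, "stride", dur, included = dur > 0,
      reason = if (dur > 0) "" else "negative duration")
    for (limb in intersect(LIMBS, names(events))) {
      on <- events[[limb]]$claw_on
      on <- on[on >= s0 & on < s1]
      if (!length(on)) next
      off <- events[[limb]]$claw_off
      off <- off[off > on[1]]
      if (!length(off)) next
      d <- off[1] - on[1]
      out[[length(out) + 1L]] <- temporal_record(
        sid, paste0("stance ", limb), d, included = d > 0,
        reason = if (d > 0) "" else "negative duration")
    }
  }
  do.call(rbind, out)
}

#' Bipedal, tripedal and quadrupedal support durations per stride
#'
#' Sweeps the union of all stance boundaries; every elementary interval
#' during which exactly the named pair (bipedal) or triple (tripedal) of
#' limbs is in stance contributes its length, same-configuration intervals
#' within a stride being summed. Quadrupedal and single-support intervals
#' are recorded separately and flagged. Intervals split by a stride boundary
#' are attributed to the stride containing their midpoint.
#'
#' @inheritParams stance_stride_durations
#' @return data.frame of temporal records.
#' @export
support_durations <- function(events, strides) {
  ints <- lapply(events[intersect(LIMBS, names(events))], stance_intervals)
  bounds <- sort(unique(unlist(lapply(ints, as.numeric))))
  if (length(bounds) < 2 || nrow(strides) == 0)
    return(temporal_record(integer(0), character(0), numeric(0))[0, ])
  lo <- bounds[-length(bounds)]; hi <- bounds[-1]
  mids <- (lo + hi) / 2
  member <- sapply(names(ints), function(limb) {
    iv <- ints[[limb]]
    inside <- rep(FALSE, length(mids))
    for (r in seq_len(nrow(iv)))
      inside <- inside | (mids >= iv[r, 1] & mids < iv[r, 2])
    inside
  })
  stride_of <- findInterval(mids, strides$start)
  stride_of[mids >= strides$end[nrow(strides)]] <- 0L
  acc <- list()
  for (j in seq_along(mids)) {
    k <- stride_of[j]
    if (k < 1) next
    limbs <- names(ints)[member[j, ]]
    nm <- config_name(limbs)
    if (nm == "none") next
    key <- paste(strides$stride_id[k], nm, sep = "\r")
    acc[[key]] <- (acc[[key]] %||% 0) + (hi[j] - lo[j])
  }
  if (!length(acc)) return(temporal_record(integer(0), character(0), numeric(0))[0, ])
  keys <- strsplit(names(acc), "\r", fixed = TRUE)
  df <- data.frame(stride_id = as.integer(vapply(keys, `[`, "", 1)),
                   parameter = vapply(keys, `[`, "", 2),
                   duration = unlist(acc, use.names = FALSE),
                   duty = NA_real_, included = TRUE, exclusion_reason = "",
                   stringsAsFactors = FALSE)
  odd <- df$parameter == "quadrupedal" | startsWith(df$parameter, "single")
  df$included[odd] <- FALSE
  df$exclusion_reason[odd] <- "non-standard support configuration"
  df[order(df$stride_id, df$parameter), ]
}

#' Speed normalization: durations to duty factors
#'
#' Divides every duration by the LH stride duration of its stride; records
#' with a resulting fraction below zero or above one are flagged excluded,
#' as are records without a matching LH stride.
#'
#' @param records Temporal records.
#' @param strides Stride index (LH claw-on boundaries).
#' @return `records` with the `duty` column filled.
#' @export
speed_normalize <- function(records, strides) {
  sd_by_id <- stats::setNames(strides$end - strides$start, strides$stride_id)
  T <- sd_by_id[as.character(records$stride_id)]
  records$duty <- records$duration / T
  miss <- is.na(T)
  if (any(miss)) {
    records$included[miss] <- FALSE
    records$exclusion_reason[miss] <- "no matching LH stride"
  }
  bad <- !miss & records$included & (records$duty < 0 | records$duty > 1)
  if (any(bad)) {
    records$included[bad] <- FALSE
    records$exclusion_reason[bad] <- "duty outside [0,1]"
  }
  records
}

#' Brute-force support-duration oracle by rasterization
#'
#' Samples stance membership on a fine regular grid and counts; used as an
#' independent cross-check of the interval sweep in [support_durations()].
#'
#' @inheritParams stance_stride_durations
#' @param step Raster step in seconds.
#' @return data.frame: stride_id, parameter, duration.
#' @export
support_durations_raster <- function(events, strides, step = 0.001) {
  ints <- lapply(events[intersect(LIMBS, names(events))], stance_intervals)
  out <- list()
  for (i in seq_len(nrow(strides))) {
    t <- seq(strides$start[i], strides$end[i] - step / 2, by = step) + step / 2
    member <- sapply(names(ints), function(limb) {
      iv <- ints[[limb]]
      inside <- rep(FALSE, length(t))
      for (r in seq_len(nrow(iv)))
        inside <- inside | (t >= iv[r, 1] & t < iv[r, 2])
      inside
    })
    nm <- apply(member, 1, function(m) config_name(names(ints)[m]))
    tab <- table(nm)
    for (p in names(tab)) {
      if (p == "none") next
      out[[length(out) + 1L]] <- data.frame(
        stride_id = strides$stride_id[i], parameter = p,
        duration = as.numeric(tab[[p]]) * step)
    }
  }
  do.call(rbind, out)
}
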