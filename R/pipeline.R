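write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full gait-analysis pipeline on one trial
#'
#' Event detection on the four limb streams, stride segmentation on the LH
#' claw-on, regularity screening, temporal parameters (stance/stride,
#' bipedal/tripedal support, speed normalization), distal-limb angle
#' reconstruction and extrema, upper-body vertical displacement, curve
#' summaries, bootstrap medians, and an exclusion ledger. All randomness is
#' governed by `config$seed`; with a fixed seed reruns are byte identical.
#'
#' @param trial A [gait_trial()].
#' @param config Configuration list from [load_config()].
#' @param out_dir Optional report directory; when given, delimited tables
#'   are written (`events.txt`, `strides.txt`, `temporal_records.txt`,
#'   `temporal_summary.txt`, `angle_records.txt`, `angle_summary.txt`,
#'   `curves/`, `exclusions.txt`, `log.txt`).
#' @return List of class `gait_report` with all intermediate and summary
#'   tables.
#' @export
run_pipeline <- function(trial, config = load_config(), out_dir = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  limbs_present <- intersect(LIMBS, names(trial$streams))
  if (length(limbs_present) < 4)
    stop("pipeline stage 'events' failed: all four limb streams are required",
         call. = FALSE)
  calib <- trial$calibration_window
  log <- c(sprintf("cowgait %s", as.character(utils::packageVersion("cowgait"))),
           sprintf("cow_id: %s  measurement_id: %s", trial$cow_id,
                   trial$measurement_id),
           sprintf("seed: %d", config$seed),
           sprintf("config: %s", paste(names(config), vapply(
             config, function(v) paste(format(v), collapse = ","),
             character(1)), sep = "=", collapse = "; ")))

  events <- stage("events", {
    ev <- lapply(trial$streams[LIMBS], detect_claw_events, config = config,
                 calibration_window = calib)
    validate_events(ev)
  })
  strides <- stage("segmentation", segment_strides(events))
  if (!nrow(strides))
    stop("pipeline stage 'segmentation' failed: fewer than 2 LH claw-on events",
         call. = FALSE)
  strides <- stage("regularity", regularity_screen(strides, events, config))

  temporal <- stage("temporal", {
    rec <- rbind(stance_stride_durations(events, strides),
                 support_durations(events, strides))
    # drop records of screened-out strides from summaries, keep in ledger
    rec$included <- rec$included & rec$stride_id %in%
      strides$stride_id[strides$included]
    speed_normalize(rec, strides)
  })

  angles <- stage("limb angles", {
    out <- list()
    for (limb in LIMBS) {
      ang <- complementary_filter_angle(trial$streams[[limb]], config, calib)
      out[[limb]] <- extract_angle_extrema(ang, trial$streams[[limb]]$time,
                                           strides, events, limb)
    }
    out
  })
  angle_records <- do.call(rbind, lapply(angles, function(a) {
    a2 <- a; attr(a2, "curves") <- NULL; a2
  }))

  angle_curves <- stage("angle curves", {
    lapply(angles, normalize_angle_curves, strides = strides, config = config)
  })

  upper_present <- intersect(UPPER_LOCATIONS, names(trial$streams))
  vdisp_curves <- stage("vertical displacement", {
    out <- list()
    for (loc in upper_present) {
      d <- vertical_displacement(trial$streams[[loc]], strides, config, calib)
      out[[loc]] <- cut_and_normalize(d, trial$streams[[loc]]$time, strides,
                                      config)
    }
    out
  })

  summaries <- stage("inference", {
    inc <- temporal[temporal$included, ]
    pars <- unique(inc$parameter)
    tsum <- do.call(rbind, lapply(pars, function(p) {
      v <- inc[inc$parameter == p, ]
      if (nrow(v) < 2) return(NULL)
      cis <- bootstrap_median_ci(v$duration, B = config$bootstrap_reps,
                                 seed = config$seed, level = config$ci_level)
      cid <- bootstrap_median_ci(v$duty[is.finite(v$duty)],
                                 B = config$bootstrap_reps,
                                 seed = config$seed, level = config$ci_level)
      data.frame(parameter = p, n_strides = cis$n,
                 median_s = cis$median, ci_low_s = cis$ci_low,
                 ci_high_s = cis$ci_high,
                 median_duty = cid$median, ci_low_duty = cid$ci_low,
                 ci_high_duty = cid$ci_high)
    }))
    ainc <- angle_records[angle_records$included, ]
    asum <- do.call(rbind, lapply(split(ainc, ainc$limb), function(v) {
      if (nrow(v) < 2) return(NULL)
      cp <- bootstrap_median_ci(v$max_protraction, B = config$bootstrap_reps,
                                seed = config$seed, level = config$ci_level)
      cr <- bootstrap_median_ci(v$max_retraction, B = config$bootstrap_reps,
                                seed = config$seed, level = config$ci_level)
      data.frame(limb = v$limb[1], n_strides = cp$n,
                 protraction_deg = cp$median, prot_ci_low = cp$ci_low,
                 prot_ci_high = cp$ci_high,
                 retraction_deg = cr$median, ret_ci_low = cr$ci_low,
                 ret_ci_high = cr$ci_high)
    }))
    list(temporal = tsum, angles = asum)
  })

  curve_summaries <- stage("curve summaries", {
    cs <- list()
    for (limb in names(angle_curves))
      if (!is.null(angle_curves[[limb]]$curves) &&
          nrow(angle_curves[[limb]]$curves) > 0)
        cs[[paste0("angle_", limb)]] <-
          summarize_curves(angle_curves[[limb]], events, strides,
                           metric = config$curve_metric)
    for (loc in names(vdisp_curves))
      if (!is.null(vdisp_curves[[loc]]$curves) &&
          nrow(vdisp_curves[[loc]]$curves) > 0)
        cs[[paste0("vdisp_", loc)]] <-
          summarize_curves(vdisp_curves[[loc]], events, strides,
                           metric = config$curve_metric)
    cs
  })

  exclusions <- stage("exclusion ledger", {
    src <- rbind(
      data.frame(stage = "stride screen", reason = strides$exclusion_reason,
                 flag = !strides$included),
      data.frame(stage = "temporal", reason = temporal$exclusion_reason,
                 flag = !temporal$included),
      data.frame(stage = "angles", reason = angle_records$exclusion_reason,
                 flag = !angle_records$included))
    src$reason[!src$flag] <- "(included)"
    agg <- stats::aggregate(flag ~ stage + reason, src, length)
    names(agg)[3] <- "count"
    agg[order(agg$stage, agg$reason), ]
  })

  report <- structure(list(
    cow_id = trial$cow_id, measurement_id = trial$measurement_id,
    events = events, strides = strides, temporal = temporal,
    angle_records = angle_records, angle_curves = angle_curves,
    vdisp_curves = vdisp_curves,
    temporal_summary = summaries$temporal, angle_summary = summaries$angles,
    curve_summaries = curve_summaries, exclusions = exclusions,
    footfalls = mean_footfall_fractions(events, strides),
    config = config, log = log), class = "gait_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

events_table <- function(events) {
  do.call(rbind, lapply(names(events), function(l) {
    e <- events[[l]]
    d <- rbind(data.frame(limb = l, event = "claw_on", time_s = e$claw_on),
               data.frame(limb = l, event = "claw_off", time_s = e$claw_off))
    d[order(d$time_s), ]
  }))
}

curves_table <- function(cs, unit_scale = 1) {
  m <- cs$curves * unit_scale
  colnames(m) <- paste0("p", seq_len(ncol(m)))
  cbind(data.frame(stride_id = cs$stride_id), as.data.frame(m))
}

#' Write a pipeline report as delimited text tables
#'
#' @param report A `gait_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "curves"), showWarnings = FALSE,
             recursive = TRUE)
  prov <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    cbind(data.frame(cow_id = report$cow_id,
                     measurement_id = report$measurement_id), df)
  }
  write_tsv(prov(events_table(report$events)),
            file.path(out_dir, "events.txt"))
  write_tsv(prov(report$strides), file.path(out_dir, "strides.txt"))
  write_tsv(prov(report$temporal), file.path(out_dir, "temporal_records.txt"))
  if (!is.null(report$temporal_summary))
    write_tsv(prov(report$temporal_summary),
              file.path(out_dir, "temporal_summary.txt"))
  write_tsv(prov(report$angle_records),
            file.path(out_dir, "angle_records.txt"))
  if (!is.null(report$angle_summary))
    write_tsv(prov(report$angle_summary),
              file.path(out_dir, "angle_summary.txt"))
  write_tsv(prov(report$footfalls), file.path(out_dir, "footfalls.txt"))
  write_tsv(prov(report$exclusions), file.path(out_dir, "exclusions.txt"))
  scale <- if (identical(report$config$displacement_unit, "mm")) 1000 else 1
  for (limb in names(report$angle_curves)) {
    cs <- report$angle_curves[[limb]]
    if (is.null(cs$curves) || !nrow(cs$curves)) next
    write_tsv(prov(curves_table(cs)),
              file.path(out_dir, "curves", paste0("angle_", limb, ".txt")))
  }
  for (loc in names(report$vdisp_curves)) {
    cs <- report$vdisp_curves[[loc]]
    if (is.null(cs$curves) || !nrow(cs$curves)) next
    write_tsv(prov(curves_table(cs, scale)),
              file.path(out_dir, "curves", paste0("vdisp_", loc, ".txt")))
  }
  for (nm in names(report$curve_summaries)) {
    s <- report$curve_summaries[[nm]]
    df <- data.frame(group = nm, stat = c("median", "mad"),
                     most_typical_id = s$most_typical_id, n = s$n)
    sc <- if (startsWith(nm, "vdisp")) scale else 1
    m <- rbind(s$median_curve, s$mad_curve) * sc
    colnames(m) <- paste0("p", seq_len(ncol(m)))
    write_tsv(prov(cbind(df, as.data.frame(m))),
              file.path(out_dir, "curves", paste0("summary_", nm, ".txt")))
  }
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report> cow %s / %s: %d strides (%d included)\n",
              x$cow_id, x$measurement_id, nrow(x$strides),
              sum(x$strides$included)))
  if (!is.null(x$temporal_summary)) {
    cat("temporal summary (s / duty):\n")
    print(x$temporal_summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
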