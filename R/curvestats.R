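#' Stride-normalize per-stride angle curves to 100 samples
#'
#' Resamples every included stride's re-zeroed angle segment to a fixed
#' number of points on the 0-100% stride scale (0 = the stride's LH
#' claw-on, 100 = the next).
#'
#' @param extrema Output of [extract_angle_extrema()] (carries the raw
#'   per-stride curves as an attribute).
#' @param strides Stride index.
#' @param config Configuration list.
#' @return A `curve_set` (matrix of curves plus stride ids).
#' @export
normalize_angle_curves <- function(extrema, strides, config = load_config()) {
  curves <- attr(extrema, "curves")
  nc <- config$n_curve_samples
  keep <- extrema$stride_id[extrema$included]
  rows <- list(); ids <- integer(0)
  for (sid in keep) {
    cv <- curves[[as.character(sid)]]
    if (is.null(cv)) next
    i <- which(strides$stride_id == sid)
    rows[[length(rows) + 1L]] <-
      resample_curve(cv$time, cv$angle, strides$start[i], strides$end[i], nc)
    ids <- c(ids, sid)
  }
  structure(list(curves = do.call(rbind, rows), stride_id = ids),
            class = "curve_set")
}

curve_distance_matrix <- function(mat, metric = c("rms", "mae")) {
  metric <- match.arg(metric)
  if (metric == "rms") {
    as.matrix(stats::dist(mat, method = "euclidean")) / sqrt(ncol(mat))
  } else {
    as.matrix(stats::dist(mat, method = "manhattan")) / ncol(mat)
  }
}

#' Most typical curve of a curve set
#'
#' Returns the member minimizing the summed pointwise distance (default:
#' root-mean-square difference over the 100 samples) to all other members;
#' ties break to the earliest stride id.
#'
#' @param cs A `curve_set` or a plain matrix (rows = curves).
#' @param metric `"rms"` or `"mae"`.
#' @return The winning member's stride id (or row index for a bare matrix).
#' @export
most_typical_curve <- function(cs, metric = c("rms", "mae")) {
  mat <- if (inherits(cs, "curve_set")) cs$curves else as.matrix(cs)
  ids <- if (inherits(cs, "curve_set")) cs$stride_id else seq_len(nrow(mat))
  if (is.null(mat) || nrow(mat) == 0) stop("most_typical_curve: empty curve set")
  if (nrow(mat) == 1) return(ids[1])
  tot <- rowSums(curve_distance_matrix(mat, match.arg(metric)))
  ord <- order(ids)
  ids[ord][which.min(tot[ord])]   # earliest id wins ties
}

#' Pointwise median and MAD curves
#'
#' The median curve is the pointwise median of the set; the MAD curve the
#' pointwise median of absolute deviations from that median (no consistency
#' scaling).
#'
#' @param cs A `curve_set` or matrix.
#' @return List with `median_curve` and `mad_curve`.
#' @export
median_mad_curves <- function(cs) {
  mat <- if (inherits(cs, "curve_set")) cs$curves else as.matrix(cs)
  if (is.null(mat) || nrow(mat) == 0) stop("median_mad_curves: empty curve set")
  med <- apply(mat, 2, stats::median)
  madc <- apply(abs(sweep(mat, 2, med)), 2, stats::median)
  list(median_curve = med, mad_curve = madc)
}

#' Mean footfall timings as percent of stride
#'
#' Per limb, the mean of (event time - stride start) / stride duration x 100
#' over all included strides, for events landing inside the stride window
#' [0, 100) — the wrapped stance marks drawn under stride-normalized curves
#' (a stance crossing the stride boundary contributes its claw-off near the
#' start of the next stride).
#'
#' @param events Per-limb event list.
#' @param strides Stride index.
#' @return data.frame: limb, mean_claw_on_pct, mean_claw_off_pct, n.
#' @export
mean_footfall_fractions <- function(events, strides) {
  inc <- strides[strides$included, , drop = FALSE]
  out <- list()
  for (limb in intersect(LIMBS, names(events))) {
    fons <- c(); foffs <- c()
    for (i in seq_len(nrow(inc))) {
      d <- inc$end[i] - inc$start[i]
      fr_on <- (events[[limb]]$claw_on - inc$start[i]) / d * 100
      fr_off <- (events[[limb]]$claw_off - inc$start[i]) / d * 100
      fons <- c(fons, fr_on[fr_on >= 0 & fr_on < 100])
      foffs <- c(foffs, fr_off[fr_off >= 0 & fr_off < 100])
    }
    out[[length(out) + 1L]] <- data.frame(
      limb = limb, mean_claw_on_pct = mean(fons),
      mean_claw_off_pct = mean(foffs), n = nrow(inc))
  }
  do.call(rbind, out)
}

#' Summarize a curve set
#'
#' Median curve, MAD band, most typical member and mean footfall marks in
#' one object, the building block of per-limb and per-cow curve reports.
#'
#' @param cs A `curve_set`.
#' @param events,strides For the footfall marks (optional).
#' @param metric Distance metric for the most typical curve.
#' @return List of class `curve_summary`.
#' @export
summarize_curves <- function(cs, events = NULL, strides = NULL,
                             metric = c("rms", "mae")) {
  mm <- median_mad_curves(cs)
  ff <- if (!is.null(events) && !is.null(strides))
    mean_footfall_fractions(events, strides) else NULL
  structure(list(median_curve = mm$median_curve, mad_curve = mm$mad_curve,
                 most_typical_id = most_typical_curve(cs, match.arg(metric)),
                 n = nrow(cs$curves), footfalls = ff),
            class = "curve_summary")
}
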