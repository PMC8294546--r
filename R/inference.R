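#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric vector (included records only).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed; the same seed reproduces the interval exactly.
#' @param level Confidence level.
#' @return data.frame: median, ci_low, ci_high, n, method.
#' @export
bootstrap_median_ci <- function(values, B = 2000L, seed = 1L, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("bootstrap_median_ci: need at least 2 values")
  med <- stats::median(values)
  if (diff(range(values)) == 0) {
    return(data.frame(median = med, ci_low = med, ci_high = med,
                      n = n, method = "bootstrap"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  res <- matrix(sample(values, n * B, replace = TRUE), n, B)
  meds <- apply(res, 2, stats::median)
  a <- (1 - level) / 2
  ci <- stats::quantile(meds, c(a, 1 - a), names = FALSE)
  data.frame(median = med, ci_low = ci[1], ci_high = ci[2],
             n = n, method = "bootstrap")
}

#' Linear mixed model comparing limbs (or limb pairs)
#'
#' Fits `value ~ 0 + group (+ stride-duration deviation) + (1 | cow)` by
#' REML, the covariate being each stride's deviation from the median LH
#' stride duration; the covariate is omitted for speed-normalized (duty)
#' responses. Reports per-group estimated means with Wald confidence
#' intervals, a pairwise CI non-overlap flag (the inferential device used
#' for hypothesis testing), and exports residuals and random-effect
#' estimates for external diagnostics. A singular fit, or fewer than two
#' cows, falls back to group-wise bootstrap intervals with the method
#' recorded.
#'
#' @param df data.frame with columns `value`, `group`, `cow_id` and (unless
#'   `normalized`) `stride_dev`.
#' @param normalized Logical: response is a duty factor (covariate dropped).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap fallback.
#' @return List of class `limb_model`: `estimates` (group, estimate, ci_low,
#'   ci_high, n, method), `nonoverlap` (logical matrix), `residuals`,
#'   `ranef`, `model`.
#' @export
fit_limb_model <- function(df, normalized = FALSE, level = 0.95, seed = 1L) {
  stopifnot(all(c("value", "group", "cow_id") %in% names(df)))
  df <- df[is.finite(df$value), , drop = FALSE]
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2) stop("fit_limb_model: need at least 2 groups")
  fallback <- function(msg) {
    warning("fit_limb_model: ", msg, "; falling back to group-wise bootstrap")
    est <- do.call(rbind, lapply(levels(df$group), function(g) {
      ci <- bootstrap_median_ci(df$value[df$group == g], seed = seed, level = level)
      data.frame(group = g, estimate = ci$median, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, n = ci$n, method = "bootstrap")
    }))
    structure(list(estimates = est, nonoverlap = nonoverlap_matrix(est),
                   residuals = NULL, ranef = NULL, model = NULL),
              class = "limb_model")
  }
  if (length(unique(df$cow_id)) < 2) return(fallback("fewer than 2 cows"))
  form <- if (normalized || is.null(df$stride_dev))
    value ~ 0 + group + (1 | cow_id) else
      value ~ 0 + group + stride_dev + (1 | cow_id)
  fit <- tryCatch(lme4::lmer(form, data = df, REML = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) return(fallback("model failed to fit"))
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("fit_limb_model: singular fit (random intercept variance near 0)")
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  gidx <- grep("^group", names(fe))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- data.frame(group = sub("^group", "", names(fe)[gidx]),
                    estimate = unname(fe[gidx]),
                    ci_low = unname(fe[gidx] - z * sqrt(diag(vc)[gidx])),
                    ci_high = unname(fe[gidx] + z * sqrt(diag(vc)[gidx])),
                    n = as.vector(table(df$group)[sub("^group", "", names(fe)[gidx])]),
                    method = "mixed_model")
  structure(list(estimates = est, nonoverlap = nonoverlap_matrix(est),
                 residuals = stats::residuals(fit),
                 ranef = lme4::ranef(fit)$cow_id,
                 model = fit),
            class = "limb_model")
}

nonoverlap_matrix <- function(est) {
  k <- nrow(est)
  m <- matrix(FALSE, k, k, dimnames = list(est$group, est$group))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j)
      m[i, j] <- est$ci_low[i] > est$ci_high[j] || est$ci_high[i] < est$ci_low[j]
  m
}

#' @export
print.limb_model <- function(x, ...) {
  cat("<limb_model> (", x$estimates$method[1], ")\n", sep = "")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
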