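#' Control-anchored relative normalization
#'
#' Divides a measurement column by the mean value of the control group at the
#' baseline IOP offset, giving "relative" units in which the control baseline
#' mean is 1 by construction (the convention used for relative SC volume).
#'
#' @param measurements data.frame of acquisition-level measurements with at
#'   least `group`, `delta_iop_mmHg` and the value column.
#' @param control_group label of the control group.
#' @param baseline_level baseline IOP offset (default 0 mmHg).
#' @param value_col measurement column to normalize (default `volume_um3`).
#' @param scheme label recorded in the output (default `"relative_volume"`).
#' @return `measurements` with columns `value` (normalized) and `scheme`
#'   appended.
#' @export
normalize_relative <- function(measurements, control_group,
                               baseline_level = 0,
                               value_col = "volume_um3",
                               scheme = "relative_volume") {
  stopifnot(value_col %in% names(measurements))
  base <- measurements[[value_col]][
    measurements$group == control_group &
      measurements$delta_iop_mmHg == baseline_level]
  base <- base[is.finite(base)]
  if (length(base) == 0)
    stop("no ", control_group, " measurements at baseline offset ",
         baseline_level, " mmHg to anchor the normalization")
  measurements$value <- measurements[[value_col]] / mean(base)
  measurements$scheme <- scheme
  measurements
}

#' Per-eye normalization to a reference IOP offset
#'
#' Divides each eye's values by that eye's mean value at the reference IOP
#' offset (default -10 mmHg, i.e. 10 mmHg below baseline), so every eye's
#' series averages exactly 1 at the reference level. Used for normalized
#' volume and normalized height.
#'
#' @param measurements data.frame with at least `eye_id`, `delta_iop_mmHg`
#'   and the value column.
#' @param reference_level reference IOP offset (default -10 mmHg).
#' @param value_col measurement column to normalize.
#' @param scheme label recorded in the output.
#' @return `measurements` with `value` and `scheme` columns appended.
#' @export
normalize_per_eye <- function(measurements, reference_level = -10,
                              value_col = "volume_um3",
                              scheme = "normalized_volume") {
  stopifnot(value_col %in% names(measurements))
  eyes <- unique(measurements$eye_id)
  ref_mean <- vapply(eyes, function(e) {
    v <- measurements[[value_col]][
      measurements$eye_id == e &
        measurements$delta_iop_mmHg == reference_level]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  missing <- eyes[is.na(ref_mean)]
  if (length(missing))
    stop("no measurements at reference offset ", reference_level,
         " mmHg for eye(s): ", paste(missing, collapse = ", "))
  measurements$value <-
    measurements[[value_col]] / ref_mean[match(measurements$eye_id, eyes)]
  measurements$scheme <- scheme
  measurements
}

#' Fit the linear IOP response of a morphometric measurement
#'
#' Ordinary least squares of a (possibly normalized) SC measurement on the
#' IOP offset, pooling all eyes and repeat acquisitions of one group. The
#' slope is the measurement change per mmHg; its 95% confidence interval is
#' t-based with `n - 2` residual degrees of freedom.
#'
#' @param formula model formula, e.g. `value ~ delta_iop_mmHg`; the right
#'   side must be a single numeric predictor.
#' @param data data.frame of one group's measurements.
#' @param level confidence level for the slope interval (default 0.95).
#' @return object of class `iop_response`: a list with `slope`, `intercept`,
#'   `slope_se`, `ci` (length-2), `residual_df`, `n_points`, `sigma`, the
#'   underlying `lm` fit and the variable names.
#' @examples
#' d <- data.frame(delta_iop_mmHg = rep(c(-10, -5, 0, 5, 10), 3))
#' d$value <- 1 - 0.03 * d$delta_iop_mmHg
#' coef(iop_response(value ~ delta_iop_mmHg, d))
#' @export
iop_response <- function(formula, data, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2 || !is.numeric(mf[[2]]))
    stop("formula must have one numeric predictor (the IOP offset)")
  x <- mf[[2]]
  if (length(x) < 3) stop("at least 3 points are required")
  if (length(unique(x)) < 2)
    stop("all points are at one IOP offset; the slope is not identifiable")
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  slope <- stats::coef(fit)[2]
  se <- sm$coefficients[2, 2]
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  structure(list(
    slope = unname(slope), intercept = unname(stats::coef(fit)[1]),
    slope_se = unname(se),
    ci = unname(slope + c(-1, 1) * tcrit * se),
    level = level,
    residual_df = fit$df.residual, n_points = length(x),
    sigma = sm$sigma, lm = fit,
    response = names(mf)[1], predictor = names(mf)[2],
    call = match.call()
  ), class = "iop_response")
}

#' @export
print.iop_response <- function(x, ...) {
  cat("Linear IOP response fit\n")
  cat(sprintf("  %s ~ %s, n = %d (residual df %d)\n", x$response,
              x$predictor, x$n_points, x$residual_df))
  cat(sprintf("  slope: %.4g per mmHg  [%.4g, %.4g] %d%% CI\n",
              x$slope, x$ci[1], x$ci[2], round(100 * x$level)))
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  invisible(x)
}

#' @export
summary.iop_response <- function(object, ...) {
  out <- list(fit = object, lm_summary = summary(object$lm))
  class(out) <- "summary.iop_response"
  out
}

#' @export
print.summary.iop_response <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying least-squares fit:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.iop_response <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.iop_response <- function(object, parm = "slope", level = 0.95, ...) {
  tcrit <- stats::qt(1 - (1 - level) / 2, df = object$residual_df)
  m <- rbind(intercept = object$intercept +
               c(-1, 1) * tcrit * summary(object$lm)$coefficients[1, 2],
             slope = object$slope + c(-1, 1) * tcrit * object$slope_se)
  colnames(m) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  m[parm, , drop = FALSE]
}

#' @export
predict.iop_response <- function(object, newdata = NULL,
                                 interval = c("none", "confidence"), ...) {
  interval <- match.arg(interval)
  stats::predict(object$lm, newdata = newdata, interval = interval,
                 level = object$level)
}

#' @export
residuals.iop_response <- function(object, ...) stats::residuals(object$lm)

#' Plot an IOP response fit
#'
#' Scatter of the pooled measurements against the IOP offset with the fitted
#' line and the pointwise mean-response confidence band.
#'
#' @param x an [iop_response()] fit.
#' @param band draw the confidence band (default TRUE).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.iop_response <- function(x, band = TRUE, ...) {
  mf <- stats::model.frame(x$lm)
  xi <- mf[[2]]; yi <- mf[[1]]
  graphics::plot(xi, yi, xlab = paste(x$predictor, "(mmHg)"),
                 ylab = x$response, ...)
  xg <- seq(min(xi), max(xi), length.out = 100)
  nd <- stats::setNames(data.frame(xg), x$predictor)
  pr <- stats::predict(x$lm, nd, interval = "confidence", level = x$level)
  if (band) {
    graphics::polygon(c(xg, rev(xg)), c(pr[, "lwr"], rev(pr[, "upr"])),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  graphics::lines(xg, pr[, "fit"], col = "steelblue", lwd = 2)
  invisible(x)
}

#' Test whether two groups' IOP-response slopes differ
#'
#' ANCOVA-style slope comparison: a single pooled linear model
#' `value ~ iop * group` is fitted and the two-sided t-test on the
#' interaction coefficient gives the p-value. The interaction estimate equals
#' the difference of the two per-group OLS slopes exactly. A degenerate
#' zero-residual model (both groups on exact lines) is reported as "no
#' difference" with p = 1 when the slopes coincide.
#'
#' @param formula e.g. `value ~ delta_iop_mmHg`.
#' @param data measurements of both groups.
#' @param group name of the grouping column in `data` (default `"group"`);
#'   must have exactly two levels. Group A is the first level.
#' @return object of class `slope_comparison`: list with `groups`,
#'   `slope_a`, `slope_b`, `delta_slope` (= a - b), `se`, `t`, `p_value`,
#'   `residual_df`, `test_description`, and the pooled `lm`.
#' @export
compare_slopes <- function(formula, data, group = "group") {
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("slope comparison requires exactly two groups")
  mf <- stats::model.frame(formula, data)
  iop <- names(mf)[2]
  resp <- names(mf)[1]
  d <- data.frame(.y = mf[[1]], .x = mf[[2]], .g = g)
  for (lv in levels(g)) {
    xs <- d$.x[d$.g == lv]
    if (length(xs) < 3 || length(unique(xs)) < 2)
      stop("group ", lv, " has too few points or IOP offsets for a fit")
  }
  fit <- stats::lm(.y ~ .x * .g, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients
  irow <- grep(":", rownames(cf))
  est <- unname(cf[irow, 1]) # slope(level2) - slope(level1)
  se <- unname(cf[irow, 2])
  tval <- unname(cf[irow, 3])
  p <- unname(cf[irow, 4])
  # both groups on exact lines: residual variance is numerical noise and the
  # t-test is meaningless; report "no difference" (p = 1) when the slopes
  # agree to the same numerical scale
  tol <- 1e-8 * max(abs(d$.y), 1)
  if (!is.finite(p) || sm$sigma < tol) {
    p <- if (abs(est) < tol) 1 else 0
    tval <- NA_real_
  }
  per_group <- vapply(levels(g), function(lv) {
    dd <- d[d$.g == lv, ]
    unname(stats::coef(stats::lm(.y ~ .x, dd))[2])
  }, numeric(1))
  per_group <- unname(per_group)
  structure(list(
    groups = levels(g),
    slope_a = per_group[1], slope_b = per_group[2],
    delta_slope = per_group[1] - per_group[2],
    se = unname(se), t = unname(tval), p_value = unname(p),
    residual_df = fit$df.residual,
    response = resp, predictor = iop, lm = fit,
    test_description = paste("two-sided t-test on the IOP-by-group",
                             "interaction of the pooled linear model")
  ), class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("IOP-response slope comparison\n")
  cat(sprintf("  %s: slope %.4g per mmHg\n", x$groups[1], x$slope_a))
  cat(sprintf("  %s: slope %.4g per mmHg\n", x$groups[2], x$slope_b))
  cat(sprintf("  difference (a - b): %.4g, P = %.3g (%s, df %d)\n",
              x$delta_slope, x$p_value, x$test_description, x$residual_df))
  invisible(x)
}

#' Per-IOP-level group contrasts with Sidak adjustment
#'
#' Two-factor (group x IOP level) linear model on the replicate values, with
#' the group difference tested at each IOP level using the pooled residual
#' variance, and per-level p-values Sidak-adjusted over the number of levels
#' tested: `p_adj = 1 - (1 - p)^m`.
#'
#' @param data measurements of both groups.
#' @param value,group,level column names of the response, the two-group
#'   factor, and the IOP level.
#' @return data.frame with one row per level present in both groups:
#'   `delta_iop_mmHg`, `diff` (group A - group B), `se`, `t`, `df`,
#'   `p_value`, `p_adj`, `n_a`, `n_b`. Levels missing from one group are
#'   skipped with a warning.
#' @export
per_level_comparison <- function(data, value = "value", group = "group",
                                 level = "delta_iop_mmHg") {
  stopifnot(all(c(value, group, level) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("per-level comparison requires two groups")
  d <- data.frame(.y = data[[value]], .g = g, .l = data[[level]])
  levels_all <- sort(unique(d$.l))
  ok <- vapply(levels_all, function(lv) {
    counts <- table(d$.g[d$.l == lv])
    length(counts) == 2 && all(counts >= 2)
  }, logical(1))
  if (any(!ok)) {
    warning("skipping IOP level(s) without >= 2 replicates in both groups: ",
            paste(levels_all[!ok], collapse = ", "))
    d <- d[d$.l %in% levels_all[ok], ]
  }
  levels_used <- levels_all[ok]
  m <- length(levels_used)
  if (m == 0) stop("no IOP level has replicates in both groups")
  d$.lf <- factor(d$.l)
  fit <- stats::lm(.y ~ .g * .lf, data = d)
  sigma2 <- summary(fit)$sigma^2
  df <- fit$df.residual
  out <- lapply(levels_used, function(lv) {
    ya <- d$.y[d$.l == lv & d$.g == levels(g)[1]]
    yb <- d$.y[d$.l == lv & d$.g == levels(g)[2]]
    diff <- mean(ya) - mean(yb)
    se <- sqrt(sigma2 * (1 / length(ya) + 1 / length(yb)))
    tval <- if (se > 0) diff / se else if (abs(diff) < 1e-12) 0 else Inf
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(delta_iop_mmHg = lv, diff = diff, se = se, t = tval, df = df,
               p_value = p, n_a = length(ya), n_b = length(yb))
  })
  out <- do.call(rbind, out)
  out$p_adj <- sidak_adjust(out$p_value, m)
  out[, c("delta_iop_mmHg", "diff", "se", "t", "df", "p_value", "p_adj",
          "n_a", "n_b")]
}
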