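#' Measure every acquisition of an experiment
#'
#' Runs the full morphometry pipeline (component extraction, SC part
#' selection, ellipse fitting, per-section and per-series aggregation) over
#' every stack of a generated or on-disk experiment and returns the
#' acquisition-level measurement table consumed by the normalization and
#' regression functions.
#'
#' @param experiment either the list returned by [generate_experiment()] or
#'   a directory containing `manifest.csv` and the written stacks.
#' @param window_um analyzed length (default 1500 um).
#' @param min_area_frac SC part-inclusion threshold (default 0.20).
#' @return data.frame with one row per (eye, IOP offset, repeat): the
#'   manifest keys plus the [series_morphometry()] columns.
#' @export
analyze_experiment <- function(experiment, window_um = 1500,
                               min_area_frac = 0.20) {
  if (is.character(experiment)) {
    man_path <- file.path(experiment, "manifest.csv")
    if (!file.exists(man_path))
      stop("no manifest.csv found under ", experiment)
    manifest <- utils::read.csv(man_path, check.names = FALSE)
    get_stack <- function(i)
      read_mask_stack(file.path(experiment, manifest$stack_path[i]))
  } else {
    manifest <- experiment$manifest
    get_stack <- function(i) experiment$stacks[[i]]
  }
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    stack <- get_stack(i)
    sections <- stack_morphometry(stack, min_area_frac = min_area_frac)
    cbind(manifest[i, c("eye_id", "group", "delta_iop_mmHg", "repeat")],
          series_morphometry(sections, stack$bscan_spacing_um,
                             window_um = window_um))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte-Carlo slope-recovery benchmark
#'
#' Repeatedly simulates an IOP experiment from a phantom's deformation model
#' and checks how well [iop_response()] recovers the generating volume slope.
#' Two modes:
#'
#' * `"analytic"` (default): per experiment, acquisition volumes are the
#'   phantom's analytic ground truth plus Gaussian measurement noise with SD
#'   `noise_frac` of the baseline volume — fast, suitable for hundreds of
#'   replicates.
#' * `"raster"`: per experiment, mask stacks are generated (with the
#'   phantom's boundary jitter) and pushed through the full image pipeline
#'   ([analyze_experiment()]); slow, exercises every stage end to end.
#'
#' @param spec a [phantom_spec()]; its deformation slopes are the truth.
#' @param n_experiments number of simulated experiments.
#' @param delta_iop_levels IOP offsets visited (default -10...+10 mmHg).
#' @param repeats_per_level repeats per offset (default 3).
#' @param noise_frac measurement-noise SD as a fraction of baseline volume
#'   (analytic mode; default 0.05).
#' @param mode `"analytic"` or `"raster"`.
#' @param seed RNG seed.
#' @return list with `fits` (data.frame: experiment, slope_hat, ci_lo,
#'   ci_hi, covered, rel_abs_error), `true_slope` (um^3/mmHg), `coverage`
#'   (fraction of experiments whose 95% CI contains the truth) and
#'   `mean_rel_abs_error`.
#' @export
recover_slopes <- function(spec, n_experiments = 200,
                           delta_iop_levels = c(-10, -5, 0, 5, 10),
                           repeats_per_level = 3, noise_frac = 0.05,
                           mode = c("analytic", "raster"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "phantom_spec"))
  true_slope <- phantom_volume_slope(spec)
  geom <- phantom_geometry(spec, delta_iop_levels)
  v0 <- phantom_geometry(spec, 0)$volume_um3
  seeds <- derive_seeds(seed, n_experiments)
  rows <- lapply(seq_len(n_experiments), function(i) {
    d <- rep(delta_iop_levels, each = repeats_per_level)
    if (mode == "analytic") {
      v <- with_seed(seeds[i],
        rep(geom$volume_um3, each = repeats_per_level) +
          stats::rnorm(length(d), sd = noise_frac * v0))
    } else {
      design <- iop_experiment_design(list(g = spec),
                                      delta_iop_levels_mmHg = delta_iop_levels,
                                      repeats_per_level = repeats_per_level)
      exp_i <- generate_experiment(design, seed = seeds[i])
      meas <- analyze_experiment(exp_i, window_um = spec$length_um)
      d <- meas$delta_iop_mmHg
      v <- meas$volume_um3
    }
    fit <- iop_response(volume_um3 ~ delta_iop_mmHg,
                        data.frame(delta_iop_mmHg = d, volume_um3 = v))
    data.frame(experiment = i, slope_hat = fit$slope,
               ci_lo = fit$ci[1], ci_hi = fit$ci[2],
               covered = fit$ci[1] <= true_slope & true_slope <= fit$ci[2],
               rel_abs_error = abs(fit$slope - true_slope) / abs(true_slope))
  })
  fits <- do.call(rbind, rows)
  list(fits = fits, true_slope = true_slope,
       coverage = mean(fits$covered),
       mean_rel_abs_error = mean(fits$rel_abs_error))
}

#' Power simulation for the slope-difference test
#'
#' Simulates two-group relative-volume experiments with prescribed generating
#' slopes and Gaussian noise, and reports how often [compare_slopes()]
#' rejects at the given alpha. Each group contributes `n_eyes` eyes measured
#' at every IOP offset with `repeats_per_level` repeats.
#'
#' @param slopes length-2 generating slopes, relative-volume units per mmHg.
#' @param baselines length-2 group intercepts at offset 0 (relative units).
#' @param sd measurement-noise SD, relative-volume units.
#' @param n_eyes eyes per group.
#' @param delta_iop_levels IOP offsets.
#' @param repeats_per_level repeats per offset per eye.
#' @param n_sim number of simulated experiments.
#' @param alpha rejection threshold.
#' @param seed RNG seed.
#' @return list with `power` (rejection fraction), `p_values` and the
#'   simulation settings.
#' @export
power_compare_slopes <- function(slopes = c(-0.044, -0.022),
                                 baselines = c(1, 0.5), sd = 0.05,
                                 n_eyes = 6,
                                 delta_iop_levels = c(-10, -5, 0, 5, 10),
                                 repeats_per_level = 3, n_sim = 500,
                                 alpha = 0.05, seed = 1) {
  stopifnot(length(slopes) == 2, length(baselines) == 2, sd > 0)
  d_one <- rep(delta_iop_levels, each = repeats_per_level)
  d_grp <- rep(d_one, n_eyes)
  n_grp <- length(d_grp)
  p_values <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    df <- data.frame(
      delta_iop_mmHg = c(d_grp, d_grp),
      group = rep(c("a", "b"), each = n_grp),
      value = c(baselines[1] + slopes[1] * d_grp,
                baselines[2] + slopes[2] * d_grp) +
        stats::rnorm(2 * n_grp, sd = sd))
    compare_slopes(value ~ delta_iop_mmHg, df)$p_value
  }, numeric(1)))
  list(power = mean(p_values < alpha), p_values = p_values,
       slopes = slopes, sd = sd, n_eyes = n_eyes, alpha = alpha)
}
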