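#' Synthetic Schlemm's canal phantom specification
#'
#' Describes a synthetic SC lumen used to generate binary B-scan mask stacks
#' with exact analytic ground truth. The lumen is an ellipse of full width
#' `width0_um` and full height `height0_um` whose height deforms linearly with
#' the IOP offset: `h(d) = height0_um + slope_height_um_per_mmHg * d`.
#' Cross-sectional area is `pi/4 * width * height`; the width is held fixed
#' unless `slope_area_frac_per_mmHg` is given, in which case the area follows
#' `A(d) = A0 * (1 + slope_area_frac_per_mmHg * d)` and the width is derived
#' from area and height.
#'
#' Septated stations model a lumen locally split into two side-by-side parts:
#' two ellipses of the same height whose widths divide the deformed width in
#' the ratio `frac : (1 - frac)`, separated by a gap of `septum_gap_px`
#' lateral pixels. This splitting conserves total area, summed major axes and
#' area-weighted minor axis exactly.
#'
#' @param length_um analyzed SC segment length in micrometers (default 1500,
#'   i.e. the 1.5 mm analysis window).
#' @param n_bscans number of cross-sections covering `length_um` (B-scan
#'   spacing is `length_um / n_bscans`).
#' @param width0_um,height0_um baseline full ellipse axes in micrometers.
#' @param slope_height_um_per_mmHg height change per mmHg of IOP offset.
#' @param slope_area_frac_per_mmHg optional fractional area change per mmHg;
#'   `NULL` (default) keeps the width fixed.
#' @param septa_stations optional list of `list(start =, end =, frac =)`
#'   entries giving 1-based inclusive B-scan index ranges that are septated
#'   and the area fraction of the first part (default `frac = 0.5`).
#' @param lateral_um_per_px,axial_um_per_px pixel calibration (defaults 7 and
#'   1.3 micrometers, the lateral and axial resolutions of the imaging
#'   system emulated).
#' @param noise_px boundary jitter amplitude: SD, in pixels, of a smooth
#'   zero-mean radial perturbation of the ellipse boundary (default 0).
#' @param septum_gap_px lateral-pixel gap separating septated parts.
#' @param grid_px optional fixed raster size `c(rows_axial, cols_lateral)`;
#'   auto-sized to fit the lumen when `NULL`.
#' @param seed default RNG seed used when generation functions are not given
#'   one explicitly.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_mask_stack()], [generate_experiment()]
#' @export
phantom_spec <- function(length_um = 1500, n_bscans = 50,
                         width0_um = 200, height0_um = 25,
                         slope_height_um_per_mmHg = -0.85,
                         slope_area_frac_per_mmHg = NULL,
                         septa_stations = NULL,
                         lateral_um_per_px = 7, axial_um_per_px = 1.3,
                         noise_px = 0, septum_gap_px = 3,
                         grid_px = NULL, seed = NULL) {
  stopifnot(width0_um > 0, height0_um > 0, n_bscans >= 2,
            lateral_um_per_px > 0, axial_um_per_px > 0,
            length_um > 0, noise_px >= 0, septum_gap_px >= 1)
  if (!is.null(septa_stations)) {
    septa_stations <- lapply(septa_stations, function(s) {
      s <- as.list(s)
      if (is.null(s$frac)) s$frac <- 0.5
      stopifnot(s$start >= 1, s$end >= s$start, s$end <= n_bscans,
                s$frac > 0, s$frac < 1)
      s
    })
  }
  structure(list(
    length_um = length_um, n_bscans = as.integer(n_bscans),
    width0_um = width0_um, height0_um = height0_um,
    slope_height_um_per_mmHg = slope_height_um_per_mmHg,
    slope_area_frac_per_mmHg = slope_area_frac_per_mmHg,
    septa_stations = septa_stations,
    lateral_um_per_px = lateral_um_per_px,
    axial_um_per_px = axial_um_per_px,
    noise_px = noise_px, septum_gap_px = as.integer(septum_gap_px),
    grid_px = grid_px, seed = seed
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Synthetic SC phantom\n")
  cat(sprintf("  segment: %g um in %d B-scans (spacing %.3g um)\n",
              x$length_um, x$n_bscans, x$length_um / x$n_bscans))
  cat(sprintf("  baseline lumen: %g x %g um (width x height)\n",
              x$width0_um, x$height0_um))
  cat(sprintf("  height slope: %g um/mmHg%s\n", x$slope_height_um_per_mmHg,
              if (is.null(x$slope_area_frac_per_mmHg)) " (width fixed)"
              else sprintf(", area slope: %g /mmHg",
                           x$slope_area_frac_per_mmHg)))
  cat(sprintf("  grid: %g um/px lateral, %g um/px axial, jitter %g px\n",
              x$lateral_um_per_px, x$axial_um_per_px, x$noise_px))
  if (!is.null(x$septa_stations))
    cat(sprintf("  septated stations: %d range(s)\n",
                length(x$septa_stations)))
  invisible(x)
}

#' Deformed phantom geometry at an IOP offset
#'
#' Analytic cross-sectional geometry of a phantom at IOP offset `delta_iop`:
#' full width and height (micrometers), area (um^2) and the volume over the
#' analyzed length (um^3). This is the phantom's ground truth, computed from
#' the deformation model, never from rasterized masks.
#'
#' @param spec a [phantom_spec()].
#' @param delta_iop IOP offset from baseline in mmHg (vectorized).
#' @return data.frame with columns `delta_iop_mmHg`, `width_um`, `height_um`,
#'   `area_um2`, `volume_um3`.
#' @export
phantom_geometry <- function(spec, delta_iop) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height0_um + spec$slope_height_um_per_mmHg * delta_iop
  bad <- h <= 0
  if (any(bad))
    stop(sprintf("deformed height is non-positive at IOP offset %s mmHg",
                 paste(delta_iop[bad], collapse = ", ")))
  if (is.null(spec$slope_area_frac_per_mmHg)) {
    w <- rep(spec$width0_um, length(h))
    a <- pi / 4 * w * h
  } else {
    a0 <- pi / 4 * spec$width0_um * spec$height0_um
    a <- a0 * (1 + spec$slope_area_frac_per_mmHg * delta_iop)
    if (any(a <= 0))
      stop(sprintf("deformed area is non-positive at IOP offset %s mmHg",
                   paste(delta_iop[a <= 0], collapse = ", ")))
    w <- 4 * a / (pi * h)
  }
  data.frame(delta_iop_mmHg = delta_iop, width_um = w, height_um = h,
             area_um2 = a, volume_um3 = a * spec$length_um)
}

# True volume slope dV/d(IOP) in um^3/mmHg implied by the deformation model.
phantom_volume_slope <- function(spec) {
  if (is.null(spec$slope_area_frac_per_mmHg)) {
    pi / 4 * spec$width0_um * spec$slope_height_um_per_mmHg * spec$length_um
  } else {
    pi / 4 * spec$width0_um * spec$height0_um *
      spec$slope_area_frac_per_mmHg * spec$length_um
  }
}

# Septated part layout for one B-scan: centers and widths (um) of the one or
# two elliptical parts at a station, given the deformed full width.
phantom_parts <- function(spec, width_um, bscan_index) {
  frac <- NA_real_
  if (!is.null(spec$septa_stations)) {
    for (s in spec$septa_stations)
      if (bscan_index >= s$start && bscan_index <= s$end) frac <- s$frac
  }
  if (is.na(frac)) {
    data.frame(offset_um = 0, width_um = width_um)
  } else {
    gap <- spec$septum_gap_px * spec$lateral_um_per_px
    w1 <- frac * width_um
    w2 <- (1 - frac) * width_um
    span <- w1 + gap + w2
    data.frame(offset_um = c(-span / 2 + w1 / 2, span / 2 - w2 / 2),
               width_um = c(w1, w2))
  }
}

# Smooth zero-mean periodic radial jitter field: 6-harmonic Fourier series
# with iid standard-normal coefficients, normalized to unit pointwise SD.
# Returns a function of the parametric angle theta.
jitter_field <- function(n_harmonics = 6) {
  a <- stats::rnorm(n_harmonics)
  b <- stats::rnorm(n_harmonics)
  k <- seq_len(n_harmonics)
  function(theta) {
    f <- 0
    for (i in k) f <- f + a[i] * cos(i * theta) + b[i] * sin(i * theta)
    f / sqrt(n_harmonics)
  }
}

# Rasterize one elliptical part onto the anisotropic grid. A pixel is
# foreground iff its center lies inside the (possibly jittered) boundary.
rasterize_part <- function(xs_um, zs_um, cx, cz, a_semi, b_semi,
                           noise_px, lat, ax) {
  xn <- outer(rep(1, length(zs_um)), (xs_um - cx) / a_semi)
  zn <- outer((zs_um - cz) / b_semi, rep(1, length(xs_um)))
  rho <- sqrt(xn^2 + zn^2)
  if (noise_px > 0) {
    eps <- jitter_field()
    theta <- atan2(zn, xn)
    # physical radius and radial pixel extent at each parametric angle
    r_th <- sqrt((a_semi * cos(theta))^2 + (b_semi * sin(theta))^2)
    cpsi <- a_semi * cos(theta) / r_th
    spsi <- b_semi * sin(theta) / r_th
    p_th <- sqrt((lat * cpsi)^2 + (ax * spsi)^2)
    thr <- 1 + noise_px * p_th / r_th * eps(theta)
    thr <- pmax(thr, 0)
  } else {
    thr <- 1
  }
  (rho <= thr) * 1L
}

#' Generate a synthetic mask stack at one IOP offset
#'
#' Rasterizes the phantom's deformed lumen into `n_bscans` binary masks on the
#' anisotropic pixel grid (a pixel is foreground iff its center lies inside
#' the ellipse boundary), with independent smooth boundary jitter per B-scan
#' and per part when `noise_px > 0`. Ground truth is computed analytically
#' from the deformation model, not from the raster.
#'
#' @param spec a [phantom_spec()].
#' @param delta_iop IOP offset from baseline, mmHg.
#' @param seed RNG seed for the boundary jitter; defaults to `spec$seed`.
#' @return a list with components `stack` (a [mask_stack()]) and `truth`
#'   (one-row data.frame from [phantom_geometry()]).
#' @examples
#' ph <- phantom_spec(n_bscans = 5, noise_px = 0)
#' gen <- generate_mask_stack(ph, delta_iop = 0)
#' dim(gen$stack$masks[[1]])
#' @export
generate_mask_stack <- function(spec, delta_iop, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), length(delta_iop) == 1)
  geom <- phantom_geometry(spec, delta_iop)
  lat <- spec$lateral_um_per_px
  ax <- spec$axial_um_per_px

  # lateral span must cover the widest (possibly septated) layout
  gap_um <- if (is.null(spec$septa_stations)) 0 else
    spec$septum_gap_px * lat
  span_um <- geom$width_um + gap_um
  if (is.null(spec$grid_px)) {
    nx <- ceiling(span_um * 1.1 / lat) + 4L
    nz <- ceiling(geom$height_um * 1.2 / ax) + 6L
  } else {
    nz <- spec$grid_px[1]
    nx <- spec$grid_px[2]
    if (nx * lat < span_um || nz * ax < geom$height_um)
      stop(sprintf(paste0("grid %d x %d px is too small for a lumen spanning",
                          " %.1f x %.1f um"), nz, nx, span_um, geom$height_um))
  }
  xs <- (seq_len(nx) - 0.5) * lat
  zs <- (seq_len(nz) - 0.5) * ax
  cx0 <- nx * lat / 2
  cz0 <- nz * ax / 2

  masks <- with_seed(seed, lapply(seq_len(spec$n_bscans), function(i) {
    parts <- phantom_parts(spec, geom$width_um, i)
    m <- matrix(0L, nz, nx)
    for (p in seq_len(nrow(parts))) {
      m <- m | rasterize_part(xs, zs, cx0 + parts$offset_um[p], cz0,
                              parts$width_um[p] / 2, geom$height_um / 2,
                              spec$noise_px, lat, ax)
    }
    m * 1L
  }))
  stack <- mask_stack(masks, lateral_um_per_px = lat, axial_um_per_px = ax,
                      bscan_spacing_um = spec$length_um / spec$n_bscans)
  list(stack = stack, truth = geom)
}

#' IOP experiment design
#'
#' The layout of a synthetic IOP-response experiment: the ordered IOP offsets
#' visited, the number of repeat acquisitions per offset, the number of eyes
#' per group, and a named list of group phantoms.
#'
#' @param groups named list of [phantom_spec()] objects, one per group; the
#'   first group is conventionally the control.
#' @param delta_iop_levels_mmHg distinct IOP offsets, mmHg (default the five
#'   offsets -10, -5, 0, +5, +10).
#' @param repeats_per_level repeat acquisitions per offset (default 3).
#' @param eyes_per_group eyes imaged per group (default 1).
#' @return object of class `iop_experiment_design`.
#' @export
iop_experiment_design <- function(groups,
                                  delta_iop_levels_mmHg = c(-10, -5, 0, 5, 10),
                                  repeats_per_level = 3,
                                  eyes_per_group = 1) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)),
            all(vapply(groups, inherits, TRUE, "phantom_spec")),
            repeats_per_level >= 1, eyes_per_group >= 1,
            !anyDuplicated(delta_iop_levels_mmHg))
  structure(list(groups = groups,
                 delta_iop_levels_mmHg = delta_iop_levels_mmHg,
                 repeats_per_level = as.integer(repeats_per_level),
                 eyes_per_group = as.integer(eyes_per_group)),
            class = "iop_experiment_design")
}

#' Generate a full synthetic IOP experiment
#'
#' Produces one mask stack per (group, eye, IOP offset, repeat) together with
#' a manifest and the analytic ground-truth table. Repeats (and eyes) differ
#' only by the boundary-jitter realization; the whole experiment is
#' reproducible from `seed`.
#'
#' @param design an [iop_experiment_design()].
#' @param seed integer seed controlling all randomness.
#' @param out_dir optional directory; when given, each stack is written as a
#'   directory of PNG masks with a JSON calibration sidecar (see
#'   [write_mask_stack()]) plus `manifest.csv` and `ground_truth.csv`, and
#'   `stack_path` in the manifest points at the written stacks.
#' @return list with `manifest` (data.frame: eye_id, group, delta_iop_mmHg,
#'   repeat, stack_path or stack index), `stacks` (list of [mask_stack()]s,
#'   in manifest order) and `truth` (ground-truth data.frame keyed like the
#'   manifest).
#' @export
generate_experiment <- function(design, seed = 1, out_dir = NULL) {
  stopifnot(inherits(design, "iop_experiment_design"))
  rows <- expand.grid(repeat_ = seq_len(design$repeats_per_level),
                      delta_iop_mmHg = design$delta_iop_levels_mmHg,
                      eye = seq_len(design$eyes_per_group),
                      group = names(design$groups),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  seeds <- derive_seeds(seed, n)
  stacks <- vector("list", n)
  truth <- vector("list", n)
  manifest <- data.frame(eye_id = sprintf("%s_eye%d", rows$group, rows$eye),
                         group = rows$group,
                         delta_iop_mmHg = rows$delta_iop_mmHg,
                         `repeat` = rows$repeat_,
                         stack_path = NA_character_,
                         check.names = FALSE)
  for (i in seq_len(n)) {
    gen <- generate_mask_stack(design$groups[[rows$group[i]]],
                               rows$delta_iop_mmHg[i], seed = seeds[i])
    stacks[[i]] <- gen$stack
    truth[[i]] <- cbind(manifest[i, c("eye_id", "group", "delta_iop_mmHg",
                                      "repeat")],
                        gen$truth[, c("width_um", "height_um", "area_um2",
                                      "volume_um3")])
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      rel <- sprintf("%s_d%+03d_r%d", manifest$eye_id[i],
                     manifest$delta_iop_mmHg[i], manifest$`repeat`[i])
      write_mask_stack(stacks[[i]], file.path(out_dir, rel))
      manifest$stack_path[i] <- rel
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    manifest$stack_path <- seq_len(n) # index into `stacks`
  }
  list(manifest = manifest, stacks = stacks, truth = truth)
}
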