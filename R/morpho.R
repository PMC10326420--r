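#' Equal-second-moment ellipse fit
#'
#' Fits to each lumen component the ellipse whose normalized central second
#' moments equal the component's, the convention behind region-property major
#' and minor axis lengths. With normalized moments (in um^2, from the raw
#' sums divided by pixel count) and the per-axis pixel-extent correction
#' (a pixel is a `lat x ax` um rectangle whose own second moment about its
#' center is `lat^2/12`, resp. `ax^2/12`):
#'
#' \deqn{u_{xx} = \mu_{20}/n + lat^2/12, \quad u_{yy} = \mu_{02}/n + ax^2/12,
#'       \quad u_{xy} = \mu_{11}/n}
#' \deqn{c = \sqrt{(u_{xx}-u_{yy})^2 + 4 u_{xy}^2}}
#' \deqn{major = 2\sqrt{2}\sqrt{u_{xx}+u_{yy}+c}, \quad
#'       minor = 2\sqrt{2}\sqrt{u_{xx}+u_{yy}-c}}
#'
#' Corrections are applied per axis in physical micrometers before the
#' eigen-decomposition, so the fit is exact on anisotropic grids (here the
#' axial pixel is ~5x smaller than the lateral one). A single-pixel
#' component yields the pixel's own ellipse, never zero axes.
#'
#' @param components data.frame from [extract_components()] (any number of
#'   rows, which may mix B-scans).
#' @return `components` with columns `major_axis_um`, `minor_axis_um` and
#'   `orientation_rad` appended. Orientation is the angle of the major axis
#'   from the lateral axis, in radians in (-pi/2, pi/2], with the axial
#'   coordinate increasing with depth.
#' @examples
#' m <- matrix(1L, 4, 4) # 4x4 filled square at 1 um/px
#' fit_ellipse(extract_components(m, 1, 1))$major_axis_um # 2*4/sqrt(3)
#' @export
fit_ellipse <- function(components) {
  stopifnot(all(c("mu20", "mu02", "mu11", "pixel_count",
                  "lateral_um_per_px", "axial_um_per_px")
                %in% names(components)))
  n <- components$pixel_count
  uxx <- components$mu20 / n + components$lateral_um_per_px^2 / 12
  uyy <- components$mu02 / n + components$axial_um_per_px^2 / 12
  uxy <- components$mu11 / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  components$major_axis_um <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  components$minor_axis_um <- 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0))
  theta <- 0.5 * atan2(2 * uxy, uxx - uyy)
  theta[theta <= -pi / 2] <- theta[theta <= -pi / 2] + pi
  theta[theta > pi / 2] <- theta[theta > pi / 2] - pi
  components$orientation_rad <- theta
  components
}

#' Per-cross-section SC morphometry
#'
#' Collapses the selected (ellipse-fitted) components of one B-scan into the
#' cross-section summary: total area, width as the sum of the fitted major
#' axes, and height as the area-weighted mean of the fitted minor axes. An
#' empty component set yields an empty-flagged record with zero area and
#' undefined width/height.
#'
#' @param components data.frame of included components for one B-scan, as
#'   returned by [fit_ellipse()].
#' @param bscan_index index recorded in the output (required when
#'   `components` has zero rows).
#' @return one-row data.frame: `bscan_index`, `n_components`, `area_um2`,
#'   `width_um`, `height_um`, `empty`.
#' @export
cross_section_morphometry <- function(components,
                                      bscan_index = components$bscan_index[1]) {
  if (nrow(components) == 0) {
    return(data.frame(bscan_index = as.integer(bscan_index), n_components = 0L,
                      area_um2 = 0, width_um = NA_real_, height_um = NA_real_,
                      empty = TRUE))
  }
  stopifnot(length(unique(components$bscan_index)) == 1,
            all(c("major_axis_um", "minor_axis_um") %in% names(components)))
  a <- components$area_um2
  data.frame(bscan_index = as.integer(components$bscan_index[1]),
             n_components = nrow(components),
             area_um2 = sum(a),
             width_um = sum(components$major_axis_um),
             height_um = sum(a * components$minor_axis_um) / sum(a),
             empty = FALSE)
}

#' Morphometry of every cross-section in a stack
#'
#' Runs component extraction, SC part selection and ellipse fitting on every
#' B-scan of a stack and returns the per-cross-section morphometry table.
#'
#' @param stack a [mask_stack()].
#' @param roi optional ROI rectangle overriding `stack$roi`.
#' @param min_area_frac part-inclusion threshold, see
#'   [select_sc_components()].
#' @return data.frame with one row per B-scan, columns as in
#'   [cross_section_morphometry()].
#' @export
stack_morphometry <- function(stack, roi = stack$roi, min_area_frac = 0.20) {
  stopifnot(inherits(stack, "mask_stack"))
  out <- lapply(seq_along(stack$masks), function(i) {
    comp <- extract_components(stack$masks[[i]], stack$lateral_um_per_px,
                               stack$axial_um_per_px, bscan_index = i)
    sel <- select_sc_components(comp, roi = roi,
                                min_area_frac = min_area_frac)
    if (nrow(sel) > 0) sel <- fit_ellipse(sel)
    cross_section_morphometry(sel, bscan_index = i)
  })
  do.call(rbind, out)
}

#' Per-eye series morphometry over a fixed analyzed length
#'
#' Aggregates per-cross-section morphometry into one acquisition-level
#' record. The analysis is restricted to the first
#' `floor(window_um / bscan_spacing_um)` sections (all, if fewer). Volume is
#' the rectangle-rule integral `sum(area) * spacing` with empty sections
#' contributing zero area; mean width, height and area are averaged over
#' non-empty sections only, since they are properties of lumen that exists.
#'
#' @param sections data.frame from [stack_morphometry()].
#' @param bscan_spacing_um B-scan spacing, micrometers.
#' @param window_um analyzed length (default 1500 um).
#' @return one-row data.frame: `volume_um3`, `mean_width_um`,
#'   `mean_height_um`, `mean_area_um2`, `n_nonempty_sections`,
#'   `n_sections_analyzed`, `length_analyzed_um`.
#' @export
series_morphometry <- function(sections, bscan_spacing_um,
                               window_um = 1500) {
  stopifnot(nrow(sections) >= 2, bscan_spacing_um > 0, window_um > 0)
  n_win <- as.integer(min(nrow(sections), floor(window_um / bscan_spacing_um)))
  s <- sections[seq_len(n_win), , drop = FALSE]
  nonempty <- !s$empty
  data.frame(
    volume_um3 = sum(s$area_um2) * bscan_spacing_um,
    mean_width_um = if (any(nonempty)) mean(s$width_um[nonempty])
                    else NA_real_,
    mean_height_um = if (any(nonempty)) mean(s$height_um[nonempty])
                     else NA_real_,
    mean_area_um2 = if (any(nonempty)) mean(s$area_um2[nonempty])
                    else NA_real_,
    n_nonempty_sections = sum(nonempty),
    n_sections_analyzed = n_win,
    length_analyzed_um = n_win * bscan_spacing_um
  )
}

#' SC area along the scan
#'
#' The area-versus-length profile of a stack: cumulative distance from the
#' first analyzed B-scan against the cross-sectional SC area.
#'
#' @param sections data.frame from [stack_morphometry()].
#' @param bscan_spacing_um B-scan spacing, micrometers.
#' @return data.frame with columns `length_um` and `area_um2`.
#' @export
area_length_profile <- function(sections, bscan_spacing_um) {
  stopifnot(bscan_spacing_um > 0)
  data.frame(length_um = (seq_len(nrow(sections)) - 1) * bscan_spacing_um,
             area_um2 = sections$area_um2)
}

#' Peripheral cornea thickness from boundary pairs
#'
#' Mean corneal thickness at the iridocorneal angle from manually traced
#' anterior/posterior boundary pairs in several (conventionally three)
#' cross-sections: per section, the mean axial separation of the boundaries
#' converted to micrometers; overall, the mean across sections.
#'
#' @param sections list with one element per cross-section, each a list (or
#'   data.frame) with numeric vectors `anterior` and `posterior` of equal
#'   length holding axial pixel coordinates over a shared lateral range
#'   (axial coordinate increases with depth, so posterior >= anterior).
#' @param axial_um_per_px axial pixel size, micrometers.
#' @return thickness in micrometers.
#' @examples
#' secs <- lapply(c(70, 80, 90), function(s)
#'   list(anterior = rep(0, 5), posterior = rep(s, 5)))
#' cornea_thickness(secs, 1.3) # 104
#' @export
cornea_thickness <- function(sections, axial_um_per_px) {
  stopifnot(length(sections) >= 1, axial_um_per_px > 0)
  per_sec <- vapply(sections, function(s) {
    stopifnot(length(s$anterior) == length(s$posterior),
              length(s$anterior) >= 1)
    sep <- s$posterior - s$anterior
    if (any(sep < 0))
      stop("crossing boundaries: posterior lies above anterior somewhere")
    mean(sep) * axial_um_per_px
  }, numeric(1))
  mean(per_sec)
}

#' Mean stained area per high-power field
#'
#' Average foreground area over a set of high-power-field (HPF) binary masks,
#' in calibrated units — the flat-mount quantification where several 20X
#' fields are acquired per individual and the positive area is averaged.
#'
#' @param field_masks list of binary matrices, one per field (1 to 8 fields).
#' @param um_per_px pixel size; a scalar for square pixels or `c(lateral,
#'   axial)`.
#' @return mean area per field in um^2.
#' @export
sc_area_per_field <- function(field_masks, um_per_px = 1) {
  if (length(field_masks) == 0)
    stop("at least one high-power-field mask is required")
  if (length(field_masks) > 8)
    warning("more than 8 fields supplied; the protocol uses 4-8 per eye")
  px_area <- prod(rep(um_per_px, length.out = 2))
  mean(vapply(field_masks, function(m) sum(m != 0) * px_area, numeric(1)))
}
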