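#' Binary mask stack with physical calibration
#'
#' Container for an ordered series of per-B-scan binary lumen masks together
#' with the pixel calibration needed to work in physical units. Masks are
#' integer matrices with rows along the axial (depth) direction and columns
#' along the lateral direction; any nonzero value is foreground.
#'
#' @param masks list of matrices, all of one shape.
#' @param lateral_um_per_px,axial_um_per_px pixel size, micrometers.
#' @param bscan_spacing_um distance between consecutive B-scans, micrometers.
#' @param roi optional rectangle marking the expected SC neighbourhood, as
#'   `list(lateral_px = c(min, max), axial_px = c(min, max))` in pixel
#'   coordinates; used by [select_sc_components()] to operationalize the
#'   "immediately lateral to the iridocorneal angle" anchor criterion.
#' @return object of class `mask_stack`.
#' @export
mask_stack <- function(masks, lateral_um_per_px, axial_um_per_px,
                       bscan_spacing_um, roi = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1,
            lateral_um_per_px > 0, axial_um_per_px > 0, bscan_spacing_um > 0)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all masks in a stack must share one raster shape")
  masks <- lapply(masks, function(m) (m != 0) * 1L)
  structure(list(masks = masks, lateral_um_per_px = lateral_um_per_px,
                 axial_um_per_px = axial_um_per_px,
                 bscan_spacing_um = bscan_spacing_um, roi = roi),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf(paste0("Mask stack: %d B-scans of %d x %d px ",
                     "(%g um/px lateral, %g um/px axial, %g um spacing)\n"),
              length(x$masks), d[1], d[2], x$lateral_um_per_px,
              x$axial_um_per_px, x$bscan_spacing_um))
  invisible(x)
}

#' @export
length.mask_stack <- function(x) length(x$masks)

#' Write a mask stack to disk
#'
#' Writes one 8-bit grayscale PNG (0/255) per B-scan, named by zero-padded
#' index, plus a `stack.json` sidecar holding the calibration.
#'
#' @param stack a [mask_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mask_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "mask_stack"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create stack directory: ", dir)
  for (i in seq_along(stack$masks)) {
    png::writePNG(stack$masks[[i]] * 1.0,
                  target = file.path(dir, sprintf("%04d.png", i)))
  }
  jsonlite::write_json(list(lateral_um_per_px = stack$lateral_um_per_px,
                            axial_um_per_px = stack$axial_um_per_px,
                            bscan_spacing_um = stack$bscan_spacing_um,
                            n_bscans = length(stack$masks)),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a mask stack from disk
#'
#' Reads a directory of single-page PNG masks ordered by file name, with the
#' calibration taken from the `stack.json` sidecar or, failing that, from the
#' `calibration` argument. Any nonzero pixel is treated as foreground.
#'
#' @param path stack directory.
#' @param calibration optional `list(lateral_um_per_px, axial_um_per_px,
#'   bscan_spacing_um)` overriding / replacing the sidecar.
#' @param roi optional ROI rectangle, see [mask_stack()].
#' @return a [mask_stack()].
#' @export
read_mask_stack <- function(path, calibration = NULL, roi = NULL) {
  if (!dir.exists(path)) stop("stack directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2)
    stop("stack at ", path, " has fewer than 2 mask pages")
  sidecar <- file.path(path, "stack.json")
  cal <- if (!is.null(calibration)) calibration
         else if (file.exists(sidecar)) jsonlite::read_json(sidecar)
         else stop("no calibration: ", path,
                   " lacks stack.json and none was supplied")
  for (f in c("lateral_um_per_px", "axial_um_per_px", "bscan_spacing_um"))
    if (is.null(cal[[f]])) stop("calibration is missing field ", f)
  masks <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1] # collapse channels
    (img != 0) * 1L
  })
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mask pages at ", path, " differ in raster shape")
  mask_stack(masks, cal$lateral_um_per_px, cal$axial_um_per_px,
             cal$bscan_spacing_um, roi = roi)
}

#' Label connected components of a binary mask
#'
#' 8-connected component labeling (diagonal contact joins regions, the
#' convention expected for thin lumen sections) via run-based union-find.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @return integer matrix of the same shape: 0 background, 1..k component
#'   labels in first-pixel (column-major) order.
#' @export
label_mask <- function(mask) {
  m <- (mask != 0)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (!any(m)) return(lab)

  # horizontal runs per row: run id, row, col range
  runs_row <- integer(0); runs_c0 <- integer(0); runs_c1 <- integer(0)
  for (r in seq_len(nr)) {
    x <- m[r, ]
    d <- diff(c(FALSE, x, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1L
    if (length(starts)) {
      runs_row <- c(runs_row, rep.int(r, length(starts)))
      runs_c0 <- c(runs_c0, starts); runs_c1 <- c(runs_c1, ends)
    }
  }
  nrun <- length(runs_row)
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # union runs on adjacent rows whose column ranges touch (8-connectivity:
  # ranges may be offset by one column and still touch diagonally)
  prev <- integer(0)
  for (r in seq_len(nr)) {
    cur <- which(runs_row == r)
    for (i in cur) for (j in prev) {
      if (runs_c0[i] <= runs_c1[j] + 1L && runs_c1[i] >= runs_c0[j] - 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    prev <- cur
  }
  root <- vapply(seq_len(nrun), find, integer(1))
  comp <- match(root, unique(root))
  # number components by their first pixel in column-major order
  first_px <- as.numeric(tapply((runs_c0 - 1) * nr + runs_row, comp, min))
  relab <- rank(first_px)[comp]
  for (i in seq_len(nrun))
    lab[runs_row[i], runs_c0[i]:runs_c1[i]] <- as.integer(relab[i])
  lab
}

#' Extract lumen components from one B-scan mask
#'
#' One record per 8-connected foreground region, with pixel count, area and
#' central second moments computed over pixel centers in physical micrometer
#' coordinates (lateral = column, axial = row; pixel center of column j is at
#' `(j - 0.5) * lateral_um_per_px`, and analogously axially). Moments are
#' raw central sums (`mu20 = sum (x - xbar)^2` etc., um^2 x pixels); divide
#' by `pixel_count` for the normalized moments used in ellipse fitting.
#'
#' @param mask binary matrix.
#' @param lateral_um_per_px,axial_um_per_px pixel calibration.
#' @param bscan_index index recorded with each component.
#' @return data.frame with one row per component: `bscan_index`, `label`,
#'   `pixel_count`, `area_um2`, `centroid_lateral_um`, `centroid_axial_um`,
#'   `centroid_col_px`, `centroid_row_px`, `mu20`, `mu02`, `mu11`, and the
#'   calibration columns `lateral_um_per_px`, `axial_um_per_px`. Empty masks
#'   yield zero rows.
#' @export
extract_components <- function(mask, lateral_um_per_px, axial_um_per_px,
                               bscan_index = 1L) {
  lab <- label_mask(mask)
  k <- max(lab)
  empty <- data.frame(bscan_index = integer(0), label = integer(0),
                      pixel_count = integer(0), area_um2 = numeric(0),
                      centroid_lateral_um = numeric(0),
                      centroid_axial_um = numeric(0),
                      centroid_col_px = numeric(0),
                      centroid_row_px = numeric(0),
                      mu20 = numeric(0), mu02 = numeric(0), mu11 = numeric(0),
                      lateral_um_per_px = numeric(0),
                      axial_um_per_px = numeric(0))
  if (k == 0) return(empty)
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  lb <- lab[idx]
  x <- (cols - 0.5) * lateral_um_per_px # lateral, um
  z <- (rows - 0.5) * axial_um_per_px   # axial, um
  n <- tabulate(lb, k)
  sx <- tapply(x, lb, sum); sz <- tapply(z, lb, sum)
  xbar <- as.numeric(sx) / n; zbar <- as.numeric(sz) / n
  dx <- x - xbar[lb]; dz <- z - zbar[lb]
  mu20 <- as.numeric(tapply(dx * dx, lb, sum))
  mu02 <- as.numeric(tapply(dz * dz, lb, sum))
  mu11 <- as.numeric(tapply(dx * dz, lb, sum))
  data.frame(bscan_index = as.integer(bscan_index), label = seq_len(k),
             pixel_count = n,
             area_um2 = n * lateral_um_per_px * axial_um_per_px,
             centroid_lateral_um = xbar, centroid_axial_um = zbar,
             centroid_col_px = xbar / lateral_um_per_px,
             centroid_row_px = zbar / axial_um_per_px,
             mu20 = mu20, mu02 = mu02, mu11 = mu11,
             lateral_um_per_px = lateral_um_per_px,
             axial_um_per_px = axial_um_per_px)
}

# Does a component centroid fall inside the ROI rectangle (pixel coords)?
in_roi <- function(components, roi) {
  if (is.null(roi)) return(rep(TRUE, nrow(components)))
  components$centroid_col_px >= roi$lateral_px[1] &
    components$centroid_col_px <= roi$lateral_px[2] &
    components$centroid_row_px >= roi$axial_px[1] &
    components$centroid_row_px <= roi$axial_px[2]
}

#' Select SC lumen parts within one cross-section
#'
#' Applies the SC part-selection rule: the anchor is the largest-area
#' component whose centroid lies inside the ROI (the whole frame when no ROI
#' is given), and every in-ROI component whose area is at least 20% of the
#' anchor's area is retained (inclusive threshold, reading "at least 20%"
#' literally). Components from one B-scan at a time.
#'
#' @param components data.frame from [extract_components()].
#' @param roi optional ROI rectangle, see [mask_stack()].
#' @param min_area_frac inclusion threshold as a fraction of the anchor area
#'   (default 0.20).
#' @return the included subset of `components` (possibly zero rows).
#' @export
select_sc_components <- function(components, roi = NULL,
                                 min_area_frac = 0.20) {
  if (nrow(components) == 0) return(components)
  stopifnot(length(unique(components$bscan_index)) == 1)
  keep <- in_roi(components, roi)
  pool <- components[keep, , drop = FALSE]
  if (nrow(pool) == 0) return(pool)
  anchor_area <- max(pool$area_um2)
  pool[pool$area_um2 >= min_area_frac * anchor_area, , drop = FALSE]
}
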