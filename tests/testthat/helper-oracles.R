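# Independent oracles and fixture builders used across the suite.

# Brute-force region moments: explicit double loop over every foreground
# pixel in physical coordinates. Deliberately naive — the oracle for the
# vectorized extract_components() path.
brute_force_moments <- function(mask, lat, ax) {
  xs <- 0; zs <- 0; n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] != 0) {
      n <- n + 1
      xs <- xs + (j - 0.5) * lat
      zs <- zs + (i - 0.5) * ax
    }
  }
  xbar <- xs / n; zbar <- zs / n
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] != 0) {
      dx <- (j - 0.5) * lat - xbar
      dz <- (i - 0.5) * ax - zbar
      mu20 <- mu20 + dx * dx
      mu02 <- mu02 + dz * dz
      mu11 <- mu11 + dx * dz
    }
  }
  list(n = n, xbar = xbar, zbar = zbar, mu20 = mu20, mu02 = mu02, mu11 = mu11)
}

# Equal-second-moment axes straight from brute-force moments.
brute_force_axes <- function(mask, lat, ax) {
  m <- brute_force_moments(mask, lat, ax)
  uxx <- m$mu20 / m$n + lat^2 / 12
  uyy <- m$mu02 / m$n + ax^2 / 12
  uxy <- m$mu11 / m$n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  c(major = 2 * sqrt(2) * sqrt(uxx + uyy + common),
    minor = 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0)))
}

# igraph pixel-adjacency labeling: independent route to 8-connected
# components, compared against label_mask().
igraph_label <- function(mask) {
  idx <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  key <- paste(rows, cols)
  edges <- integer(0)
  for (k in seq_along(idx)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- match(paste(rows[k] + dr, cols[k] + dc), key)
      if (!is.na(nb) && nb > k) edges <- c(edges, k, nb)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# Rasterize an axis-aligned ellipse (pixel-center rule) without the phantom
# machinery — fixture for moment and fitting tests.
raster_ellipse <- function(a_um, b_um, lat = 1, ax = 1, pad_px = 3,
                           angle = 0, shift_px = c(0, 0)) {
  nx <- ceiling(2 * a_um / lat) + 2 * pad_px
  nz <- ceiling(2 * max(a_um, b_um) / ax) + 2 * pad_px
  cx <- nx * lat / 2 + shift_px[1] * lat
  cz <- nz * ax / 2 + shift_px[2] * ax
  x <- outer(rep(1, nz), (seq_len(nx) - 0.5) * lat) - cx
  z <- outer((seq_len(nz) - 0.5) * ax, rep(1, nx)) - cz
  xr <- cos(angle) * x + sin(angle) * z
  zr <- -sin(angle) * x + cos(angle) * z
  ((xr / a_um)^2 + (zr / b_um)^2 <= 1) * 1L
}

# Random lumpy blob: thresholded sum of a few random ellipses, for oracle
# equivalence tests over irregular shapes.
random_blob <- function(seed, n_px = 24) {
  set.seed(seed)
  m <- matrix(0L, n_px, n_px)
  for (k in 1:3) {
    a <- runif(1, 3, n_px / 2.5); b <- runif(1, 2, n_px / 3)
    cx <- runif(1, n_px * 0.3, n_px * 0.7)
    cz <- runif(1, n_px * 0.3, n_px * 0.7)
    ang <- runif(1, 0, pi)
    x <- outer(rep(1, n_px), seq_len(n_px) - 0.5) - cx
    z <- outer(seq_len(n_px) - 0.5, rep(1, n_px)) - cz
    xr <- cos(ang) * x + sin(ang) * z
    zr <- -sin(ang) * x + cos(ang) * z
    m <- m | ((xr / a)^2 + (zr / b)^2 <= 1)
  }
  m * 1L
}

# Place filled rectangles into a blank frame; returns the mask. Each rect is
# c(row0, col0, height, width), kept separated by the caller.
rect_mask <- function(nr, nc, rects) {
  m <- matrix(0L, nr, nc)
  for (r in rects) m[r[1]:(r[1] + r[3] - 1), r[2]:(r[2] + r[4] - 1)] <- 1L
  m
}
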