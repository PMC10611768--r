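# Synthetic SEM-like fibre images with exact analytic ground truth.
#
# A generated frame holds one straight horizontal fibre band (grey 128 before
# noise) on a darker background (grey 30), with scale boundaries drawn as
# bright curves (grey 255). Boundary geometry is constructed as polylines in
# physical (um) coordinates *first*; the ground truth records their exact
# lengths per 100 um axial window before rasterisation, so the morphometry
# stage can be validated against known truth.

#' Specification of a synthetic fibre image
#'
#' @param diameter_um fibre diameter (um), > 0.
#' @param length_um imaged fibre length (um), >= 100.
#' @param um_per_px physical pixel pitch (um/px). Default resolves the band
#'   to at least ~25 px across (and never coarser than 1 um/px).
#' @param pattern scale arrangement: `"coronal"` (transverse circular arcs,
#'   fine fibres), `"coronal_reticulate"` (diagonal bands, medium fibres) or
#'   `"reticulate"` (irregular random tiles, coarse fibres).
#' @param scales_per_100um mean number of visible scales per 100 um window.
#' @param edge_width_px drawn boundary line width in pixels.
#' @param noise_sd additive Gaussian grey-level noise (8-bit units).
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @param arc_sagitta_frac coronal arcs bulge by this fraction of the
#'   diameter (0 gives straight transverse chords).
#' @param band_angle_deg inclination of coronal-reticulate bands from the
#'   transverse direction, degrees.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(diameter_um, length_um = 300,
                       um_per_px = NULL,
                       pattern = c("coronal", "coronal_reticulate", "reticulate"),
                       scales_per_100um = NULL,
                       edge_width_px = 2, noise_sd = 8, seed = 1,
                       arc_sagitta_frac = 0.15, band_angle_deg = 35) {
  pattern <- match.arg(pattern)
  check_positive(diameter_um, "diameter_um")
  if (length_um < 100) stop_domain("`length_um` must be >= 100 (at least one full window)")
  if (is.null(um_per_px)) um_per_px <- max(0.2, min(1, diameter_um / 25))
  check_positive(um_per_px, "um_per_px")
  if (is.null(scales_per_100um))   # field-typical density rises with diameter
    scales_per_100um <- max(3, round(0.22 * diameter_um))
  if (scales_per_100um < 1) stop_domain("`scales_per_100um` must be >= 1")
  check_nonneg(noise_sd, "noise_sd")
  if (edge_width_px < 1) stop_domain("`edge_width_px` must be >= 1")
  structure(list(diameter_um = diameter_um, length_um = length_um,
                 um_per_px = um_per_px, pattern = pattern,
                 scales_per_100um = scales_per_100um,
                 edge_width_px = edge_width_px, noise_sd = noise_sd,
                 seed = seed, arc_sagitta_frac = arc_sagitta_frac,
                 band_angle_deg = band_angle_deg),
            class = "image_spec")
}

#' @export
print.image_spec <- function(x, ...) {
  cat(sprintf("<image_spec> %s fibre, d = %g um, L = %g um, %g scales/100um, %g um/px, seed %d\n",
              x$pattern, x$diameter_um, x$length_um, x$scales_per_100um,
              x$um_per_px, x$seed))
  invisible(x)
}

# Discretise a circular arc through (x0, 0) and (x0, d), bulging +x by
# sagitta s, into a polyline with ~step_um vertex spacing.
arc_polyline <- function(x0, d, s, step_um) {
  if (s <= 1e-12) return(cbind(x = c(x0, x0), y = c(0, d)))
  half <- d / 2
  R <- (half^2 + s^2) / (2 * s)
  theta <- asin(min(1, half / R))
  cx <- x0 + s - R
  n <- max(8L, ceiling(2 * theta * R / step_um))
  phi <- seq(-theta, theta, length.out = n + 1L)
  cbind(x = cx + R * cos(phi), y = half + R * sin(phi))
}

# Clip segment (x1,y1)-(x2,y2) to the vertical slab 0 <= x <= L.
clip_segment_x <- function(x1, y1, x2, y2, L) {
  if (x2 < x1) { tmp <- x1; x1 <- x2; x2 <- tmp; tmp <- y1; y1 <- y2; y2 <- tmp }
  if (x2 <= 0 || x1 >= L) return(NULL)
  if (x1 < 0) { y1 <- y1 + (y2 - y1) * (0 - x1) / (x2 - x1); x1 <- 0 }
  if (x2 > L) { y2 <- y1 + (y2 - y1) * (L - x1) / (x2 - x1); x2 <- L }
  c(x1, y1, x2, y2)
}

# Build boundary polylines + scale-cell axial extents for one pattern.
# Returns list(polylines = list of n x 2 matrices (um),
#              cells = data.frame(xmin, xmax, frame = touches axial frame))
scale_geometry <- function(spec) {
  d <- spec$diameter_um; L <- spec$length_um
  s100 <- spec$scales_per_100um
  step <- 0.3 * spec$um_per_px
  delta <- 100 / s100
  if (spec$pattern == "coronal") {
    sag <- spec$arc_sagitta_frac * d
    n <- floor(L / delta)
    x0 <- (seq_len(n) - 0.5) * delta
    polylines <- lapply(x0, arc_polyline, d = d, s = sag, step_um = step)
    lo <- c(0, x0); hi <- c(x0 + sag, L)
    cells <- data.frame(xmin = lo, xmax = pmin(hi, L))
    cells$frame <- cells$xmin <= 1e-9 | cells$xmax >= L - 1e-9
  } else if (spec$pattern == "coronal_reticulate") {
    off <- d * tan(spec$band_angle_deg * pi / 180)
    n <- floor(L / delta)
    x0 <- (seq_len(n) - 0.5) * delta
    polylines <- list()
    for (x in x0) {
      cl <- clip_segment_x(x - off / 2, 0, x + off / 2, d, L)
      if (!is.null(cl)) polylines[[length(polylines) + 1L]] <-
          cbind(x = cl[c(1, 3)], y = cl[c(2, 4)])
    }
    lo <- c(0, x0 - off / 2); hi <- c(x0 + off / 2, L)
    cells <- data.frame(xmin = pmax(lo, 0), xmax = pmin(hi, L))
    cells$frame <- lo <= 1e-9 | hi >= L - 1e-9
  } else {  # reticulate: nearest-seed (Voronoi) tessellation of a seeded
    # jittered-grid point process at mean density s100 per 100 um window
    ny <- max(1L, round(sqrt(s100 * d / 100)))
    dx <- ny * 100 / s100
    nx <- max(2L, round(L / dx))
    gx <- (rep(seq_len(nx), each = ny) - 0.5) * (L / nx)
    gy <- (rep(seq_len(ny), times = nx) - 0.5) * (d / ny)
    px <- gx + runif(length(gx), -0.4, 0.4) * (L / nx)
    py <- gy + runif(length(gy), -0.4, 0.4) * (d / ny)
    px <- pmin(pmax(px, 1e-6), L - 1e-6)
    py <- pmin(pmax(py, 1e-6), d - 1e-6)
    dd <- deldir::deldir(px, py, rw = c(0, L, 0, d), suppressMsge = TRUE)
    sg <- dd$dirsgs
    polylines <- lapply(seq_len(nrow(sg)), function(i)
      cbind(x = c(sg$x1[i], sg$x2[i]), y = c(sg$y1[i], sg$y2[i])))
    tl <- deldir::tile.list(dd)
    cells <- do.call(rbind, lapply(tl, function(t)
      data.frame(xmin = min(t$x), xmax = max(t$x))))
    cells$frame <- cells$xmin <= 1e-9 | cells$xmax >= L - 1e-9
  }
  list(polylines = polylines, cells = cells)
}

# Exact per-window ground truth from the analytic geometry.
geometry_ground_truth <- function(geom, spec) {
  L <- spec$length_um
  nw <- floor(L / 100)
  breaks <- seq(0, 100 * nw, by = 100)
  segs <- do.call(rbind, lapply(geom$polylines, function(p) {
    n <- nrow(p)
    cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  }))
  if (is.null(segs)) segs <- matrix(numeric(0), ncol = 4)
  len_w <- segment_lengths_by_window(segs, breaks)
  counts <- numeric(nw)
  for (w in seq_len(nw)) {
    w0 <- breaks[w]; w1 <- breaks[w + 1L]
    a <- geom$cells$xmin; b <- geom$cells$xmax
    overlap <- b > w0 + 1e-9 & a < w1 - 1e-9
    inside <- overlap & a >= w0 - 1e-9 & b <= w1 + 1e-9 & !geom$cells$frame
    counts[w] <- sum(inside) + 0.5 * sum(overlap & !inside)
  }
  structure(list(boundary_length_per_window = len_w,
                 scale_count_per_window = counts,
                 true_diameter_um = spec$diameter_um,
                 window_breaks_um = breaks),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> d = %g um; per-window boundary length (um): %s; scale counts: %s\n",
              x$true_diameter_um,
              paste(round(x$boundary_length_per_window, 1), collapse = ", "),
              paste(x$scale_count_per_window, collapse = ", ")))
  invisible(x)
}

# Rasterise polylines onto the pixel grid (logical mask), line width w px.
rasterise_polylines <- function(polylines, um_per_px, nrow_px, ncol_px,
                                row_offset_px, width_px) {
  m <- matrix(FALSE, nrow_px, ncol_px)
  for (p in polylines) {
    n <- nrow(p)
    for (i in seq_len(n - 1L)) {
      x1 <- p[i, 1] / um_per_px; y1 <- p[i, 2] / um_per_px
      x2 <- p[i + 1L, 1] / um_per_px; y2 <- p[i + 1L, 2] / um_per_px
      len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      ns <- max(2L, ceiling(len / 0.3) + 1L)
      t <- seq(0, 1, length.out = ns)
      cc <- pmin(ncol_px, pmax(1, ceiling(x1 + t * (x2 - x1))))
      rr <- pmin(nrow_px, pmax(1, row_offset_px + ceiling(y1 + t * (y2 - y1))))
      m[cbind(rr, cc)] <- TRUE
    }
  }
  if (width_px > 1L) {
    out <- m
    for (dr in 0:(width_px - 1L)) for (dc in 0:(width_px - 1L))
      if (dr || dc) out <- out | shift_mat(m, dr - width_px %/% 2, dc - width_px %/% 2, FALSE)
    m <- out
  }
  m
}

#' Generate a synthetic fibre image with exact ground truth
#'
#' Renders one straight horizontal fibre band carrying the scale-boundary
#' pattern described by `spec`, and returns the exact per-100-um-window
#' boundary lengths and visible-scale counts (0.5 granularity) computed
#' analytically from the drawn polylines before rasterisation.
#'
#' @param spec an [image_spec()].
#' @return `list(image = fibre_image, truth = ground_truth)`.
#' @examples
#' g <- generate_fibre_image(image_spec(22, pattern = "coronal",
#'                                      scales_per_100um = 6, seed = 42))
#' g$truth$scale_count_per_window
#' @export
generate_fibre_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  spacing_px <- (100 / spec$scales_per_100um) / spec$um_per_px
  if (spacing_px < 2 * spec$edge_width_px)
    stop_domain("scale spacing below 2 x edge width: boundaries unresolvable at this pixel pitch")
  upp <- spec$um_per_px
  W <- round(spec$length_um / upp)
  band_px <- max(2L, round(spec$diameter_um / upp))
  if (band_px > 4000L || W > 8000L)
    stop_domain("fibre wider/longer than supported frame at this pixel pitch")
  margin <- max(8L, round(0.15 * band_px))
  H <- band_px + 2L * margin
  with_seed(spec$seed, {
    geom <- scale_geometry(spec)
    truth <- geometry_ground_truth(geom, spec)
    img <- matrix(30, H, W)
    band_rows <- (margin + 1L):(margin + band_px)
    img[band_rows, ] <- 128
    edges <- rasterise_polylines(geom$polylines, upp, H, W,
                                 row_offset_px = margin, width_px = spec$edge_width_px)
    # boundaries exist only on the fibre surface
    keep <- matrix(FALSE, H, W); keep[band_rows, ] <- TRUE
    edges <- edges & keep
    img[edges] <- 255
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    img <- round(pmin(pmax(img, 0), 255))
    image <- fibre_image(img, um_per_px = upp,
                         id = sprintf("sim-%s-d%g-s%d", spec$pattern,
                                      spec$diameter_um, spec$seed))
    list(image = image, truth = truth)
  })
}

#' Construct a fibre image object
#'
#' @param pixels numeric matrix of grey levels (row 1 = top of frame).
#' @param um_per_px physical pixel pitch, um/px (> 0); mandatory because all
#'   downstream measurements are reported in physical units.
#' @param id identifier carried into result tables.
#' @return Object of class `fibre_image`.
#' @export
fibre_image <- function(pixels, um_per_px, id = "fibre") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop_domain("`pixels` must be a non-empty matrix")
  check_positive(um_per_px, "um_per_px")
  structure(list(pixels = pixels, um_per_px = um_per_px, id = as.character(id)),
            class = "fibre_image")
}

#' @export
print.fibre_image <- function(x, ...) {
  cat(sprintf("<fibre_image> '%s': %d x %d px at %g um/px (%g x %g um)\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$um_per_px,
              nrow(x$pixels) * x$um_per_px, ncol(x$pixels) * x$um_per_px))
  invisible(x)
}
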