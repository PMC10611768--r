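# Scale morphometry: diameter, scale-boundary perimeter per 100 um axial
# window, visible-scale count (0.5 rule), SPI, and pattern class.

#' Detect the fibre band in a micrograph
#'
#' Automatic (Otsu) thresholding, retention of the largest connected
#' foreground component, a least-squares axis through the component's pixel
#' centroids (principal axis), and the diameter as the mean of 50 chord
#' lengths measured perpendicular to the axis at evenly spaced stations.
#'
#' @param image a [fibre_image()] containing one straight fibre band.
#' @param n_chords number of perpendicular chords averaged (50 mirrors the
#'   50-reading diameter protocol used with SEM micrographs).
#' @return List with `mask` (logical matrix), `axis` (centroid um, unit
#'   direction, along-axis range um), `diameter_um`, `diameter_cv_pct`,
#'   `threshold`.
#' @export
detect_fibre <- function(image, n_chords = 50L) {
  stopifnot(inherits(image, "fibre_image"))
  img <- image$pixels
  upp <- image$um_per_px
  thr <- otsu_threshold(img)
  largest <- function(threshold) {
    lab <- label_components(img > threshold, connectivity = 4)
    if (max(lab) == 0L) return(list(size = 0L, lab = lab, k = 0L))
    sizes <- tabulate(lab[lab > 0L])
    k <- which.max(sizes)
    list(size = sizes[k], lab = lab, k = k)
  }
  solidity <- function(cand) {
    if (cand$size == 0L) return(0)
    idx <- which(cand$lab == cand$k, arr.ind = TRUE)
    cand$size / (diff(range(idx[, 1])) + 1) / (diff(range(idx[, 2])) + 1)
  }
  cand <- largest(thr)
  # when the fibre band fills most of the frame, the two-class split can
  # land between the band and its bright boundaries, leaving only a sparse
  # web of curves as foreground; a fibre band is a solid block, so re-split
  # the lower greys (background vs band) when the component is not solid
  if (cand$size < 0.10 * length(img) || solidity(cand) < 0.5) {
    thr2 <- otsu_threshold(img[img <= thr])
    cand2 <- largest(thr2)
    if (cand2$size > 0L && solidity(cand2) > solidity(cand)) {
      cand <- cand2; thr <- thr2
    }
  }
  if (cand$size < 0.01 * length(img))
    stop_domain("no fibre: largest component covers < 1% of the frame")
  mask <- cand$lab == cand$k
  touches <- c(any(mask[1, ]), any(mask[nrow(mask), ]),
               any(mask[, 1]), any(mask[, ncol(mask)]))
  if (sum(touches) < 2L)
    warning("fibre fragment: component touches fewer than 2 frame edges",
            call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * upp
  y <- (idx[, 1] - 0.5) * upp
  cx <- mean(x); cy <- mean(y)
  cv <- cov(cbind(x - cx, y - cy))
  eig <- eigen(cv, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (v[1] < 0) v <- -v                  # orient along +x
  along <- (x - cx) * v[1] + (y - cy) * v[2]
  across <- -(x - cx) * v[2] + (y - cy) * v[1]
  # physical pixel extents, not centres: half a pixel beyond each end
  arange <- range(along) + c(-upp / 2, upp / 2)
  span <- diff(arange)
  stations <- seq(arange[1] + 0.02 * span, arange[2] - 0.02 * span,
                  length.out = n_chords)
  half <- upp / 2
  chords <- vapply(stations, function(s) {
    sel <- along >= s - half & along < s + half
    if (!any(sel)) return(NA_real_)
    diff(range(across[sel])) + upp       # pixel extents, inclusive
  }, numeric(1))
  chords <- chords[is.finite(chords)]
  diameter <- mean(chords)
  list(mask = mask,
       axis = list(centroid_um = c(cx, cy), direction = v,
                   along_range_um = arange),
       diameter_um = diameter,
       diameter_cv_pct = 100 * sd(chords) / diameter,
       threshold = thr)
}

#' Segment scale boundaries to a 1-px skeleton
#'
#' Scale boundaries render as bright ridge lines on the fibre surface. The
#' image is lightly smoothed, hysteresis-thresholded relative to the fibre
#' surface grey level inside the mask, morphologically thinned to unit
#' width, and spurs shorter than 3 px are pruned. An empty skeleton is a
#' valid result (a fibre with no visible boundaries).
#'
#' @param image a [fibre_image()].
#' @param mask fibre mask from [detect_fibre()].
#' @param high,low hysteresis thresholds as fractions of the ridge contrast
#'   (max minus median grey inside the mask) above the median.
#' @param min_contrast ridge contrast below which the skeleton is empty.
#' @return Logical matrix, the boundary skeleton.
#' @export
segment_scale_edges <- function(image, mask, high = 0.5, low = 0.25,
                                min_contrast = 20) {
  stopifnot(inherits(image, "fibre_image"))
  img <- smooth3(image$pixels)
  inside <- img[mask]
  med <- median(inside)
  contrast <- max(inside) - med
  empty <- matrix(FALSE, nrow(img), ncol(img))
  if (contrast < min_contrast) return(empty)
  t_high <- med + high * contrast
  t_low <- med + low * contrast
  weak <- img > t_low & mask
  strong <- img > t_high & mask
  if (!any(strong)) return(empty)
  lab <- label_components(weak, connectivity = 8)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0L]
  edges <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  # thinning retracts the ends of thick lines by 1-2 px, which would open
  # gaps where boundaries meet the fibre margin and merge adjacent scale
  # regions; extend the edge support past the mask so the retraction
  # happens outside the band, then crop back
  edges_ext <- edges | (dilate_square(edges, 2) & !mask)
  prune_spurs(thin_mask(edges_ext), min_len = 3) & mask
}

#' Measure scale perimeter and counts per axial window
#'
#' Windows of `window_um` tile the fibre axis starting at the first station
#' where a full window fits; an incomplete trailing window is discarded.
#' The perimeter in a window is the chain-code length of the skeleton edges
#' whose midpoints fall in the window (1 per 4-connected step, sqrt(2) per
#' diagonal step, times the pixel pitch). Scale regions are 4-connected
#' components of the mask minus the skeleton; a region entirely inside a
#' window counts 1, a region cut by a window boundary or by the axial frame
#' ends counts 0.5.
#'
#' @param skeleton logical matrix from [segment_scale_edges()].
#' @param axis axis descriptor from [detect_fibre()].
#' @param mask fibre mask from [detect_fibre()].
#' @param um_per_px pixel pitch, um/px.
#' @param window_um axial window length (100 um is the reference protocol).
#' @param min_region_px regions smaller than this many pixels are treated
#'   as segmentation debris and not counted.
#' @return `data.frame(window_index, start_um, end_um, perimeter_um,
#'   full_scales, partial_scales, scale_count)`.
#' @export
measure_windows <- function(skeleton, axis, mask, um_per_px, window_um = 100,
                            min_region_px = 4) {
  check_positive(window_um, "window_um")
  v <- axis$direction; ctr <- axis$centroid_um
  along_of <- function(idx) {
    x <- (idx[, 2] - 0.5) * um_per_px
    y <- (idx[, 1] - 0.5) * um_per_px
    (x - ctr[1]) * v[1] + (y - ctr[2]) * v[2]
  }
  arange <- axis$along_range_um
  nwin <- floor((diff(arange) + 1e-9) / window_um)
  if (nwin < 1L) stop_domain("fibre too short: axis shorter than one window")
  starts <- arange[1] + (seq_len(nwin) - 1L) * window_um
  ends <- starts + window_um
  # --- skeleton length per window -----------------------------------------
  e <- skeleton_edge_list(skeleton)
  per <- numeric(nwin)
  if (nrow(e) > 0L) {
    a1 <- along_of(cbind(e$r1, e$c1))
    a2 <- along_of(cbind(e$r2, e$c2))
    mid <- (a1 + a2) / 2
    wi <- floor((mid - arange[1]) / window_um) + 1L
    ok <- wi >= 1L & wi <= nwin
    if (any(ok)) {
      sums <- tapply(e$w[ok] * um_per_px, wi[ok], sum)
      per[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  # --- scale regions -------------------------------------------------------
  reg <- mask & !skeleton
  lab <- label_components(reg, connectivity = 4)
  full <- integer(nwin); part <- integer(nwin)
  if (max(lab) > 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    al <- along_of(idx)
    ids <- lab[lab > 0L]
    sz <- tabulate(ids)
    rmin <- tapply(al, ids, min) - um_per_px / 2
    rmax <- tapply(al, ids, max) + um_per_px / 2
    keep <- sz >= min_region_px
    rmin <- rmin[keep]; rmax <- rmax[keep]
    frame_touch <- rmin <= arange[1] + um_per_px | rmax >= arange[2] - um_per_px
    eps <- 1e-6
    for (w in seq_len(nwin)) {
      ov <- rmax > starts[w] + eps & rmin < ends[w] - eps
      ins <- ov & rmin >= starts[w] - eps & rmax <= ends[w] + eps & !frame_touch
      full[w] <- sum(ins)
      part[w] <- sum(ov & !ins)
    }
  }
  data.frame(window_index = seq_len(nwin),
             start_um = starts - arange[1], end_um = ends - arange[1],
             perimeter_um = per,
             full_scales = full, partial_scales = part,
             scale_count = full + 0.5 * part)
}

#' Scale perimeter index (SPI)
#'
#' The total scale perimeter per 100 um length of fibre divided by the
#' fibre diameter; dimensionless, and scale-invariant under a common
#' rescaling of both arguments.
#'
#' @param perimeter_per_100um total scale perimeter in a 100 um window, um.
#' @param diameter_um fibre diameter, um (> 0).
#' @return `perimeter_per_100um / diameter_um`.
#' @examples
#' round(compute_spi(542, 36), 1)  # 15.1
#' @export
compute_spi <- function(perimeter_per_100um, diameter_um) {
  if (any(diameter_um <= 0)) stop_domain("`diameter_um` must be > 0")
  if (any(perimeter_per_100um < 0)) stop_domain("perimeter must be >= 0")
  perimeter_per_100um / diameter_um
}

#' Diameter-based scale pattern class
#'
#' Fine fibres (< 25 um) show the coronal pattern, medium fibres (25-50 um,
#' boundaries inclusive) the coronal-reticulate pattern, and coarse fibres
#' (> 50 um) the reticulate pattern.
#'
#' @param diameter_um fibre diameter(s), um (> 0).
#' @return Character vector: `"coronal"`, `"coronal_reticulate"` or
#'   `"reticulate"`.
#' @export
classify_pattern <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop_domain("`diameter_um` must be > 0")
  ifelse(diameter_um < 25, "coronal",
         ifelse(diameter_um <= 50, "coronal_reticulate", "reticulate"))
}

#' Full morphometric measurement of one fibre image
#'
#' Runs [detect_fibre()], [segment_scale_edges()] and [measure_windows()],
#' then aggregates: the total scale perimeter per 100 um is the mean over
#' windows, the visible-scale count is the window mean rounded to the 0.5
#' granularity, SPI is perimeter over diameter, and the pattern class
#' follows the diameter thresholds.
#'
#' @param image a [fibre_image()].
#' @param window_um axial window length, um.
#' @param ... passed to [measure_windows()].
#' @return Object of class `fibre_measurement`.
#' @export
measure_fibre <- function(image, window_um = 100, ...) {
  det <- detect_fibre(image)
  skel <- segment_scale_edges(image, det$mask)
  win <- measure_windows(skel, det$axis, det$mask, image$um_per_px,
                         window_um = window_um, ...)
  total <- mean(win$perimeter_um)
  m <- structure(list(id = image$id,
                      diameter_um = det$diameter_um,
                      diameter_cv_pct = det$diameter_cv_pct,
                      windows = win,
                      total_perimeter_per_100um = total,
                      scales_per_100um = round_half(mean(win$scale_count)),
                      spi = compute_spi(total, det$diameter_um),
                      pattern = classify_pattern(det$diameter_um)),
                 class = "fibre_measurement")
  m
}

#' @export
print.fibre_measurement <- function(x, ...) {
  cat(sprintf(
    "<fibre_measurement> '%s'\n  diameter: %.1f um (CV %.1f%%), pattern: %s\n  perimeter/100um: %.0f um over %d window(s), scales/100um: %.1f, SPI: %.1f\n",
    x$id, x$diameter_um, x$diameter_cv_pct, x$pattern,
    x$total_perimeter_per_100um, nrow(x$windows), x$scales_per_100um, x$spi))
  invisible(x)
}

#' Flatten fibre measurements to a data frame
#'
#' @param measurements list of `fibre_measurement` objects.
#' @return One row per fibre with the per-fibre summary columns.
#' @export
measurements_to_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m)
    data.frame(id = m$id, diameter_um = m$diameter_um,
               diameter_cv_pct = m$diameter_cv_pct,
               perimeter_per_100um = m$total_perimeter_per_100um,
               scale_count = m$scales_per_100um,
               spi = m$spi, pattern = m$pattern)))
}
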