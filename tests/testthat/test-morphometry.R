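# Scale morphometry: detection, segmentation, windowed measurement, SPI,
# pattern classes.

test_that("a constant-width band yields an exact diameter with zero CV", {
  img <- make_band_image(width_px = 20, length_px = 160, um_per_px = 0.5)
  det <- detect_fibre(img)
  expect_equal(det$diameter_um, 20 * 0.5, tolerance = 1e-9)
  expect_equal(det$diameter_cv_pct, 0, tolerance = 1e-9)
})

test_that("featureless frames and fragments are flagged", {
  flat <- fibre_image(matrix(30, 40, 60), um_per_px = 0.5)
  expect_error(detect_fibre(flat), "no fibre")
  frag <- fibre_image({m <- matrix(30, 60, 60); m[25:35, 20:40] <- 128; m},
                      um_per_px = 0.5)
  expect_warning(detect_fibre(frag), "fragment")
})

test_that("synthetic fibre diameters are recovered within 1 um", {
  g <- generate_fibre_image(image_spec(22, pattern = "coronal",
                                       scales_per_100um = 6, noise_sd = 0, seed = 1))
  det <- detect_fibre(g$image)
  expect_lt(abs(det$diameter_um - 22), 1)
})

test_that("segmentation recovers each drawn arc as one component", {
  g <- generate_fibre_image(image_spec(22, length_um = 300, pattern = "coronal",
                                       scales_per_100um = 6, noise_sd = 0, seed = 42))
  det <- detect_fibre(g$image)
  sk <- segment_scale_edges(g$image, det$mask)
  expect_equal(max(label_components(sk, 8)), 18)  # 6 arcs x 3 windows
  # a boundary-free image gives an empty skeleton
  img0 <- make_band_image()
  det0 <- detect_fibre(img0)
  expect_equal(sum(segment_scale_edges(img0, det0$mask)), 0)
})

test_that("a straight transverse boundary measures its chord length", {
  sp <- image_spec(30, length_um = 300, pattern = "coronal",
                   scales_per_100um = 1, noise_sd = 0, seed = 2,
                   arc_sagitta_frac = 0)
  g <- generate_fibre_image(sp)
  det <- detect_fibre(g$image)
  sk <- segment_scale_edges(g$image, det$mask)
  win <- measure_windows(sk, det$axis, det$mask, g$image$um_per_px)
  # one chord of length = diameter per window, within sqrt(2) px
  tol <- sqrt(2) * g$image$um_per_px
  expect_true(all(abs(win$perimeter_um - 30) <= tol + 1e-9))
})

test_that("the 0.5 counting rule: interior regions 1, cut regions 0.5", {
  # hand-built scene: 120 um band with 6 transverse skeleton lines; the
  # single 100 um window holds 5 interior regions plus 2 cut regions
  # (frame-touching head, window-boundary-crossing tail) -> 6.0
  upp <- 1
  mask <- matrix(TRUE, 20, 120)
  skel <- matrix(FALSE, 20, 120)
  for (cc in c(15, 30, 45, 60, 75, 90)) skel[, cc] <- TRUE
  axis <- make_axis(length_um = 120, centre_um = c(60, 10))
  win <- measure_windows(skel, axis, mask, um_per_px = upp, window_um = 100)
  expect_equal(nrow(win), 1L)
  expect_equal(win$full_scales, 5L)
  expect_equal(win$partial_scales, 2L)
  expect_equal(win$scale_count, 6)
  # perimeter: 6 lines x 20 px x (19 unit steps each) -> 19 um per line
  expect_equal(win$perimeter_um, 6 * 19)
  # empty skeleton: zero perimeter, the whole band is one frame-cut region
  win0 <- measure_windows(matrix(FALSE, 20, 120), axis, mask, upp)
  expect_equal(win0$perimeter_um, 0)
  expect_equal(win0$scale_count, 0.5)
})

test_that("a fibre shorter than one window is rejected", {
  mask <- matrix(TRUE, 10, 50)
  axis <- make_axis(length_um = 50, centre_um = c(25, 5))
  expect_error(measure_windows(matrix(FALSE, 10, 50), axis, mask, 1),
               "too short")
})

test_that("compute_spi reproduces worked examples and is scale-invariant", {
  expect_equal(round(compute_spi(542, 36), 1), 15.1)
  expect_equal(compute_spi(0, 17), 0)
  spi_dartmoor <- compute_spi(754, 72)
  expect_equal(spi_dartmoor, 10.47, tolerance = 1e-3)
  expect_true(spi_dartmoor >= 6 && spi_dartmoor <= 11)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(1, 10, 900); d <- runif(1, 15, 90); c0 <- runif(1, 0.1, 10)
    expect_equal(compute_spi(c0 * p, c0 * d), compute_spi(p, d), tolerance = 1e-12)
  }
  expect_error(compute_spi(100, 0), "diameter")
})

test_that("pattern classes follow the diameter thresholds", {
  expect_identical(classify_pattern(22), "coronal")
  expect_identical(classify_pattern(36), "coronal_reticulate")
  expect_identical(classify_pattern(72), "reticulate")
  # interval is closed at both stated boundaries
  expect_identical(classify_pattern(c(25, 50)),
                   c("coronal_reticulate", "coronal_reticulate"))
  expect_identical(classify_pattern(c(24.99, 50.01)),
                   c("coronal", "reticulate"))
  expect_error(classify_pattern(0), "diameter")
})

test_that("dense reticulate fibres count ~16 scales per 100 um", {
  # a longer fibre dilutes the frame-cut 0.5-count deflation (two end cells
  # shared over all windows), so the window mean reflects the density
  g <- generate_fibre_image(image_spec(72, length_um = 500, pattern = "reticulate",
                                       scales_per_100um = 16, noise_sd = 0, seed = 5))
  m <- measure_fibre(g$image)
  expect_lt(abs(m$scales_per_100um - 16), 1 + 1e-9)
  # and the measurement tracks the generator's exact ground truth closely
  expect_lt(abs(m$scales_per_100um - mean(g$truth$scale_count_per_window)), 1)
  expect_identical(m$pattern, "reticulate")
})

test_that("measured perimeter rises strictly with boundary density", {
  per <- vapply(c(4, 8, 12), function(s) {
    g <- generate_fibre_image(image_spec(40, pattern = "coronal",
                                         scales_per_100um = s, noise_sd = 0, seed = 8))
    measure_fibre(g$image)$total_perimeter_per_100um
  }, numeric(1))
  expect_true(all(diff(per) > 0))
})

test_that("measure_fibre aggregates consistently (SPI identity, 0.5 counts)", {
  g <- generate_fibre_image(image_spec(36, pattern = "coronal_reticulate",
                                       scales_per_100um = 8, noise_sd = 8, seed = 12))
  m <- measure_fibre(g$image)
  expect_equal(m$spi, m$total_perimeter_per_100um / m$diameter_um, tolerance = 1e-9)
  expect_true(m$scales_per_100um * 2 == round(m$scales_per_100um * 2))
  expect_true(all(m$windows$perimeter_um >= 0))
  expect_identical(m$pattern, classify_pattern(m$diameter_um))
  tab <- measurements_to_table(list(m))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$spi, m$spi)
})
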