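# Synthetic image generator: analytic ground truth and determinism.

test_that("straight transverse boundaries give chord-length ground truth", {
  # one straight boundary per window: boundary length per window = diameter
  for (d in c(18, 30, 55)) {
    sp <- image_spec(d, length_um = 300, pattern = "coronal",
                     scales_per_100um = 1, noise_sd = 0, seed = 3,
                     arc_sagitta_frac = 0)
    g <- generate_fibre_image(sp)
    expect_equal(g$truth$boundary_length_per_window, rep(d, 3), tolerance = 1e-12)
    expect_equal(g$truth$true_diameter_um, d)
  }
})

test_that("coronal geometry: n arcs per window, interior count n", {
  sp <- image_spec(22, length_um = 300, pattern = "coronal",
                   scales_per_100um = 6, noise_sd = 0, seed = 42)
  g <- generate_fibre_image(sp)
  expect_equal(g$truth$scale_count_per_window, c(6, 6, 6))
  # arc length: chord 22 um with sagitta 0.15*22; all windows equal
  expect_equal(length(unique(round(g$truth$boundary_length_per_window, 9))), 1)
  arc <- g$truth$boundary_length_per_window[1] / 6
  expect_gt(arc, 22)          # arcs are longer than their chord
  expect_lt(arc, pi * 22 / 2) # but shorter than a semicircle
})

test_that("seeded generation is bit-reproducible", {
  for (pat in c("coronal", "reticulate")) {
    sp <- image_spec(40, pattern = pat, noise_sd = 8, seed = 7)
    a <- generate_fibre_image(sp)
    b <- generate_fibre_image(sp)
    expect_identical_matrix(a$image$pixels, b$image$pixels)
    expect_identical(a$truth, b$truth)
  }
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_fibre_image(image_spec(30, seed = 5)))
  expect_identical(runif(1), before)
})

test_that("ground truth invariants hold across patterns and seeds", {
  for (seed in 1:4) {
    for (pat in c("coronal", "coronal_reticulate", "reticulate")) {
      g <- generate_fibre_image(image_spec(35 + 5 * seed, pattern = pat,
                                           noise_sd = 0, seed = seed))
      tr <- g$truth
      expect_true(all(tr$boundary_length_per_window >= 0))
      expect_true(all(tr$scale_count_per_window * 2 ==
                        round(tr$scale_count_per_window * 2)))
      expect_true(all(tr$scale_count_per_window >= 0))
    }
  }
})

test_that("unresolvable or invalid specs are rejected", {
  expect_error(image_spec(30, length_um = 80), "length_um")
  expect_error(image_spec(-3), "diameter_um")
  expect_error(image_spec(30, scales_per_100um = 0), "scales_per_100um")
  # spacing below 2 x edge width at this pixel pitch
  sp <- image_spec(60, um_per_px = 1, scales_per_100um = 30, edge_width_px = 2)
  expect_error(generate_fibre_image(sp), "unresolvable")
})
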