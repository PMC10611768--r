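# Diffusion-coefficient estimation from uptake kinetics.

test_that("absorbance converts through the calibration line", {
  cal <- list(slope = 2, intercept = 0)
  expect_equal(absorbance_to_concentration(0.8, cal), 0.4)
  expect_equal(absorbance_to_concentration(0.1, list(slope = 3, intercept = 0.1)), 0)
  expect_error(absorbance_to_concentration(1, list(slope = 0)), "slope")
  # round trip: concentration -> absorbance -> concentration
  cal <- list(slope = 1.7, intercept = 0.05)
  ce <- c(0, 0.12, 0.4)
  expect_equal(absorbance_to_concentration(cal$slope * ce + cal$intercept, cal),
               ce, tolerance = 1e-12)
})

test_that("Mt follows the mass balance (C0 - Ce) V / W", {
  expect_equal(compute_Mt(0.4, 0.1, 50, 1), 15)    # 2% omf, 1:50 liquor
  expect_equal(compute_Mt(0.4, 0, 50, 1), 20)      # full exhaustion
  expect_equal(compute_Mt(0.4, 0.4, 50, 1), 0)
  expect_warning(out <- compute_Mt(0.4, 0.45, 50, 1), "clipped")
  expect_equal(out, 0)
  expect_error(compute_Mt(0.4, 0.1, 50, 0), "W")
})

test_that("Me estimation: plateau mean, user override, no-plateau flag", {
  s_const <- uptake_series(seq(5, 240, by = 5), rep(7.5, 48))
  expect_equal(as.numeric(estimate_Me(s_const)), 7.5)
  expect_true(is.na(attr(estimate_Me(s_const), "flag")))
  # plateau round trip on a noise-free saturating series
  sp <- kinetics_spec(0.4e-8, 12e-4, Me = 18, model = "cylinder_series")
  s <- generate_uptake_series(sp)
  expect_equal(as.numeric(estimate_Me(s)), 18, tolerance = 1e-3)
  # strictly rising, never plateaus
  s_rise <- uptake_series(c(60, 120, 180, 240), c(1, 2, 3, 4))
  me <- estimate_Me(s_rise)
  expect_equal(as.numeric(me), 3.5)
  expect_identical(attr(me, "flag"), "no plateau")
  expect_equal(as.numeric(estimate_Me(s_rise, value = 9)), 9)
})

test_that("fit_hill recovers D exactly from noise-free hill_early data", {
  for (D in c(0.09e-8, 0.59e-8)) {
    for (r in c(11e-4, 36e-4)) {
      tc <- r^2 / D
      # geometric grid so every cutoff keeps >= 3 early points; capped
      # below T = pi/16 where the hill model saturates (Mt clips to Me)
      tmin <- 10^seq(log10(2e-4), log10(0.15), length.out = 40) * tc / 60
      s <- generate_uptake_series(kinetics_spec(D, r, Me = 18, times_min = tmin))
      for (cutoff in c(0.2, 0.5, 1)) {
        f <- fit_hill(s, Me = 18, cutoff = cutoff)
        expect_lt(abs(f$D / D - 1), 1e-9)
        # structural invariant D = k^2 pi r^2 / 16
        expect_lt(abs(f$D - f$slope_k^2 * pi * r^2 / 16), 1e-12 * f$D + 1e-30)
        expect_gt(f$r_squared, 1 - 1e-12)
      }
    }
  }
})

test_that("D scales with the square of the radius at fixed slope", {
  D <- 0.2e-8; r <- 14e-4
  tc <- r^2 / D
  tmin <- seq(0.002, 0.2, length.out = 20) * tc / 60
  s <- generate_uptake_series(kinetics_spec(D, r, Me = 18, times_min = tmin))
  f1 <- fit_hill(s, Me = 18, radius_cm = r)
  f2 <- fit_hill(s, Me = 18, radius_cm = 2 * r)
  expect_equal(f2$slope_k, f1$slope_k)
  expect_equal(f2$D / f1$D, 4, tolerance = 1e-12)
})

test_that("cylinder-data bias grows monotonically with the cutoff", {
  # the Hill line is exact only as t -> 0; fitting the exact cylinder
  # solution underestimates D, increasingly so for later cutoffs
  D <- 0.13e-8; r <- 15.5e-4; tc <- r^2 / D
  tmin <- seq(0.0005, 0.06, by = 0.0005) * tc / 60
  s <- generate_uptake_series(kinetics_spec(D, r, Me = 18, times_min = tmin,
                                            model = "cylinder_series"))
  ratio <- vapply(c(0.1, 0.3, 0.5), function(co)
    fit_hill(s, Me = 18, cutoff = co)$D / D, numeric(1))
  expect_true(all(diff(ratio) < 0))
  expect_true(all(ratio < 1))
  # oracle-frozen magnitudes: ~0.97 at cutoff 0.1, ~0.90 at 0.3
  expect_equal(ratio[1], 0.966, tolerance = 0.02)
  expect_equal(ratio[2], 0.899, tolerance = 0.02)
})

test_that("degenerate fits are flagged rather than extrapolated", {
  s0 <- uptake_series(c(5, 10, 15, 20), rep(0, 4))
  f0 <- fit_hill(s0, Me = 1, radius_cm = 12e-4)
  expect_equal(f0$D, 0)
  # apparent negative uptake (noise below the blank) gives a negative slope
  s_neg <- uptake_series(c(5, 10, 15, 20), c(-0.05, -0.1, -0.12, -0.15))
  f_neg <- fit_hill(s_neg, Me = 1, radius_cm = 12e-4)
  expect_equal(f_neg$D, 0)
  expect_identical(f_neg$flag, "negative slope")
  s_short <- uptake_series(c(5, 10), c(0.1, 0.2))
  expect_error(fit_hill(s_short, Me = 1, radius_cm = 12e-4), "insufficient")
})

test_that("replicate aggregation reports mean and standard error", {
  mk <- function(D) structure(list(D = D), class = "diffusion_fit")
  agg <- aggregate_replicates(list(mk(0.090e-8), mk(0.092e-8)))
  expect_equal(agg$mean_D, 0.091e-8)
  expect_equal(agg$stderr_D, 0.001e-8, tolerance = 1e-12)
  one <- aggregate_replicates(list(mk(0.2e-8)))
  expect_equal(one$stderr_D, 0)
  expect_identical(one$flag, "n=1")
  same <- aggregate_replicates(list(mk(1e-9), mk(1e-9), mk(1e-9)))
  expect_equal(same$stderr_D, 0)
})
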