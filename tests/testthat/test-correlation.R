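# Correlation framework: quadratic-through-origin fit, SPI bands, linear
# D relations, new-breed validation.

test_that("noise-free quadratic data are interpolated exactly", {
  truth <- correlation_model(14.41, -0.04)
  tab <- generate_measurement_table(40, c(19, 80), truth, noise_sd = 0, seed = 3)
  fit <- fit_perimeter_model(tab$diameter_um, tab$perimeter_per_100um)
  expect_lt(abs(fit$a - 14.41), 1e-9)
  expect_lt(abs(fit$b - (-0.04)), 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_gt(fit$r_squared_uncentered, 1 - 1e-9)
})

test_that("pure linear data yield a zero quadratic coefficient", {
  x <- c(10, 20, 30, 45, 60)
  fit <- fit_perimeter_model(x, 7.3 * x)
  expect_equal(fit$a, 7.3, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
})

test_that("coefficients match the normal-equations oracle on small tables", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    x <- runif(n, 15, 90)
    y <- 12 * x - 0.03 * x^2 + rnorm(n, 0, 20)
    fit <- fit_perimeter_model(x, y)
    want <- oracle_quadratic_fit(x, y)
    expect_equal(c(fit$a, fit$b), unname(want), tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_perimeter_model(c(10, 10, 10), c(1, 2, 3)), "distinct")
  expect_error(fit_perimeter_model(c(-1, 10, 20), c(1, 2, 3)), "> 0")
  expect_error(fit_perimeter_model(c(10, 20), c(1, 2)), "distinct")
})

test_that("predict_perimeter evaluates the quadratic and guards its range", {
  m <- correlation_model(14.41, -0.04)
  expect_equal(predict_perimeter(m, 0), 0)
  expect_equal(predict_perimeter(m, 36), 466.92, tolerance = 1e-12)
  expect_equal(predict_perimeter(m, 72), 830.16, tolerance = 1e-12)
  expect_warning(predict_perimeter(m, 200), "vertex")
  expect_error(predict_perimeter(m, -5), ">= 0")
})

test_that("SPI band check assigns bands and flags membership", {
  expect_identical(spi_band_check(72, 10.5),
                   list(band = "coarse", in_range = TRUE, spi_range = c(6, 11)))
  fine_off <- spi_band_check(22, 25)
  expect_identical(fine_off$band, "fine")
  expect_false(fine_off$in_range)
  # the medium band read strictly excludes 15.1 (the source narrative is
  # internally inconsistent here; the strict band is used)
  med <- spi_band_check(36, 15.1)
  expect_identical(med$band, "medium")
  expect_false(med$in_range)
  expect_true(spi_band_check(36, 15.0)$in_range)
  # below the finest band: no extrapolation
  expect_identical(spi_band_check(17, 18)$band, "unclassified")
  # boundaries: 29.5 um is medium (bands tile the axis), 65 medium, 66 coarse
  expect_identical(spi_band_check(29.5, 14)$band, "fine")
  expect_identical(spi_band_check(30, 14)$band, "medium")
  expect_identical(spi_band_check(65, 11)$band, "medium")
  expect_identical(spi_band_check(66, 10)$band, "coarse")
})

test_that("breed-level linear relations fit by OLS", {
  exact <- fit_linear_relation(c(1, 2, 3, 4), 0.1 + 0.05 * c(1, 2, 3, 4))
  expect_equal(exact$slope, 0.05, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  # breed triples: perimeter vs D has a positive slope
  tri <- fit_linear_relation(c(309, 510, 754), c(0.091, 0.133, 0.592),
                             "avg_perimeter_per_100um")
  expect_gt(tri$slope, 0)
  two <- fit_linear_relation(c(22, 72), c(0.091, 0.592))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_linear_relation(c(5, 5), c(1, 2)), "identical")
})

test_that("new-breed validation reports residual, band and pattern checks", {
  m <- correlation_model(14.41, -0.04)
  v <- validate_new_breed(36, 542, m, observed_pattern = "coronal_reticulate",
                          id = "validation fibre")
  expect_equal(v$residual, 542 - 466.92, tolerance = 1e-9)
  expect_identical(v$expected_pattern, "coronal_reticulate")
  expect_true(v$pattern_match)
  expect_identical(v$band, "medium")
  on_curve <- validate_new_breed(40, predict_perimeter(m, 40), m)
  expect_equal(on_curve$residual, 0, tolerance = 1e-12)
})

test_that("model-implied SPI falls with diameter when b < 0", {
  m <- correlation_model(14.41, -0.04)
  x <- seq(5, 120, by = 5)
  spi <- predict_perimeter(m, x) / x
  expect_true(all(diff(spi) < 0))
  expect_equal(spi, m$a + m$b * x, tolerance = 1e-12)
})

test_that("breed summaries aggregate per-fibre tables", {
  tab <- data.frame(breed = rep(c("A", "B"), each = 3),
                    diameter_um = c(20, 22, 24, 70, 72, 74),
                    perimeter_per_100um = c(300, 310, 320, 740, 754, 768),
                    scale_count = c(6, 6, 6, 16, 16, 16))
  s <- summarise_breed_table(tab)
  expect_equal(s$mean_perimeter_per_100um, c(310, 754))
  expect_equal(s$mean_diameter_um, c(22, 72))
  expect_equal(s$n, c(3L, 3L))
})
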