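# Synthetic per-fibre measurement tables (diameter, perimeter, scale count),
# emulating a per-fibre morphometry spreadsheet.

#' Generate a synthetic per-fibre measurement table
#'
#' Samples fibre diameters uniformly over `diameter_range`, evaluates the
#' through-origin quadratic perimeter law `a*x + b*x^2` of `model`, adds
#' seeded Gaussian noise (clipped at 0), and derives a visible-scale count
#' by dividing the perimeter by a typical single-scale boundary length and
#' rounding to the 0.5-count granularity.
#'
#' @param n_fibres number of fibres (>= 3).
#' @param diameter_range `c(min, max)` diameters, um.
#' @param model a [correlation_model()] (or any list with elements `a`, `b`).
#' @param noise_sd Gaussian noise on perimeter, um.
#' @param seed RNG seed.
#' @param scale_perimeter_um mean boundary length of a single scale used for
#'   the count column (um). ~50 um is typical of the studied wools
#'   (breed-average perimeter / breed-average count ranges 47-52).
#' @return `data.frame(diameter_um, perimeter_per_100um, scale_count)`.
#' @export
generate_measurement_table <- function(n_fibres, diameter_range, model,
                                       noise_sd = 0, seed = 1,
                                       scale_perimeter_um = 50) {
  if (n_fibres < 3) stop_domain("`n_fibres` must be >= 3")
  if (length(diameter_range) != 2L || diameter_range[1] <= 0 ||
      diameter_range[2] < diameter_range[1])
    stop_domain("`diameter_range` must be c(min, max) with 0 < min <= max")
  check_nonneg(noise_sd, "noise_sd")
  with_seed(seed, {
    x <- runif(n_fibres, diameter_range[1], diameter_range[2])
    y <- model$a * x + model$b * x^2 + rnorm(n_fibres, 0, noise_sd)
    y <- pmax(0, y)
    data.frame(diameter_um = x,
               perimeter_per_100um = y,
               scale_count = round_half(y / scale_perimeter_um))
  })
}
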