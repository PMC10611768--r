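# Correlation framework: the through-origin quadratic perimeter-diameter
# law y = a*x + b*x^2, SPI diameter bands, breed-level linear relations
# between the diffusion coefficient and morphology, and validation of a
# new fibre type against the fitted framework.

#' Construct a correlation model
#'
#' @param a linear coefficient, um per um.
#' @param b quadratic coefficient, um per um^2.
#' @param r_squared centered coefficient of determination.
#' @param r_squared_uncentered uncentered variant (through-origin fits have
#'   no unique R^2 convention; both are carried).
#' @param n number of fibres fitted.
#' @param response `"perimeter"` or `"scale_count"`.
#' @return Object of class `correlation_model`.
#' @export
correlation_model <- function(a, b, r_squared = NA_real_,
                              r_squared_uncentered = NA_real_,
                              n = NA_integer_,
                              response = c("perimeter", "scale_count")) {
  response <- match.arg(response)
  structure(list(a = a, b = b, r_squared = r_squared,
                 r_squared_uncentered = r_squared_uncentered,
                 n = n, response = response),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> %s = %.4g*x %+.4g*x^2  (R^2 = %.4f, n = %s)\n",
              x$response, x$a, x$b,
              x$r_squared, ifelse(is.na(x$n), "?", x$n)))
  if (!is.na(x$b) && x$b < 0)
    cat(sprintf("  monotone increasing up to the vertex x = %.1f um\n",
                x$a / (2 * abs(x$b))))
  invisible(x)
}

#' Fit the through-origin quadratic perimeter model
#'
#' Least squares over the basis `{x, x^2}` with no intercept: the boundary
#' perimeter must vanish at zero diameter. The centered R^2
#' (`1 - SS_res / sum((y - mean(y))^2)`) is reported as the headline
#' goodness of fit; the uncentered variant is carried alongside.
#'
#' @param x fibre diameters, um (> 0, >= 3 distinct values).
#' @param y response (perimeter per 100 um, or scale count), same length.
#' @param response which quantity `y` is.
#' @return A [correlation_model()].
#' @export
fit_perimeter_model <- function(x, y, response = c("perimeter", "scale_count")) {
  response <- match.arg(response)
  if (length(x) != length(y)) stop_domain("`x` and `y` must have equal length")
  if (length(unique(x)) < 3L) stop_domain("need >= 3 distinct x values")
  if (any(x <= 0)) stop_domain("diameters must be > 0")
  X <- cbind(x = x, x2 = x^2)
  fit <- lm.fit(X, y)
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop_domain("degenerate design: collinear basis")
  res <- y - X %*% cf
  ss_res <- sum(res^2)
  r2c <- 1 - ss_res / sum((y - mean(y))^2)
  r2u <- 1 - ss_res / sum(y^2)
  correlation_model(a = unname(cf[1]), b = unname(cf[2]),
                    r_squared = r2c, r_squared_uncentered = r2u,
                    n = length(y), response = response)
}

#' Predict perimeter (or scale count) from diameter
#'
#' Evaluates `a*x + b*x^2`. When `b < 0` the curve is only monotone up to
#' its vertex `a / (2|b|)`; predictions beyond the vertex are returned with
#' a warning since they extrapolate past the physically meaningful range.
#'
#' @param model a [correlation_model()].
#' @param x diameter(s), um (>= 0; a zero-diameter fibre has zero perimeter).
#' @return Predicted response, um.
#' @examples
#' m <- correlation_model(14.41, -0.04)
#' predict_perimeter(m, 36)  # 466.92
#' @export
predict_perimeter <- function(model, x) {
  stopifnot(inherits(model, "correlation_model"))
  if (any(x < 0)) stop_domain("`x` must be >= 0")
  if (model$b < 0) {
    vertex <- model$a / (2 * abs(model$b))
    if (any(x > vertex))
      warning(sprintf("prediction beyond the model vertex (%.1f um): extrapolation", vertex),
              call. = FALSE)
  }
  model$a * x + model$b * x^2
}

#' Reference SPI diameter bands
#'
#' Fine fibres (19-29 um) carry SPI 14-20, medium fibres (30-65 um) SPI
#' 11-15 and coarse fibres (> 65 um) SPI 6-11. Diameters between the stated
#' fine and medium limits (29-30 um) fall to the medium band so the bands
#' tile the diameter axis; below 19 um is unclassified (no extrapolation).
#'
#' @return Object of class `spi_bands`: a data.frame with columns `band`,
#'   `d_lo`, `d_hi`, `spi_lo`, `spi_hi`.
#' @export
spi_bands <- function() {
  structure(data.frame(band = c("fine", "medium", "coarse"),
                       d_lo = c(19, 30, 65),
                       d_hi = c(30, 65, Inf),
                       spi_lo = c(14, 11, 6),
                       spi_hi = c(20, 15, 11)),
            class = c("spi_bands", "data.frame"))
}

#' Check an SPI value against its diameter band
#'
#' Assigns the band by diameter (fine: 19 to < 30 um, medium: 30-65 um,
#' coarse: > 65 um) and flags whether the SPI lies inside that band's
#' inclusive range. Diameters below 19 um return band `"unclassified"`
#' with `in_range = NA`.
#'
#' @param diameter_um fibre diameter, um (> 0).
#' @param spi scale perimeter index.
#' @param bands an `spi_bands` table (default [spi_bands()]).
#' @return `list(band, in_range, spi_range)`.
#' @export
spi_band_check <- function(diameter_um, spi, bands = spi_bands()) {
  check_positive(diameter_um, "diameter_um")
  if (diameter_um < min(bands$d_lo))
    return(list(band = "unclassified", in_range = NA, spi_range = c(NA, NA)))
  # fine [19, 30), medium [30, 65], coarse (65, Inf)
  i <- if (diameter_um > bands$d_hi[2]) 3L else if (diameter_um >= bands$d_lo[2]) 2L else 1L
  rng <- c(bands$spi_lo[i], bands$spi_hi[i])
  list(band = bands$band[i],
       in_range = spi >= rng[1] & spi <= rng[2],
       spi_range = rng)
}

#' Ordinary least-squares line through breed-level points
#'
#' Fits `D ~ predictor` across breed-level summaries (mean diameter,
#' average perimeter per 100 um, or average scale count) by OLS.
#'
#' @param predictor numeric vector (>= 2 points, not all equal).
#' @param D response (diffusion coefficients, any consistent unit).
#' @param predictor_name label stored in the result.
#' @return Object of class `linear_relation`: `list(predictor, slope,
#'   intercept, r_squared, n)`.
#' @export
fit_linear_relation <- function(predictor, D,
                                predictor_name = "mean_diameter") {
  if (length(predictor) != length(D)) stop_domain("lengths differ")
  if (length(predictor) < 2L) stop_domain("need >= 2 points")
  if (var(predictor) == 0) stop_domain("identical predictor values: slope undefined")
  fit <- lm(D ~ predictor)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((D - mean(D))^2)
  structure(list(predictor = predictor_name,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(D)),
            class = "linear_relation")
}

#' @export
print.linear_relation <- function(x, ...) {
  cat(sprintf("<linear_relation> D = %.4g + %.4g * %s (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$predictor, x$r_squared, x$n))
  invisible(x)
}

#' Validate a new fibre type against the correlation framework
#'
#' Compares a measured fibre (or breed summary) with the fitted quadratic:
#' residual = measured minus predicted perimeter, plus SPI band membership
#' and the expected pattern class for the measured diameter.
#'
#' @param diameter_um measured mean diameter, um.
#' @param perimeter_per_100um measured total scale perimeter per 100 um, um.
#' @param model a [correlation_model()].
#' @param bands an `spi_bands` table.
#' @param observed_pattern optional observed pattern class to compare with
#'   the diameter-implied one.
#' @param id label for the report.
#' @return Object of class `validation_report`.
#' @export
validate_new_breed <- function(diameter_um, perimeter_per_100um, model,
                               bands = spi_bands(), observed_pattern = NULL,
                               id = "new breed") {
  check_positive(diameter_um, "diameter_um")
  check_nonneg(perimeter_per_100um, "perimeter_per_100um")
  predicted <- predict_perimeter(model, diameter_um)
  spi <- compute_spi(perimeter_per_100um, diameter_um)
  band <- spi_band_check(diameter_um, spi, bands)
  expected_pattern <- classify_pattern(diameter_um)
  structure(list(id = id,
                 diameter_um = diameter_um,
                 measured_perimeter = perimeter_per_100um,
                 predicted_perimeter = predicted,
                 residual = perimeter_per_100um - predicted,
                 spi = spi,
                 band = band$band, spi_in_band = band$in_range,
                 spi_range = band$spi_range,
                 expected_pattern = expected_pattern,
                 observed_pattern = observed_pattern,
                 pattern_match = if (is.null(observed_pattern)) NA
                                 else identical(observed_pattern, expected_pattern)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> '%s' (d = %.1f um)\n", x$id, x$diameter_um))
  cat(sprintf("  perimeter: measured %.1f um, predicted %.1f um, residual %+.1f um\n",
              x$measured_perimeter, x$predicted_perimeter, x$residual))
  cat(sprintf("  SPI %.1f -> band '%s' [%g, %g], in range: %s\n",
              x$spi, x$band, x$spi_range[1], x$spi_range[2], x$spi_in_band))
  cat(sprintf("  pattern expected: %s%s\n", x$expected_pattern,
              if (!is.null(x$observed_pattern))
                sprintf(", observed: %s (match: %s)", x$observed_pattern, x$pattern_match)
              else ""))
  invisible(x)
}

#' Breed-level summary of a per-fibre table
#'
#' @param table data.frame with columns `breed`, `diameter_um`,
#'   `perimeter_per_100um`, `scale_count`.
#' @return One row per breed with means and standard deviations.
#' @export
summarise_breed_table <- function(table) {
  stopifnot(all(c("breed", "diameter_um", "perimeter_per_100um", "scale_count")
                %in% names(table)))
  breeds <- unique(table$breed)
  do.call(rbind, lapply(breeds, function(b) {
    d <- table[table$breed == b, ]
    data.frame(breed = b,
               n = nrow(d),
               mean_diameter_um = mean(d$diameter_um),
               mean_perimeter_per_100um = mean(d$perimeter_per_100um),
               sd_perimeter_per_100um = sd(d$perimeter_per_100um),
               mean_scale_count = mean(d$scale_count))
  }))
}
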