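# Dye-bath kinetics: absorbance -> concentration -> Mt, and the apparent
# diffusion coefficient from the early-phase Hill fit
#   Mt/Me = 4 * sqrt(D t / (pi r^2)),
# i.e. D = slope^2 * pi * r^2 / 16 where slope is the through-origin
# least-squares slope of Mt/Me against sqrt(t seconds).

#' Construct a dye-bath record
#'
#' @param C0 initial dye concentration, mg/ml.
#' @param V bath volume, ml.
#' @param W fibre mass, g.
#' @param radius_cm fibre radius, cm (mean diameter / 2 x 1e-4 when the
#'   diameter is in um).
#' @param calibration `list(slope, intercept)` of the Beer-Lambert
#'   absorbance-vs-concentration line at the dye's lambda-max (535 nm for
#'   CI Acid Violet 90); slope must be positive.
#' @return Object of class `dyebath_record`.
#' @export
dyebath_record <- function(C0, V, W, radius_cm,
                           calibration = list(slope = 1, intercept = 0)) {
  check_positive(C0, "C0"); check_positive(V, "V")
  check_positive(W, "W"); check_positive(radius_cm, "radius_cm")
  if (is.null(calibration$slope) || calibration$slope <= 0)
    stop_domain("calibration slope must be > 0")
  if (is.null(calibration$intercept)) calibration$intercept <- 0
  structure(list(C0 = C0, V = V, W = W, radius_cm = radius_cm,
                 calibration = calibration),
            class = "dyebath_record")
}

#' Convert absorbance to dye concentration
#'
#' Inverts the linear calibration `A = slope * C + intercept`; negative
#' concentrations (noise below the blank) are clipped to 0.
#'
#' @param A absorbance value(s).
#' @param calibration `list(slope, intercept)`, slope > 0.
#' @return Concentration, mg/ml.
#' @export
absorbance_to_concentration <- function(A, calibration) {
  if (is.null(calibration$slope) || calibration$slope <= 0)
    stop_domain("calibration slope must be > 0")
  intercept <- if (is.null(calibration$intercept)) 0 else calibration$intercept
  pmax(0, (A - intercept) / calibration$slope)
}

#' Dye adsorbed per gram of fibre
#'
#' `Mt = (C0 - Ce) * V / W`. Values of `Ce` exceeding `C0` (measurement
#' noise) are clipped to `C0` with a warning, giving zero uptake.
#'
#' @param C0 initial dye concentration, mg/ml.
#' @param Ce residual dye concentration at time t, mg/ml.
#' @param V bath volume, ml.
#' @param W fibre mass, g.
#' @return `Mt` in mg/g.
#' @examples
#' compute_Mt(0.4, 0.1, 50, 1)  # 15 mg/g
#' @export
compute_Mt <- function(C0, Ce, V, W) {
  check_positive(C0, "C0"); check_positive(V, "V")
  if (!is.numeric(W) || any(W <= 0)) stop_domain("`W` must be > 0")
  if (any(Ce < 0)) stop_domain("`Ce` must be >= 0")
  if (any(Ce > C0)) {
    warning("Ce > C0 clipped to C0 (zero uptake)", call. = FALSE)
    Ce <- pmin(Ce, C0)
  }
  (C0 - Ce) * V / W
}

#' Estimate the equilibrium uptake Me
#'
#' Default rule: the mean `Mt` of the final two time points, restricted to
#' `t >= 180` min when at least two such points exist. If the series is
#' still rising at the end (final step exceeds 5% of the estimate) the
#' result carries a `"no plateau"` flag.
#'
#' @param series an [uptake_series()].
#' @param value optional user-supplied `Me` (returned as-is, no flag).
#' @return Numeric `Me` (mg/g) with attribute `flag` (`NA` or
#'   `"no plateau"`).
#' @export
estimate_Me <- function(series, value = NULL) {
  stopifnot(inherits(series, "uptake_series"))
  if (!is.null(value)) {
    check_positive(value, "value")
    return(structure(value, flag = NA_character_))
  }
  n <- length(series$Mt)
  if (n < 2L) stop_domain("need >= 2 points to estimate Me")
  late <- which(series$time_min >= 180)
  idx <- if (length(late) >= 2L) tail(late, 2L) else c(n - 1L, n)
  Me <- mean(series$Mt[idx])
  flag <- NA_character_
  if (Me <= 0) stop_domain("estimated Me is not positive")
  if ((series$Mt[n] - series$Mt[n - 1L]) > 0.05 * Me) flag <- "no plateau"
  structure(Me, flag = flag)
}

#' Apparent diffusion coefficient from the early-phase Hill fit
#'
#' Restricts the series to points with `Mt/Me <= cutoff`, fits a
#' least-squares line through the origin of `Mt/Me` on `sqrt(t)` (seconds),
#' and converts the slope `k` to `D = k^2 * pi * r^2 / 16`. The fit is
#' forced through the origin because the model has zero uptake at t = 0.
#'
#' @param series an [uptake_series()].
#' @param Me equilibrium uptake (mg/g); default from [estimate_Me()].
#' @param radius_cm fibre radius, cm; default taken from the series.
#' @param cutoff early-phase validity cutoff on `Mt/Me` (default 0.5).
#' @return Object of class `diffusion_fit` with elements `Me`, `slope_k`
#'   (per sqrt-second), `D` (cm^2/s), `n_points_used`, `fit_window`,
#'   `r_squared` (centered, of the restricted fit), `flag`.
#' @export
fit_hill <- function(series, Me = NULL, radius_cm = NULL, cutoff = 0.5) {
  stopifnot(inherits(series, "uptake_series"))
  if (cutoff <= 0 || cutoff > 1) stop_domain("`cutoff` must be in (0, 1]")
  if (is.null(radius_cm)) radius_cm <- series$radius_cm
  if (is.null(radius_cm))
    stop_domain("`radius_cm` missing: not in series and not supplied")
  check_positive(radius_cm, "radius_cm")
  if (is.null(Me)) Me <- estimate_Me(series)
  frac <- series$Mt / as.numeric(Me)
  t_sec <- series$time_min * 60
  sel <- frac <= cutoff + 1e-12 & t_sec > 0
  if (sum(sel) < 3L)
    stop_domain("insufficient early-phase data: fewer than 3 points with Mt/Me <= cutoff")
  x <- sqrt(t_sec[sel]); y <- frac[sel]
  k <- sum(x * y) / sum(x * x)
  flag <- NA_character_
  if (k < 0) {
    flag <- "negative slope"
    k_eff <- 0
  } else k_eff <- k
  D <- k_eff^2 * pi * radius_cm^2 / 16
  ss_res <- sum((y - k_eff * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(Me = as.numeric(Me), slope_k = k_eff, D = D,
                 radius_cm = radius_cm, n_points_used = sum(sel),
                 fit_window = cutoff, r_squared = r2,
                 replicate_id = series$replicate_id,
                 flag = flag, me_flag = attr(Me, "flag")),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> '%s': D = %.3f x 1e-8 cm^2/s (slope %.4g /sqrt(s), %d pts, Mt/Me <= %g, R^2 = %.4f)%s\n",
    x$replicate_id, x$D * 1e8, x$slope_k, x$n_points_used, x$fit_window,
    x$r_squared, if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Aggregate replicate diffusion fits
#'
#' Mean and standard error of the mean (sd / sqrt(n)) of `D` across
#' replicate fits, matching the convention of reporting the average of
#' repeat dyeing runs with its standard error.
#'
#' @param fits list of `diffusion_fit` objects (>= 1).
#' @return `list(mean_D, stderr_D, n, flag)`; a single replicate yields
#'   `stderr_D = 0` flagged `"n=1"`.
#' @export
aggregate_replicates <- function(fits) {
  if (inherits(fits, "diffusion_fit")) fits <- list(fits)
  if (length(fits) < 1L) stop_domain("need at least one fit")
  D <- vapply(fits, function(f) f$D, numeric(1))
  n <- length(D)
  list(mean_D = mean(D),
       stderr_D = if (n > 1L) sd(D) / sqrt(n) else 0,
       n = n,
       flag = if (n == 1L) "n=1" else NA_character_)
}
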