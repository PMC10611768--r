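# Synthetic dye-bath uptake series from Fickian models.
#
# Two generating models for relative uptake f = Mt/Me of an infinite
# cylinder of radius r (cm), diffusion coefficient D (cm^2/s), time t (s):
#
#   hill_early:       f = min(1, 4 * sqrt(D t / (pi r^2)))
#   cylinder_series:  f = 1 - sum_n (4 / b_n^2) exp(-D b_n^2 t / r^2),
#                     b_n the positive roots of the Bessel function J0.
#
# The early-time (Hill) form is the leading term of the series solution and
# is the model under which the apparent diffusion coefficient is defined.

# First `n` positive roots of J0, via bracketed root refinement around the
# McMahon asymptotic locations. Memoised after first call.
.j0_roots_cache <- new.env(parent = emptyenv())

#' Positive roots of the Bessel function J0
#'
#' @param n number of roots.
#' @return Numeric vector of the first `n` roots (2.4048, 5.5201, ...).
#' @export
bessel_j0_zeros <- function(n) {
  key <- "roots"
  have <- if (exists(key, .j0_roots_cache)) get(key, .j0_roots_cache) else numeric(0)
  if (length(have) < n) {
    need <- (length(have) + 1L):n
    extra <- vapply(need, function(k) {
      approx_k <- (k - 0.25) * pi + 1 / (8 * (k - 0.25) * pi)
      uniroot(function(x) besselJ(x, 0), c(approx_k - 0.6, approx_k + 0.6),
              tol = 1e-13)$root
    }, numeric(1))
    have <- c(have, extra)
    assign(key, have, .j0_roots_cache)
  }
  have[seq_len(n)]
}

# Crank's short-time expansion for the cylinder, accurate for small
# dimensionless time T = D t / r^2 (error O(T^2)).
cylinder_short_time <- function(Tn) {
  (4 / sqrt(pi)) * sqrt(Tn) - Tn - (1 / (3 * sqrt(pi))) * Tn^1.5
}

#' Exact relative uptake of a Fickian cylinder
#'
#' Evaluates `Mt/Me` for radial diffusion into an infinite cylinder from a
#' well-stirred infinite bath. The Bessel series is used where it converges
#' quickly (dimensionless time `T = D*t/r^2 >= 0.01`, terms truncated below
#' 1e-10); the short-time expansion is used below that, where the two forms
#' agree to ~1e-6.
#'
#' @param t_sec time(s), seconds.
#' @param D diffusion coefficient, cm^2/s.
#' @param radius_cm cylinder radius, cm.
#' @return `Mt/Me` in `[0, 1]`.
#' @export
uptake_cylinder_series <- function(t_sec, D, radius_cm) {
  check_nonneg(D, "D"); check_positive(radius_cm, "radius_cm")
  Tn <- D * t_sec / radius_cm^2
  out <- numeric(length(Tn))
  big <- Tn >= 0.01
  if (any(big)) {
    b <- bessel_j0_zeros(80L)
    for (i in which(big)) {
      terms <- (4 / b^2) * exp(-b^2 * Tn[i])
      terms <- terms[terms >= 1e-10 | seq_along(terms) == 1L]
      out[i] <- 1 - sum(terms)
    }
  }
  small <- !big & Tn > 0
  out[small] <- cylinder_short_time(Tn[small])
  pmin(1, pmax(0, out))
}

#' Early-time (Hill) relative uptake
#'
#' @inheritParams uptake_cylinder_series
#' @return `min(1, 4*sqrt(D*t/(pi*r^2)))`.
#' @export
uptake_hill_early <- function(t_sec, D, radius_cm) {
  check_nonneg(D, "D"); check_positive(radius_cm, "radius_cm")
  pmin(1, 4 * sqrt(D * t_sec / (pi * radius_cm^2)))
}

#' Specification of a synthetic uptake experiment
#'
#' @param D_true apparent diffusion coefficient, cm^2/s (the studied dye/wool
#'   systems span roughly 0.09e-8 to 0.59e-8).
#' @param radius_cm fibre radius, cm (11e-4 to 36e-4 for the studied wools).
#' @param Me equilibrium uptake, mg dye per g fibre.
#' @param times_min sampling times in minutes, strictly increasing, >= 0.
#'   Default is the 5-240 min dye-bath schedule at 5 min steps.
#' @param noise_sd additive Gaussian noise on Mt, mg/g.
#' @param model `"hill_early"` or `"cylinder_series"`.
#' @param seed RNG seed.
#' @return Object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(D_true, radius_cm, Me = 18,
                          times_min = seq(5, 240, by = 5),
                          noise_sd = 0, model = c("hill_early", "cylinder_series"),
                          seed = 1) {
  model <- match.arg(model)
  check_nonneg(D_true, "D_true"); check_positive(radius_cm, "radius_cm")
  check_positive(Me, "Me"); check_nonneg(noise_sd, "noise_sd")
  if (length(times_min) == 0L) stop_domain("`times_min` must be non-empty")
  if (any(times_min < 0)) stop_domain("`times_min` must be non-negative")
  if (length(times_min) > 1L && any(diff(times_min) <= 0))
    stop_domain("`times_min` must be strictly increasing")
  structure(list(D_true = D_true, radius_cm = radius_cm, Me = Me,
                 times_min = times_min, noise_sd = noise_sd,
                 model = model, seed = seed),
            class = "kinetics_spec")
}

#' Generate a synthetic dye-uptake series
#'
#' Evaluates the chosen uptake model at `times_min`, adds seeded Gaussian
#' noise, and clips to `[0, Me]`. At `t = 0` uptake is exactly 0 before
#' noise.
#'
#' @param spec a [kinetics_spec()].
#' @param replicate_id label carried into fit reports.
#' @return An [uptake_series()] with `Mt` in mg/g.
#' @export
generate_uptake_series <- function(spec, replicate_id = "rep1") {
  stopifnot(inherits(spec, "kinetics_spec"))
  t_sec <- spec$times_min * 60
  frac <- switch(spec$model,
                 hill_early = uptake_hill_early(t_sec, spec$D_true, spec$radius_cm),
                 cylinder_series = uptake_cylinder_series(t_sec, spec$D_true, spec$radius_cm))
  Mt <- spec$Me * frac
  if (spec$noise_sd > 0)
    Mt <- with_seed(spec$seed, Mt + rnorm(length(Mt), 0, spec$noise_sd))
  Mt <- pmin(spec$Me, pmax(0, Mt))
  uptake_series(time_min = spec$times_min, Mt = Mt,
                radius_cm = spec$radius_cm, replicate_id = replicate_id,
                meta = list(D_true = spec$D_true, Me_true = spec$Me,
                            model = spec$model, seed = spec$seed))
}

#' Construct an uptake series
#'
#' A dye-bath uptake record: strictly increasing times (minutes) with dye
#' adsorbed per gram of fibre `Mt` (mg/g), plus the fibre radius used when
#' converting the early-phase slope into a diffusion coefficient.
#'
#' @param time_min times, minutes, strictly increasing, >= 0.
#' @param Mt dye adsorbed, mg/g.
#' @param radius_cm fibre radius, cm (optional until fitting).
#' @param replicate_id replicate label.
#' @param bath optional [dyebath_record()].
#' @param meta free-form provenance list.
#' @return Object of class `uptake_series`.
#' @export
uptake_series <- function(time_min, Mt, radius_cm = NULL,
                          replicate_id = "rep1", bath = NULL, meta = list()) {
  if (length(time_min) != length(Mt))
    stop_domain("`time_min` and `Mt` must have equal length")
  if (any(time_min < 0)) stop_domain("times must be non-negative")
  if (length(time_min) > 1L && any(diff(time_min) <= 0))
    stop_domain("times must be strictly increasing")
  structure(list(time_min = as.numeric(time_min), Mt = as.numeric(Mt),
                 radius_cm = radius_cm, replicate_id = as.character(replicate_id),
                 bath = bath, meta = meta),
            class = "uptake_series")
}

#' @export
print.uptake_series <- function(x, ...) {
  cat(sprintf("<uptake_series> '%s': %d points, t = %g..%g min, Mt = %.3g..%.3g mg/g\n",
              x$replicate_id, length(x$time_min), min(x$time_min),
              max(x$time_min), min(x$Mt), max(x$Mt)))
  invisible(x)
}
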