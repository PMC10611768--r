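# End-to-end orchestration: measure -> correlate -> kinetics -> validate.

#' Pipeline run configuration
#'
#' @param seed integer seed governing every random draw in the run.
#' @param window_um axial window length, um.
#' @param hill_cutoff early-phase Mt/Me cutoff for [fit_hill()].
#' @param spi_bands reference SPI bands.
#' @param output_dir where report files are written.
#' @param write_plots also emit a QC plot PDF (PDFs embed timestamps, so
#'   they are excluded from byte-identity guarantees).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, window_um = 100, hill_cutoff = 0.5,
                       spi_bands = woolscale::spi_bands(),
                       output_dir = tempfile("woolscale_run_"),
                       write_plots = FALSE) {
  check_positive(window_um, "window_um")
  if (hill_cutoff <= 0 || hill_cutoff > 1) stop_domain("cutoff must be in (0, 1]")
  structure(list(seed = as.integer(seed), window_um = window_um,
                 hill_cutoff = hill_cutoff, spi_bands = spi_bands,
                 output_dir = output_dir, write_plots = isTRUE(write_plots)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) morphometry of every input image; (2) the through-origin
#' quadratic perimeter-diameter fit when >= 3 fibres are available;
#' (3) kinetics fits per uptake replicate plus replicate aggregation, when
#' uptake data are supplied (skipped and noted otherwise); (4) validation
#' of a held-out fibre against the fitted model, when requested. Outputs
#' (per-fibre CSV, per-window CSV, model JSON, kinetics JSON, run log) are
#' deterministic given the same config and inputs.
#'
#' @param config a [run_config()].
#' @param images list of [fibre_image()] objects or image file paths.
#' @param uptake list of [uptake_series()], or a CSV path.
#' @param bath a [dyebath_record()] (needed when `uptake` is a CSV of
#'   absorbance/concentration).
#' @param validate optional `list(diameter_um, perimeter_per_100um, id)`
#'   measured on a fibre type held out of the fit.
#' @return Object of class `pipeline_report` (also serialized under
#'   `config$output_dir`).
#' @export
run_pipeline <- function(config, images = list(), uptake = NULL,
                         bath = NULL, validate = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("woolscale %s", as.character(packageVersion("woolscale"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("window_um: %g", config$window_um),
                 sprintf("hill_cutoff: %g", config$hill_cutoff))
  # --- stage 1: morphometry ------------------------------------------------
  measurements <- list()
  if (length(images) > 0L) {
    measurements <- lapply(images, function(im) {
      if (is.character(im)) im <- read_image(im)
      tryCatch(measure_fibre(im, window_um = config$window_um),
               error = function(e) stop("stage measure [", im$id, "]: ",
                                        conditionMessage(e), call. = FALSE))
    })
    tab <- measurements_to_table(measurements)
    names(tab) <- c("id", "diameter_um", "diameter_cv_pct",
                    "perimeter_per_100um_um", "scale_count", "spi", "pattern")
    write.csv(tab, file.path(config$output_dir, "fibres.csv"), row.names = FALSE)
    wins <- do.call(rbind, lapply(measurements, function(m)
      cbind(id = m$id, m$windows)))
    names(wins) <- c("id", "window_index", "start_um", "end_um",
                     "perimeter_um", "full_scales", "partial_scales", "scale_count")
    write.csv(wins, file.path(config$output_dir, "windows.csv"), row.names = FALSE)
    log_lines <- c(log_lines, sprintf("measured %d fibre image(s)", length(measurements)))
  }
  # --- stage 2: correlation ------------------------------------------------
  model <- NULL
  if (length(measurements) >= 3L) {
    tab <- measurements_to_table(measurements)
    model <- tryCatch(
      fit_perimeter_model(tab$diameter_um, tab$perimeter_per_100um),
      error = function(e) stop("stage correlate: ", conditionMessage(e), call. = FALSE))
    jsonlite::write_json(unclass(model),
                         file.path(config$output_dir, "perimeter_model.json"),
                         auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf("fitted perimeter model: a=%.4g b=%.4g R2=%.4f",
                                      model$a, model$b, model$r_squared))
  } else log_lines <- c(log_lines, "correlate stage skipped: fewer than 3 fibres")
  # --- stage 3: kinetics ---------------------------------------------------
  kin <- NULL
  if (!is.null(uptake)) {
    if (is.character(uptake)) uptake <- read_uptake_csv(uptake, bath = bath)
    if (inherits(uptake, "uptake_series")) uptake <- list(uptake)
    fits <- lapply(uptake, function(s)
      tryCatch(fit_hill(s, cutoff = config$hill_cutoff),
               error = function(e) stop("stage kinetics [", s$replicate_id,
                                        "]: ", conditionMessage(e), call. = FALSE)))
    agg <- aggregate_replicates(fits)
    kin <- list(fits = fits, aggregate = agg)
    jsonlite::write_json(
      list(replicates = lapply(fits, function(f)
        list(replicate_id = f$replicate_id, D_cm2_per_s = f$D,
             slope_per_sqrt_s = f$slope_k, n_points = f$n_points_used,
             r_squared = f$r_squared, flag = f$flag)),
        mean_D_cm2_per_s = agg$mean_D, stderr_D_cm2_per_s = agg$stderr_D,
        # display convention: value x 1e-8 cm^2/s to 3 decimals
        display = sprintf("%.3f +/- %.3f x 1e-8 cm2/s",
                          agg$mean_D * 1e8, agg$stderr_D * 1e8)),
      file.path(config$output_dir, "kinetics.json"),
      auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf("kinetics: mean D = %.3f x 1e-8 cm2/s (n=%d)",
                                      agg$mean_D * 1e8, agg$n))
  } else log_lines <- c(log_lines, "kinetics stage skipped: no uptake data")
  # --- stage 4: validation -------------------------------------------------
  val <- NULL
  if (!is.null(validate) && !is.null(model)) {
    val <- validate_new_breed(validate$diameter_um, validate$perimeter_per_100um,
                              model, bands = config$spi_bands,
                              id = validate$id %||% "held-out fibre")
    jsonlite::write_json(unclass(val), file.path(config$output_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf("validation: residual %+.1f um", val$residual))
  }
  if (config$write_plots) write_qc_plots(config, measurements, model, kin)
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  structure(list(config = config, measurements = measurements,
                 model = model, kinetics = kin, validation = val,
                 output_dir = config$output_dir, log = log_lines),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n ", paste(x$log, collapse = "\n  "), "\n")
  invisible(x)
}

# QC plots: perimeter vs diameter with fitted curve, SPI vs diameter,
# Mt/Me vs sqrt(t) per replicate.
write_qc_plots <- function(config, measurements, model, kin) {
  pdf(file.path(config$output_dir, "qc_plots.pdf"), width = 7, height = 5)
  on.exit(dev.off())
  if (length(measurements) > 0L) {
    tab <- measurements_to_table(measurements)
    plot(tab$diameter_um, tab$perimeter_per_100um, pch = 19,
         xlab = "diameter (um)", ylab = "scale perimeter per 100 um (um)",
         main = "Perimeter vs diameter")
    if (!is.null(model)) {
      xs <- seq(min(tab$diameter_um), max(tab$diameter_um), length.out = 100)
      lines(xs, model$a * xs + model$b * xs^2, col = 2)
    }
    plot(tab$diameter_um, tab$spi, pch = 19,
         xlab = "diameter (um)", ylab = "SPI", main = "SPI vs diameter")
  }
  if (!is.null(kin)) {
    for (f in kin$fits) {
      # refit line for display only
      plot(NA, xlim = c(0, 10), ylim = c(0, 1), xlab = "sqrt(t) (s^1/2)",
           ylab = "Mt/Me", main = paste("Hill fit", f$replicate_id))
      abline(0, f$slope_k, col = 2)
    }
  }
  invisible(NULL)
}
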