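# Readers and writers. Images: 8-bit grayscale PNG (via the png package)
# or plain-text ASCII PGM (P2); the physical scale travels in a JSON
# sidecar because measurements without physical units are meaningless.

#' Write an ASCII PGM (P2) image
#'
#' @param pixels numeric matrix of grey levels 0-255.
#' @param path output path.
#' @param maxval maximum grey value recorded in the header.
#' @export
write_pgm <- function(pixels, path, maxval = 255) {
  m <- round(pmin(pmax(pixels, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  write(t(m), file = con, ncolumns = ncol(m))
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return Numeric matrix of grey levels.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop_domain("not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop_domain("corrupt PGM: pixel count mismatch")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a fibre image with its physical-scale sidecar
#'
#' Accepts 8-bit grayscale PNG or ASCII PGM. Multi-channel PNGs are
#' converted to grey by luminance (0.2126 R + 0.7152 G + 0.0722 B). The
#' um-per-pixel scale must come from the JSON sidecar
#' (`<image>.json`, field `um_per_px`) or the `um_per_px` argument;
#' without it the reader stops — physical units are mandatory.
#'
#' @param path image path (`.png` or `.pgm`).
#' @param um_per_px physical scale override; if `NULL` the sidecar is read.
#' @param id fibre identifier; defaults to the file name.
#' @return A [fibre_image()].
#' @export
read_image <- function(path, um_per_px = NULL, id = NULL) {
  if (!file.exists(path)) stop_domain("image file not found: ", path)
  if (is.null(um_per_px)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop_domain("no physical scale: supply `um_per_px` or a JSON sidecar ", sc)
    meta <- jsonlite::read_json(sc)
    if (is.null(meta$um_per_px))
      stop_domain("no physical scale: sidecar lacks `um_per_px`")
    um_per_px <- as.numeric(meta$um_per_px)
    if (is.null(id) && !is.null(meta$id)) id <- meta$id
  }
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      ch <- dim(a)[3]
      if (ch >= 3L) a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
      else a <- a[, , 1]
    }
    round(a * 255)
  } else if (ext == "pgm") {
    read_pgm(path)
  } else stop_domain("unsupported image format: .", ext, " (use PNG or PGM)")
  fibre_image(px, um_per_px = um_per_px,
              id = if (is.null(id)) basename(path) else id)
}

#' Write a fibre image plus its JSON sidecar
#'
#' @param image a [fibre_image()].
#' @param path output path (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_fibre_image <- function(image, path) {
  stopifnot(inherits(image, "fibre_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image$pixels / 255, 0), 1), path)
  } else if (ext == "pgm") {
    write_pgm(image$pixels, path)
  } else stop_domain("unsupported image format: .", ext)
  jsonlite::write_json(list(um_per_px = image$um_per_px, id = image$id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dye-bath uptake series from CSV
#'
#' Expected columns: `replicate_id` (optional, single replicate assumed if
#' absent), `time_min`, and exactly one of `mt_mg_g`, `ce_mg_ml`,
#' `absorbance`. Absorbance and concentration columns require a `bath`
#' (with calibration for absorbance) to convert to `Mt` via
#' [absorbance_to_concentration()] and [compute_Mt()]. Rows are sorted by
#' time within replicate (with a warning if they arrived unsorted);
#' duplicate or negative times are errors.
#'
#' @param path CSV path.
#' @param bath a [dyebath_record()], required unless the file carries
#'   `mt_mg_g` directly.
#' @return List of [uptake_series()], one per replicate.
#' @export
read_uptake_csv <- function(path, bath = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_min", "time"), names(df))[1]
  if (is.na(tcol)) stop_domain("uptake CSV needs a `time_min` column")
  vcol <- intersect(c("mt_mg_g", "ce_mg_ml", "absorbance"), names(df))
  if (length(vcol) != 1L)
    stop_domain("uptake CSV needs exactly one of mt_mg_g / ce_mg_ml / absorbance")
  if (vcol != "mt_mg_g" && is.null(bath))
    stop_domain("`bath` required to convert ", vcol, " to Mt")
  if (vcol == "absorbance" && is.null(bath$calibration))
    stop_domain("bath config lacks the absorbance calibration")
  if (!"replicate_id" %in% names(df)) df$replicate_id <- "rep1"
  if (any(df[[tcol]] < 0)) stop_domain("negative times in uptake CSV")
  lapply(split(df, df$replicate_id), function(d) {
    if (anyDuplicated(d[[tcol]]))
      stop_domain("duplicate times within replicate ", d$replicate_id[1])
    if (is.unsorted(d[[tcol]])) {
      warning("unsorted times in replicate ", d$replicate_id[1],
              "; sorting", call. = FALSE)
      d <- d[order(d[[tcol]]), ]
    }
    Mt <- switch(vcol,
                 mt_mg_g = d$mt_mg_g,
                 ce_mg_ml = compute_Mt(bath$C0, pmin(d$ce_mg_ml, bath$C0),
                                       bath$V, bath$W),
                 absorbance = {
                   ce <- absorbance_to_concentration(d$absorbance, bath$calibration)
                   compute_Mt(bath$C0, pmin(ce, bath$C0), bath$V, bath$W)
                 })
    uptake_series(time_min = d[[tcol]], Mt = Mt,
                  radius_cm = bath$radius_cm,
                  replicate_id = d$replicate_id[1], bath = bath)
  })
}

#' Read a dye-bath configuration JSON
#'
#' Fields: `C0` (mg/ml), `V` (ml), `W` (g), `radius_um` or `radius_cm`,
#' optional `calibration` `{slope, intercept}`.
#'
#' @param path JSON path.
#' @return A [dyebath_record()].
#' @export
read_bath_json <- function(path) {
  j <- jsonlite::read_json(path)
  radius_cm <- if (!is.null(j$radius_cm)) as.numeric(j$radius_cm)
               else if (!is.null(j$radius_um)) as.numeric(j$radius_um) * 1e-4
               else stop_domain("bath config needs radius_um or radius_cm")
  cal <- if (is.null(j$calibration)) list(slope = 1, intercept = 0)
         else list(slope = as.numeric(j$calibration$slope),
                   intercept = as.numeric(j$calibration$intercept %||% 0))
  dyebath_record(C0 = as.numeric(j$C0), V = as.numeric(j$V),
                 W = as.numeric(j$W), radius_cm = radius_cm,
                 calibration = cal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
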