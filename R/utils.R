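# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All generators in the package draw through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round to the nearest multiple of 0.5 (visible-scale counting granularity).
round_half <- function(x) round(x * 2) / 2

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_domain(sprintf("`%s` must be a single non-negative finite number", name))
  invisible(x)
}

# Length of a polyline given as an n x 2 matrix of (x, y) vertices.
polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

# Split segment lengths into axial windows: for segments (x1,y1)-(x2,y2),
# return the summed length falling into each interval [breaks[i], breaks[i+1]).
# Clipping is exact: length scales linearly with the clipped x-fraction.
segment_lengths_by_window <- function(seg, breaks) {
  nw <- length(breaks) - 1L
  out <- numeric(nw)
  if (nrow(seg) == 0L) return(out)
  len <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
  xlo <- pmin(seg[, 1], seg[, 3])
  xhi <- pmax(seg[, 1], seg[, 3])
  span <- xhi - xlo
  for (w in seq_len(nw)) {
    a <- pmax(xlo, breaks[w])
    b <- pmin(xhi, breaks[w + 1L])
    ov <- pmax(0, b - a)
    frac <- ifelse(span > 0, ov / span,
                   # vertical segment: belongs wholly to the window holding x
                   as.numeric(xlo >= breaks[w] & xlo < breaks[w + 1L]))
    out[w] <- sum(len * frac)
  }
  out
}
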