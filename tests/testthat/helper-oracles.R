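# Independent oracles and fixture builders shared across tests.

# Brute-force chain-code length: O(n^2) over all pixel pairs, counting each
# 8-adjacent pair once (1 for orthogonal, sqrt(2) for diagonal). Written as
# an exhaustive pixel walk, independent of the shift-matrix implementation.
oracle_chain_length <- function(skel, um_per_px = 1) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  n_orth <- 0L; n_diag <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dr <- abs(idx[i, 1] - idx[j, 1])
        dc <- abs(idx[i, 2] - idx[j, 2])
        if (dr <= 1L && dc <= 1L) {
          if (dr + dc == 1L) n_orth <- n_orth + 1L else n_diag <- n_diag + 1L
        }
      }
    }
  }
  (n_orth + n_diag * sqrt(2)) * um_per_px
}

# Brute-force connected-component labelling by repeated flood fill.
oracle_label <- function(mask, connectivity = 4) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- matrix(0L, nrow(m), ncol(m))
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
        else cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  cur <- 0L
  repeat {
    todo <- which(m & lab == 0L, arr.ind = TRUE)
    if (nrow(todo) == 0L) break
    cur <- cur + 1L
    queue <- todo[1, , drop = FALSE]
    lab[queue] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# Normal-equations solve for the no-intercept quadratic fit.
oracle_quadratic_fit <- function(x, y) {
  X <- cbind(x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# A flat synthetic band image with no boundaries: constant-width rectangle.
make_band_image <- function(width_px = 20, length_px = 160, um_per_px = 0.5,
                            margin_px = 10) {
  H <- width_px + 2 * margin_px
  img <- matrix(30, H, length_px)
  img[(margin_px + 1):(margin_px + width_px), ] <- 128
  fibre_image(img, um_per_px = um_per_px, id = "band")
}

# Hand-built axis descriptor for a horizontal band in pixel space.
make_axis <- function(length_um, centre_um) {
  list(centroid_um = centre_um, direction = c(1, 0),
       along_range_um = c(-length_um / 2, length_um / 2))
}

expect_identical_matrix <- function(a, b) {
  expect_true(is.matrix(a) && is.matrix(b) && all(dim(a) == dim(b)) &&
                all(a == b))
}
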