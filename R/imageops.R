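# Raster primitives for fibre micrograph analysis.
#
# Images are plain numeric matrices indexed [row, col]; row 1 is the top of
# the frame. Physical coordinates: x_um = (col - 0.5) * um_per_px along the
# frame, y_um = (row - 0.5) * um_per_px down the frame.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Otsu's automatic threshold
#'
#' Picks the grey-level cut maximising between-class variance of the
#' two-class split of the histogram. Used to separate the fibre band
#' (bright) from the background (dark) in micrographs.
#'
#' @param img numeric matrix of grey levels (any range; binned to 256 levels).
#' @return A single threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  # 256-bin histogram over the observed range
  nb <- 256L
  bin <- pmin(nb, 1L + floor((v - rng[1]) / diff(rng) * nb))
  h <- tabulate(bin, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  rng[1] + k / nb * diff(rng)
}

#' Label connected components of a binary mask
#'
#' Two-pass run-based labelling with union-find. 4-connectivity is used for
#' scale regions (so a thin 8-connected boundary curve separates them);
#' 8-connectivity for curvilinear structures such as edge skeletons.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components
#'   labelled 1..n in no particular order.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m)
  lab <- matrix(0L, nr, ncol(m))
  # runs per row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (r in seq_len(nr)) {
    x <- m[r, ]
    if (!any(x)) next
    rl <- rle(x)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    run_row <- c(run_row, rep.int(r, sum(keep)))
    run_s <- c(run_s, starts[keep])
    run_e <- c(run_e, ends[keep])
  }
  n <- length(run_row)
  if (n == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  idx_by_row <- split(seq_len(n), run_row)
  rows_present <- as.integer(names(idx_by_row))
  for (ri in seq_along(rows_present)) {
    r <- rows_present[ri]
    prev <- idx_by_row[[as.character(r - 1L)]]
    if (is.null(prev)) next
    for (i in idx_by_row[[ri]]) {
      ov <- prev[run_s[prev] <= run_e[i] + slack & run_e[prev] >= run_s[i] - slack]
      for (j in ov) {
        a <- find(i); b <- find(j)
        if (a != b) parent[a] <- b
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, unique(root))
  for (k in seq_len(n)) lab[run_row[k], run_s[k]:run_e[k]] <- relab[k]
  lab
}

#' Morphologically thin a binary mask to a unit-width skeleton
#'
#' Zhang-Suen two-subiteration thinning. Preserves 8-connectivity and
#' endpoints, so boundary curves that reach the fibre margin keep reaching
#' it after thinning (important for scale-region separation).
#'
#' @param mask logical or 0/1 matrix.
#' @return Logical matrix, the 1-px-wide skeleton.
#' @export
thin_mask <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, 1, 0);  p6 <- shift_mat(m, -1, 0)
      p4 <- shift_mat(m, 0, -1); p8 <- shift_mat(m, 0, 1)
      p3 <- shift_mat(m, 1, -1); p5 <- shift_mat(m, -1, -1)
      p7 <- shift_mat(m, -1, 1); p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # A = number of 0->1 transitions in the ordered ring p2..p9,p2
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  staircase_cleanup(m == 1L)
}

# Remove redundant pixels left by Zhang-Suen on staircases: a pixel whose
# neighbours remain a single 8-connected component without it (e.g. the
# corner of a N,E,SE triangle) adds spurious chain-code triangles. Removal
# is sequential so the curve stays 8-connected throughout. Endpoints
# (single neighbour) are never touched.
staircase_cleanup <- function(m) {
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  # adjacency between the 8 ring positions as actual pixels
  ring_adj <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    i != j && abs(offs[i, 1] - offs[j, 1]) <= 1 && abs(offs[i, 2] - offs[j, 2]) <= 1))
  neighbours_connected <- function(present) {
    ids <- which(present)
    if (length(ids) <= 1L) return(TRUE)
    seen <- ids[1]; frontier <- ids[1]
    while (length(frontier) > 0L) {
      nxt <- setdiff(ids[colSums(ring_adj[frontier, ids, drop = FALSE]) > 0], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(ids)
  }
  repeat {
    changed <- FALSE
    px <- which(m & neighbour_count(m) >= 2, arr.ind = TRUE)
    for (k in seq_len(nrow(px))) {
      r <- px[k, 1]; c <- px[k, 2]
      if (!m[r, c]) next
      rr <- r + offs[, 1]; cc <- c + offs[, 2]
      inb <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      present <- inb
      present[inb] <- m[cbind(rr[inb], cc[inb])]
      nn <- sum(present)
      if (nn >= 2 && nn <= 4 && neighbours_connected(present)) {
        m[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# 8-neighbour count of each true pixel.
neighbour_count <- function(m) {
  mi <- matrix(as.integer(m), nrow(m), ncol(m))
  shift_mat(mi, 1, 0) + shift_mat(mi, -1, 0) + shift_mat(mi, 0, 1) +
    shift_mat(mi, 0, -1) + shift_mat(mi, 1, 1) + shift_mat(mi, 1, -1) +
    shift_mat(mi, -1, 1) + shift_mat(mi, -1, -1)
}

#' Prune short spurs from a skeleton
#'
#' Removes terminal branches shorter than `min_len` pixels that are attached
#' to a junction; genuine curve ends (no junction within `min_len`) are kept.
#'
#' @param skel logical matrix (1-px skeleton).
#' @param min_len branches strictly shorter than this are removed.
#' @return Logical matrix.
#' @export
prune_spurs <- function(skel, min_len = 3) {
  m <- matrix(as.logical(skel), nrow(skel), ncol(skel))
  nr <- nrow(m); nc <- ncol(m)
  nb_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbours_of <- function(r, c) {
    rr <- r + nb_offsets[, 1]; cc <- c + nb_offsets[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    keep <- m[cbind(rr, cc)]
    cbind(rr[keep], cc[keep])
  }
  repeat {
    ncnt <- neighbour_count(m)
    ends <- which(m & ncnt == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (k in seq_len(nrow(ends))) {
      path <- list(ends[k, , drop = TRUE])
      cur <- ends[k, ]
      prev <- NULL
      is_spur <- FALSE
      while (length(path) < min_len) {
        nbs <- neighbours_of(cur[1], cur[2])
        if (!is.null(prev))
          nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nbs) == 0L) break            # isolated short arc: keep
        if (nrow(nbs) > 1L) { is_spur <- TRUE; break }  # reached a junction
        nxt <- nbs[1, ]
        if (nrow(neighbours_of(nxt[1], nxt[2])) >= 3) { is_spur <- TRUE; break }
        prev <- cur; cur <- nxt
        path[[length(path) + 1L]] <- cur
      }
      if (is_spur) {
        for (p in path) m[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  # a pruned branch can leave a redundant 1-px bump on the parent curve
  staircase_cleanup(m)
}

# Unique adjacent skeleton-pixel pairs with chain-code weights.
# Returns a data.frame: r1,c1,r2,c2, w (1 or sqrt(2)).
skeleton_edge_list <- function(skel) {
  m <- matrix(as.logical(skel), nrow(skel), ncol(skel))
  pick <- function(dr, dc, w) {
    both <- m & shift_mat(m, -dr, -dc, FALSE)   # neighbour at (+dr,+dc) exists
    idx <- which(both, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(data.frame(r1 = integer(0), c1 = integer(0),
                        r2 = integer(0), c2 = integer(0), w = numeric(0)))
    data.frame(r1 = idx[, 1], c1 = idx[, 2],
               r2 = idx[, 1] + dr, c2 = idx[, 2] + dc, w = w)
  }
  # each pair counted once: east, south, south-east, south-west
  rbind(pick(0, 1, 1), pick(1, 0, 1), pick(1, 1, sqrt(2)), pick(1, -1, sqrt(2)))
}

#' Chain-code length of a skeleton
#'
#' Sums unit steps between 4-adjacent skeleton pixels and `sqrt(2)` steps
#' between diagonally adjacent ones, each adjacent pair counted once.
#' `method = "corrected"` applies Kulpa's weights (0.9481, 1.3408) which
#' remove the systematic over-estimate of the naive chain code for lines of
#' arbitrary orientation.
#'
#' @param skel logical matrix.
#' @param um_per_px physical scale; length is returned in the same units.
#' @param method `"chain"` (exact 1 / sqrt(2) weights) or `"corrected"`.
#' @return Total length (um if `um_per_px` given in um/px).
#' @export
skeleton_length <- function(skel, um_per_px = 1, method = c("chain", "corrected")) {
  method <- match.arg(method)
  e <- skeleton_edge_list(skel)
  if (nrow(e) == 0L) return(0)
  n_orth <- sum(e$w == 1)
  n_diag <- nrow(e) - n_orth
  len <- if (method == "corrected") 0.9481 * n_orth + 1.3408 * n_diag
         else n_orth + n_diag * sqrt(2)
  len * um_per_px
}

replace_na <- function(x, repl) {
  idx <- is.na(x)
  x[idx] <- repl[idx]
  x
}

# 3x3 binomial smoothing (separable [1 2 1]/4), replicating edge pixels.
smooth3 <- function(img) {
  tmp <- (replace_na(shift_mat(img, 0, -1, NA), img) + 2 * img +
            replace_na(shift_mat(img, 0, 1, NA), img)) / 4
  (replace_na(shift_mat(tmp, -1, 0, NA), tmp) + 2 * tmp +
     replace_na(shift_mat(tmp, 1, 0, NA), tmp)) / 4
}

# Binary dilation with a (2k+1)x(2k+1) square, k >= 0.
dilate_square <- function(mask, k) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (k <= 0) return(m)
  out <- m
  for (dr in -k:k) for (dc in -k:k)
    if (dr != 0 || dc != 0) out <- out | shift_mat(m, dr, dc, FALSE)
  out
}
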