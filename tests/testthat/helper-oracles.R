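# Independent brute-force references used to validate the fast
# implementations. These deliberately share no code with the package.

# focal mean by direct double loop over all cell pairs
bf_focal_mean <- function(v, radius_cells) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (is.na(v[i, j])) next
    s <- 0; n <- 0
    for (r in 1:nr) for (c in 1:nc) {
      if ((r - i)^2 + (c - j)^2 <= radius_cells^2 + 1e-9 && !is.na(v[r, c])) {
        s <- s + v[r, c]; n <- n + 1
      }
    }
    out[i, j] <- s / n
  }
  out
}

# Bellman-Ford accumulated cost over the 8-neighbor cost graph
# (edge weight = mean resistance x center distance), column-major cells
bf_cost_distance <- function(v, cs, src) {
  nr <- nrow(v); nc <- ncol(v); n <- nr * nc
  d <- rep(Inf, n); d[src] <- 0
  repeat {
    changed <- FALSE
    for (cell in 1:n) {
      if (!is.finite(d[cell])) next
      r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
      if (is.na(v[r, c])) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc2 <- c + dc
        if (rr < 1 || rr > nr || cc2 < 1 || cc2 > nc) next
        if (is.na(v[rr, cc2])) next
        nb <- (cc2 - 1) * nr + rr
        w <- (v[r, c] + v[rr, cc2]) / 2 * cs * sqrt(dr^2 + dc^2)
        if (d[cell] + w < d[nb] - 1e-12) {
          d[nb] <- d[cell] + w; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# greedy thinning reference: repeatedly drop the point with most neighbors
# within radius, ties broken by lowest index
ref_thin <- function(pts, radius) {
  keep <- rep(TRUE, nrow(pts))
  d <- as.matrix(dist(pts[, c("x", "y")]))
  repeat {
    nb <- sapply(seq_len(nrow(pts)), function(i) {
      if (!keep[i]) return(-1L)
      sum(keep & d[i, ] < radius) - 1L
    })
    if (max(nb) <= 0) break
    keep[which.max(nb)] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

# AUC by exhaustive pair counting (ties count one half)
bf_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# empirical semivariogram range: first lag (along rows and columns) where
# the semivariance reaches 95% of the field variance
semivariogram_range <- function(v, max_lag = 40) {
  sill <- stats::var(as.vector(v))
  g <- vapply(seq_len(max_lag), function(h) {
    a <- c(v[seq_len(nrow(v) - h), ], v[, seq_len(ncol(v) - h)])
    b <- c(v[(h + 1):nrow(v), ], v[, (h + 1):ncol(v)])
    0.5 * mean((a - b)^2)
  }, 0)
  idx <- which(g >= 0.95 * sill)
  if (length(idx) == 0) max_lag else idx[1]
}

# shared small fixtures ------------------------------------------------

# 7x7 two-class map: class 4 in columns 1-3 (21 cells), class 5 in
# columns 4-7 (28 cells)
two_block_landcover <- function() {
  raster_grid(matrix(c(rep(4, 7 * 3), rep(5, 7 * 4)), 7, 7),
              cell_size = 250)
}

make_uniform_resistance <- function(n, cell_size = 1) {
  raster_grid(matrix(1, n, n), cell_size = cell_size)
}

cell_center <- function(g, row, col) {
  list(x = g$xmin + (col - 0.5) * g$cell_size,
       y = g$ymin + (nrow(g$values) - row + 0.5) * g$cell_size)
}
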