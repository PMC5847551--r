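# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Winding-number point-in-polygon (package uses even-odd ray casting).
# Agrees with even-odd for simple (non-self-intersecting) polygons.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  wn <- 0L
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1L
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# Exhaustive per-pixel-center rasterization oracle for a single-ring polygon.
oracle_rasterize <- function(ring, grid) {
  hits <- NULL
  for (row in 0:(grid$rows - 1L)) {
    for (col in 0:(grid$cols - 1L)) {
      cx <- grid$origin_x + (col + 0.5) * grid$pixel_width
      cy <- grid$origin_y - (row + 0.5) * grid$pixel_height
      if (oracle_point_in_ring(cx, cy, ring)) hits <- rbind(hits, c(row, col))
    }
  }
  hits
}

# Simple star-shaped random polygon (closed ring) in map coordinates.
random_polygon <- function(grid, min_r = 1.5, max_r = 18) {
  k <- sample(5:12, 1)
  cx <- runif(1, 2, grid$cols - 2) * grid$pixel_width + grid$origin_x
  cy <- grid$origin_y - runif(1, 2, grid$rows - 2) * grid$pixel_height
  theta <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, min_r, max_r)
  ring <- cbind(cx + r * cos(theta), cy + r * sin(theta))
  rbind(ring, ring[1, ])
}

# Vectorized winding-number oracle (same rule as oracle_point_in_ring but
# vectorized over query points, for the exhaustive 64 x 64 sweeps).
oracle_winding_vec <- function(px, py, ring) {
  wn <- integer(length(px))
  for (i in seq_len(nrow(ring) - 1L)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    wn <- wn + ((y1 <= py) & (y2 > py) & (is_left > 0)) -
      ((y1 > py) & (y2 <= py) & (is_left < 0))
  }
  wn != 0L
}

# Brute-force Mann-Kendall S and tie-corrected var_S by pair/group loops.
oracle_mk <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  var_S <- n * (n - 1) * (2 * n + 5)
  for (v in unique(x)) {
    t <- sum(x == v)
    if (t > 1) var_S <- var_S - t * (t - 1) * (2 * t + 5)
  }
  list(S = S, var_S = var_S / 18)
}

# Sort-and-accumulate evenness oracle written as an explicit loop.
oracle_evenness <- function(vals, q = 0.95) {
  tot <- sum(vals)
  if (tot <= 0) return(NA_real_)
  sorted <- sort(vals, decreasing = TRUE)
  acc <- 0
  for (k in seq_along(sorted)) {
    acc <- acc + sorted[k]
    if (acc >= q * tot) return(k / length(sorted))
  }
  1
}

# Shoelace polygon area and perimeter for the area-consistency check.
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
ring_perimeter <- function(ring) {
  sum(sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2))
}
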