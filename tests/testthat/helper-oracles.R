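# Independent brute-force reference implementations used to validate the
# package's vectorised spatial operations. Deliberately written as plain
# double loops, sharing no code with the package internals.

bf_focal <- function(values, window, stat) {
  nr <- nrow(values); nc <- ncol(values)
  k <- (window - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - k):min(nr, r + k)
    cs <- max(1, c - k):min(nc, c + k)
    w <- values[rs, cs]
    w <- w[!is.na(w)]
    if (!length(w)) next
    out[r, c] <- switch(stat,
                        range = max(w) - min(w),
                        mean = mean(w),
                        min = min(w),
                        max = max(w))
  }
  out
}

bf_distance <- function(mask_values, cell_size) {
  nr <- nrow(mask_values); nc <- ncol(mask_values)
  src <- which(!is.na(mask_values) & mask_values == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- sqrt((src[, 1] - r)^2 + (src[, 2] - c)^2)
    out[r, c] <- min(d) * cell_size
  }
  out
}

# dense queen (8-neighbour) weights with self-inclusion over an nr x nc
# grid, cells ordered column-major
bf_queen_weights <- function(nr, nc, include_self = TRUE) {
  n <- nr * nc
  W <- matrix(0, n, n)
  pos <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (dr == 0 && dc == 0 && !include_self) next
      W[pos(r, c), pos(r2, c2)] <- 1
    }
  }
  W
}

bf_gistar <- function(x, W) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    swx <- sum(W[i, ] * x)
    sw <- sum(W[i, ])
    sw2 <- sum(W[i, ]^2)
    z[i] <- (swx - xbar * sw) / (S * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  z
}

# quartic kernel density (points per km^2) by direct double loop
bf_kde <- function(points, h, geom) {
  nr <- nrow(geom$values); nc <- ncol(geom$values)
  cs <- geom$cell_size
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    x <- geom$origin[1] + (c - 0.5) * cs
    y <- geom$origin[2] - (r - 0.5) * cs
    if (nrow(points)) {
      d2 <- (points$x - x)^2 + (points$y - y)^2
      inside <- d2 < h^2
      out[r, c] <- sum(3 / (pi * h^2) * (1 - d2[inside] / h^2)^2)
    }
  }
  out * 1e6
}

# small fully-specified scene for indicator recipe tests: 6 x 6 grid,
# two zones (left/right halves), hand-chosen land use
tiny_scene <- function(cell_size = 30) {
  lu <- matrix(3L, 6, 6)           # forest background
  lu[2, 2] <- 1L; lu[3, 2] <- 1L   # paddy in zone 1
  lu[2, 3] <- 2L; lu[5, 2] <- 2L   # dry land in zone 1
  lu[2, 5] <- 2L; lu[3, 5] <- 2L   # dry land in zone 2
  lu[5, 5] <- 4L                   # water in zone 2
  zid <- matrix(rep(c(1L, 2L), each = 3), 6, 6, byrow = TRUE)
  tab <- data.frame(zone = 1:2, name = c("west", "east"),
                    fert_total = c(100, 50), pest_total = c(1, 2),
                    lv_load = c(0.2, 0.4), lv_facility = c(0.1, 0.3),
                    lv_scale = c(0.3, 0.5), cod = c(0.8, 1.2),
                    nh3n = c(0.6, 1.0), tp = c(0.9, 1.4),
                    runoff = c(61.95, 123.9),
                    river_density = c(0.404, 0.202),
                    lake_density = c(0.025, 0.05))
  dem <- grid_layer(matrix(seq(100, 200, length.out = 36), 6, 6),
                    cell_size)
  list(land_use = categorical_grid(lu, data.frame(
         code = 1:6, label = c("paddy", "dry_land", "forest", "water",
                               "artificial", "other")),
         cell_size = cell_size),
       dem = dem, slope = grid_layer(matrix(7.5, 6, 6), cell_size),
       erosivity = grid_layer(matrix(150, 6, 6), cell_size),
       zones = zone_map(zid, tab, cell_size = cell_size))
}
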