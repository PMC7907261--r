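test_that("grid constructors validate geometry and class tables", {
  g <- grid_layer(matrix(1:12, 3, 4), cell_size = 30, origin = c(100, 500))
  expect_s3_class(g, "agrisk_grid")
  expect_identical(dim(g), c(3L, 4L))
  expect_error(grid_layer(matrix(1, 2, 2), cell_size = -5), "positive")
  expect_error(categorical_grid(matrix(c(1L, 9L), 1, 2),
                                c(paddy = 1L, forest = 3L)),
               "absent from")
  tb <- data.frame(zone = 1:2, name = c("a", "b"))
  expect_error(zone_map(matrix(c(1L, 3L), 1, 2), tb), "bijective")
  expect_error(zone_map(matrix(1L, 2, 2),
                        data.frame(zone = c(1, 1), name = c("a", "a"))),
               "duplicated")
})

test_that("cell centres follow the top-left, row-major convention", {
  g <- grid_layer(matrix(0, 2, 3), cell_size = 10, origin = c(100, 200))
  cc <- cell_centers(g)
  expect_equal(cc$x[1, 1], 105)  # origin_x + 0.5 * cell
  expect_equal(cc$y[1, 1], 195)  # origin_y - 0.5 * cell
  expect_equal(cc$x[2, 3], 125)
  expect_equal(cc$y[2, 3], 185)
})

test_that("focal statistic handles constants, maxima and parameter errors", {
  g <- grid_layer(matrix(5, 4, 4))
  expect_true(all(focal_statistic(g, 3, "range")$values == 0))
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_true(all(focal_statistic(grid_layer(m), 3, "max")$values == 9))
  expect_error(focal_statistic(g, 4, "mean"), "odd")
  expect_error(focal_statistic(g, -3, "mean"), "odd")
})

test_that("focal statistic ignores nodata and matches the brute force", {
  set.seed(42)
  for (stat in c("range", "mean", "min", "max")) {
    m <- matrix(rnorm(100), 10, 10)
    m[sample(100, 12)] <- NA
    got <- focal_statistic(grid_layer(m), 7, stat)$values
    expect_equal(got, bf_focal(m, 7, stat), tolerance = 1e-12)
  }
  # a fully-nodata window yields nodata
  m <- matrix(NA_real_, 5, 5); m[5, 5] <- 1
  got <- focal_statistic(grid_layer(m), 3, "mean")$values
  expect_true(is.na(got[1, 1]))
  expect_equal(got[4, 4], 1)
})

test_that("euclidean distance matches neighbours and the brute force", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  d <- euclidean_distance(grid_layer(m, cell_size = 30))$values
  expect_equal(d[3, 3], 0)
  expect_equal(d[2, 3], 30)
  expect_equal(d[2, 2], 30 * sqrt(2))
  expect_error(euclidean_distance(grid_layer(matrix(0, 3, 3))),
               "no source")
  set.seed(7)
  m <- matrix(rbinom(400, 1, 0.05), 20, 20)
  m[1, 1] <- 1
  g <- grid_layer(m, cell_size = 30)
  expect_lt(max(abs(euclidean_distance(g)$values -
                      bf_distance(m, 30))), 1e-6 * 30)
})

test_that("zonal spread yields per-hectare intensities and conserves mass", {
  zid <- matrix(1L, 4, 4)
  zones <- zone_map(zid, data.frame(zone = 1, name = "z"), cell_size = 30)
  mask <- grid_layer(matrix(c(1, 1, 1, 1, rep(0, 12)), 4, 4),
                     cell_size = 30)
  out <- zonal_spread(zones, c("1" = 100), mask)
  # 100 kg over 4 cells of 0.09 ha
  expect_equal(out$values[mask$values == 1],
               rep(100 / (4 * 0.09), 4))
  expect_equal(out$values[mask$values == 0], rep(0, 12))
  expect_equal(sum(out$values) * 0.09, 100, tolerance = 1e-9)
  expect_true(all(zonal_spread(zones, c("1" = 0), mask)$values == 0))
})

test_that("zonal spread matches per-zone hand computation and warns on
           zones without mask cells", {
  set.seed(1)
  zid <- matrix(sample(1:3, 36, TRUE), 6, 6)
  zid[zid == 3] <- 1  # keep zone 3 out of the grid? no - rebuild below
  zid[1, 1] <- 3L
  tab <- data.frame(zone = 1:3, name = c("a", "b", "c"))
  zones <- zone_map(zid, tab, cell_size = 30)
  mask_m <- matrix(rbinom(36, 1, 0.5), 6, 6)
  mask_m[1, 1] <- 0  # zone 3 has its only cell masked out
  mask <- grid_layer(mask_m, cell_size = 30)
  totals <- c("1" = 90, "2" = 45, "3" = 10)
  expect_warning(out <- zonal_spread(zones, totals, mask), "3")
  for (z in 1:2) {
    cells <- zid == z & mask_m == 1
    expect_equal(unique(out$values[cells]),
                 totals[[as.character(z)]] / (sum(cells) * 0.09))
    expect_equal(sum(out$values[cells]) * 0.09, totals[[as.character(z)]],
                 tolerance = 1e-9)
  }
})

test_that("zonal mean and area proportions match direct computation", {
  zid <- matrix(rep(1:2, each = 8), 4, 4)
  zones <- zone_map(zid, data.frame(zone = 1:2, name = c("a", "b")))
  g <- grid_layer(matrix(1:16, 4, 4))
  zm <- zonal_mean(zones, g)
  expect_equal(zm$mean, c(mean(1:8), mean(9:16)))
  const <- grid_layer(matrix(3.5, 4, 4))
  expect_equal(zonal_mean(zones, const)$mean, c(3.5, 3.5))
  cg <- categorical_grid(matrix(rep(c(1L, 2L), 8), 4, 4),
                         c(a = 1L, b = 2L))
  ap <- area_proportions(cg)
  expect_equal(ap$percent, c(50, 50))
  expect_equal(sum(ap$percent), 100, tolerance = 1e-6)
  one <- categorical_grid(matrix(2L, 2, 2), c(b = 2L))
  expect_equal(area_proportions(one)$percent, 100)
})

test_that("mismatched geometries are rejected rather than resampled", {
  a <- grid_layer(matrix(0, 3, 3))
  b <- grid_layer(matrix(0, 3, 4))
  c_ <- grid_layer(matrix(0, 3, 3), cell_size = 10)
  expect_false(same_geometry(a, b))
  expect_false(same_geometry(a, c_))
  zones <- zone_map(matrix(1L, 3, 3), data.frame(zone = 1, name = "z"))
  expect_error(zonal_mean(zones, b), "geometry")
})
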