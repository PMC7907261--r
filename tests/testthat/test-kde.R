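test_that("at-risk cell selection returns cell centres", {
  g <- grid_layer(matrix(1, 4, 4), cell_size = 30)
  expect_equal(nrow(select_at_risk_cells(g, 3)), 0)
  g$values[2, 3] <- 3
  pts <- select_at_risk_cells(g, 3)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$x, (3 - 0.5) * 30)
  expect_equal(pts$y, -(2 - 0.5) * 30)
  g$values[4, 1] <- 5
  expect_equal(nrow(select_at_risk_cells(g, 3)), 2)
  expect_equal(nrow(select_at_risk_cells(g, 4)), 1)
})

test_that("the quartic kernel density matches its closed form and the
           brute force", {
  geom <- grid_layer(matrix(0, 20, 20), cell_size = 30)
  empty <- kernel_density_surface(data.frame(x = numeric(),
                                             y = numeric()), 300, geom)
  expect_true(all(empty$values == 0))
  # single point at a cell centre: density there is 3/(pi h^2), in km^-2
  h <- 300
  pt <- data.frame(x = 10.5 * 30, y = -10.5 * 30)
  d <- kernel_density_surface(pt, h, geom)
  expect_equal(d$values[11, 11], 3 / (pi * h^2) * 1e6)
  expect_error(kernel_density_surface(pt, -5, geom), "positive")
  set.seed(31)
  pts <- data.frame(x = runif(50, 0, 600), y = runif(50, -600, 0))
  got <- kernel_density_surface(pts, 150, geom)$values
  expect_lt(max(abs(got - bf_kde(pts, 150, geom))), 1e-9)
})

test_that("the kernel integrates to one point each for interior points", {
  geom <- grid_layer(matrix(0, 60, 60), cell_size = 30)
  h <- 150
  set.seed(12)
  # points at least 2h from the boundary
  pts <- data.frame(x = runif(25, 2 * h, 1800 - 2 * h),
                    y = -runif(25, 2 * h, 1800 - 2 * h))
  d <- kernel_density_surface(pts, h, geom)
  mass <- sum(d$values * 1e-6 * 30^2)
  expect_lt(abs(mass - nrow(pts)) / nrow(pts), 0.01)
})

test_that("equal-interval zoning builds 10 classes with the top class as
           gathering mask", {
  m <- matrix(0, 10, 10)
  m[1, 1] <- 950; m[1, 2] <- 1000; m[5, 5] <- 50; m[9, 9] <- 101
  dens <- grid_layer(m)
  z <- equal_interval_grades(dens, 10)
  expect_equal(z$grade10$values[1, 1], 10)   # 950 in (900, 1000]
  expect_equal(z$grade10$values[1, 2], 10)
  expect_equal(z$grade10$values[5, 5], 1)    # 50 in [0, 100]
  expect_equal(z$grade10$values[9, 9], 2)    # 101 in (100, 200]
  expect_equal(z$grade10$values[2, 2], 1)    # zero density is class 1
  expect_equal(sum(z$gathering_mask$values), 2)
  expect_error(equal_interval_grades(grid_layer(matrix(0, 3, 3))),
               "all zero")
  # random surface against direct binning
  set.seed(6)
  m <- matrix(runif(100, 0, 123), 10, 10)
  z2 <- equal_interval_grades(grid_layer(m), 10)
  w <- max(m) / 10
  want <- pmin(ceiling(m / w), 10)
  want[m == 0] <- 1
  expect_equal(z2$grade10$values, want)
})

test_that("gathering zones are connected components with centroids", {
  m <- matrix(0, 10, 10)
  m[2:3, 2:3] <- 1          # 4-cell block
  m[8, 8] <- 1              # isolated cell
  m[7, 7] <- 1              # diagonal neighbour joins by 8-connectivity
  zones <- gathering_zones(grid_layer(m, cell_size = 30))
  expect_equal(nrow(zones), 2)
  expect_equal(zones$cells, c(4, 2))
  expect_equal(zones$area_ha[1], 4 * 0.09)
  expect_equal(zones$x[1], mean(c(1.5, 2.5) * 30))
  expect_equal(zones$y[1], mean(-c(1.5, 2.5) * 30))
  none <- gathering_zones(grid_layer(matrix(0, 4, 4)))
  expect_equal(nrow(none), 0)
})

test_that("risk_kde recovers a planted cluster as the top density class", {
  sc <- generate_scene(scene_config(
    nrows = 100, ncols = 100, n_zones = 6, seed = 2,
    clusters = list(list(center = c(30, 70), radius = 450,
                         target_grade = 4))))
  fit <- ito3de(sc)
  k <- risk_kde(fit, min_grade = 4)
  expect_gt(nrow(k$points), 0)
  truth <- sc$truth$clusters[[1]]$center_xy
  top <- k$zones[1, ]
  expect_lt(sqrt((top$x - truth["x"])^2 + (top$y - truth["y"])^2),
            k$bandwidth)
})
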