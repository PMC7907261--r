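test_that("scene generation is deterministic under the seed", {
  cfg <- scene_config(nrows = 40, ncols = 40, n_zones = 4, seed = 5)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$land_use$values, b$land_use$values)
  expect_identical(a$zones$table, b$zones$table)
  c_ <- generate_scene(scene_config(nrows = 40, ncols = 40, n_zones = 4,
                                    seed = 6))
  expect_false(identical(a$dem$values, c_$dem$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- rnorm(1)
  set.seed(100)
  invisible(generate_scene(scene_config(nrows = 20, ncols = 20,
                                        n_zones = 2, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("land-use shares match the configured proportions", {
  sc <- generate_scene(scene_config(nrows = 60, ncols = 60, n_zones = 5,
                                    seed = 23))
  ap <- area_proportions(sc$land_use)
  expect_lt(abs(ap$percent[ap$label == "water"] - 2), 0.5)
  expect_lt(abs(ap$percent[ap$label == "forest"] - 45), 0.5)
  expect_equal(sum(ap$percent), 100, tolerance = 1e-6)
})

test_that("scene layers share geometry and slope derives from the DEM", {
  sc <- generate_scene(scene_config(nrows = 30, ncols = 30, n_zones = 3,
                                    seed = 9))
  expect_true(same_geometry(sc$dem, sc$slope))
  expect_true(same_geometry(sc$dem, sc$land_use))
  expect_true(same_geometry(sc$dem, sc$zones$grid))
  expect_true(all(sc$slope$values >= 0))
  flat <- grid_layer(matrix(100, 10, 10), cell_size = 30)
  expect_true(all(agrisk:::slope_from_dem(flat)$values == 0))
})

test_that("a planted cluster pushes its cells into the target grade", {
  sc <- generate_scene(scene_config(
    nrows = 80, ncols = 80, n_zones = 6, seed = 2,
    clusters = list(list(center = c(40, 40), radius = 450,
                         target_grade = 3))))
  fit <- ito3de(sc)
  rows <- matrix(seq_len(80), 80, 80)
  cols <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  inside <- (rows - 40)^2 + (cols - 40)^2 <= 15^2
  grades <- fit$grade$values[inside]
  expect_gte(mean(grades == 3), 0.9)
})

test_that("an infeasible cluster target raises an error", {
  # surcharges can only raise risk: a no-risk target inside an
  # intensive-agriculture patch is unreachable
  expect_error(generate_scene(scene_config(
    nrows = 40, ncols = 40, n_zones = 4, seed = 2,
    clusters = list(list(center = c(20, 20), radius = 300,
                         target_grade = 1)))),
    "infeasible")
})

test_that("cluster config is validated", {
  expect_error(scene_config(clusters = list(list(radius = -1,
                                                 target_grade = 3))),
               "radius")
  expect_error(scene_config(land_proportions = c(water = 1)),
               "land_proportions")
})

test_that("a zero-drift epoch series repeats the base scene exactly", {
  sc <- generate_scene(scene_config(nrows = 40, ncols = 40, n_zones = 4,
                                    seed = 13))
  eps <- generate_epoch_series(sc, 3, drift_spec(fert_factor = c(1, 1, 1),
                                                 pest_factor = c(1, 1, 1),
                                                 paddy_loss = 0))
  expect_identical(eps[[1]]$land_use$values, eps[[3]]$land_use$values)
  expect_identical(eps[[1]]$zones$table, eps[[3]]$zones$table)
  fits <- lapply(eps, ito3de)
  tr <- risk_transition(fits[[1]], fits[[2]], fits[[3]])
  expect_equal(sum(tr$proportions$percent[1:5]), 100, tolerance = 1e-9)
})

test_that("monotone intensification in one zone concentrates increases
           there", {
  sc <- generate_scene(scene_config(nrows = 60, ncols = 60, n_zones = 6,
                                    seed = 25))
  # strong monotone intensification so farmland crosses the wide
  # medium band (1.0-3.0] into high risk
  drift <- drift_spec(fert_factor = c(1, 2.5, 6),
                      pest_factor = c(1, 2.5, 6),
                      paddy_loss = 0, zones = 2)
  eps <- generate_epoch_series(sc, 3, drift)
  fits <- lapply(eps, ito3de)
  tr <- risk_transition(fits[[1]], fits[[2]], fits[[3]])
  inc <- tr$category$values == 6
  zid <- sc$zones$grid$values
  # all increases lie in the drifted zone, which gains a real share
  expect_true(all(zid[inc] == 2))
  expect_gt(mean(inc[zid == 2]), 0.05)
  # the drifted zone's mean-score trajectory itself reads as increase
  zm <- vapply(fits, function(f)
    zonal_mean(sc$zones, f$score)$mean[2], numeric(1))
  expect_true(all(diff(zm) > 0))
})

test_that("default drift reproduces the decade dynamics in aggregate", {
  sc <- generate_scene(scene_config(nrows = 50, ncols = 50, n_zones = 5,
                                    seed = 26))
  eps <- generate_epoch_series(sc, 3)
  # paddy halves by the final epoch
  n_paddy <- vapply(eps, function(e) sum(e$land_use$values == 1L),
                    numeric(1))
  expect_equal(n_paddy[3] / n_paddy[1], 0.5, tolerance = 0.02)
  expect_true(n_paddy[1] > n_paddy[2] && n_paddy[2] > n_paddy[3])
  # fertilizer totals rise then fall
  f <- vapply(eps, function(e) sum(e$zones$table$fert_total), numeric(1))
  expect_true(f[2] > f[1] && f[3] < f[1])
})
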