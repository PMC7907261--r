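test_that("reference-value normalization follows the index directions", {
  g <- grid_layer(matrix(c(0, 125, 250, 500), 2, 2))
  pos <- normalize_positive(g, 250)
  expect_equal(pos$values, matrix(c(0, 0.5, 1, 2), 2, 2))
  # a fertilizer level of 411 kg/ha against the 250 kg/ha reference is
  # medium risk
  expect_equal(normalize_positive(411, 250), 1.644)
  neg <- normalize_negative(grid_layer(matrix(c(3000, 1500, 750, 0), 2, 2)),
                            1500)
  expect_equal(neg$values, matrix(c(0.5, 1, 2, 10), 2, 2))
  expect_error(normalize_positive(g, 0), "positive")
  expect_error(normalize_negative(g, -2), "positive")
})

test_that("normalization identities hold over random draws", {
  set.seed(123)
  for (i in 1:100) {
    E <- runif(1, 0.1, 100)
    C <- runif(1, E / 9, 9 * E)  # off-clamp region
    expect_equal(normalize_positive(C, E) * normalize_negative(C, E), 1,
                 tolerance = 1e-12)
    expect_equal(normalize_positive(E, E), 1)
    expect_equal(normalize_negative(E, E), 1)
  }
})

test_that("values are capped at 10 and the negative floor realises it", {
  expect_equal(normalize_positive(1e9, 1), 10)
  expect_equal(normalize_negative(0, 1500), 10)
  expect_equal(normalize_negative(1500 / 10, 1500), 10)
})

test_that("the Nemerow index combines mean and maximum", {
  expect_equal(nemerow_index(c(2, 2, 2)), 2)
  expect_equal(nemerow_index(c(0, 0, 3)), sqrt((1 + 9) / 2))
  g <- grid_layer(matrix(runif(9), 3, 3))
  expect_equal(nemerow_index(list(g))$values, g$values)
  expect_error(nemerow_index(list()), "no sub-indices")
  expect_error(nemerow_index(c(-1, 2)), ">= 0")
  # bounded between mean and max; homogeneous of degree 1
  set.seed(5)
  for (i in 1:50) {
    p <- runif(3, 0, 5)
    v <- nemerow_index(p)
    expect_gte(v, mean(p) - 1e-12)
    expect_lte(v, max(p) + 1e-12)
    expect_equal(nemerow_index(2 * p), 2 * v, tolerance = 1e-12)
  }
})

test_that("indicator layers stay within [0, cap] on a synthetic scene", {
  sc <- generate_scene(scene_config(nrows = 40, ncols = 40, n_zones = 4,
                                    seed = 11))
  fit <- ito3de(sc)
  for (id in names(fit$indicators)) {
    v <- fit$indicators[[id]]$values
    expect_gte(min(v, na.rm = TRUE), 0)
    expect_lte(max(v, na.rm = TRUE), 10)
  }
})

test_that("indicator recipes follow their definitions on a tiny scene", {
  sc <- tiny_scene()
  # I1: zone totals spread over farmland, then / 250
  i1 <- build_indicator("I1", agrisk:::assemble_inputs(sc))
  farm1 <- sc$land_use$values %in% 1:2 &
    sc$zones$grid$values == 1
  expect_equal(unique(i1$values[farm1]), 100 / (4 * 0.09) / 250)
  expect_true(all(i1$values[sc$land_use$values == 3] == 0))
  # I7: slope/15 on farmland, 0 on forest
  i7 <- build_indicator("I7", agrisk:::assemble_inputs(sc))
  expect_equal(unique(i7$values[farm1]), 7.5 / 15)
  expect_true(all(i7$values[sc$land_use$values == 3] == 0))
  # I8: 1500 m / distance to the single water cell
  i8 <- build_indicator("I8", agrisk:::assemble_inputs(sc))
  wr <- which(sc$land_use$values == 4L, arr.ind = TRUE)
  expect_equal(i8$values[wr], 10)  # distance 0 clamps to the cap
  d <- sqrt(2) * 4 * 30  # cell (1,1) is 4 diagonal steps from the water
  expect_equal(i8$values[1, 1], 1500 / d)
  # I9: per-zone Nemerow of the three pollution indices
  i9 <- build_indicator("I9", agrisk:::assemble_inputs(sc))
  expect_equal(i9$values[1, 1],
               nemerow_index(c(0.8, 0.6, 0.9)))
  # I10: 61.95 / runoff; zone 1 sits at the reference
  i10 <- build_indicator("I10", agrisk:::assemble_inputs(sc))
  expect_equal(i10$values[1, 1], 1)
  expect_equal(i10$values[1, 6], 0.5)
  # I11: densities at their references give exactly 1
  i11 <- build_indicator("I11", agrisk:::assemble_inputs(sc))
  expect_equal(i11$values[1, 1], 1)
  # I12: paddy share vs 0.3339; zone 2 has no paddy -> farmland capped
  i12 <- build_indicator("I12", agrisk:::assemble_inputs(sc))
  p1 <- 2 / 4  # zone 1: 2 paddy of 4 farmland cells
  expect_equal(i12$values[2, 2], 0.3339 / p1)
  expect_equal(i12$values[2, 5], 10)
  expect_true(all(i12$values[sc$land_use$values == 3] == 0))
  # missing inputs are reported with the indicator id
  expect_error(build_indicator("I4", list()), "I4")
})

test_that("a paddy share at the long-term reference scores exactly 1", {
  expect_equal(normalize_negative(0.3339, 0.3339), 1)
})
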