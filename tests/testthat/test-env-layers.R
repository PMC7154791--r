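toy_grid <- function(nr = 20, nc = 20) grid_spec(nr, nc, cell_size = 3000)

const_layer <- function(v, g, kind) layer(matrix(v, g$n_rows, g$n_cols), g, kind)

test_that("Martin curve matches its closed form", {
  g <- toy_grid()
  n <- bathyniche:::n_cells(g)
  # value frozen from an independent evaluation of 10 * 2^-0.858
  out <- martin_poc(const_layer(10, g, "epc100"),
                    const_layer(200, g, "depth"))
  expect_equal(out$values[1], 5.517168700209797, tolerance = 1e-12)
  # identity at the export depth, zero flux propagates
  expect_equal(martin_poc(const_layer(10, g, "epc100"),
                          const_layer(100, g, "depth"))$values[5], 10)
  expect_equal(martin_poc(const_layer(0, g, "epc100"),
                          const_layer(1234, g, "depth"))$values[5], 0)
  # homogeneity of degree 1 in the export flux
  a <- martin_poc(const_layer(3, g, "epc100"), const_layer(700, g, "depth"))
  b <- martin_poc(const_layer(6, g, "epc100"), const_layer(700, g, "depth"))
  expect_equal(2 * a$values, b$values)
  expect_error(martin_poc(const_layer(1, g, "epc100"),
                          const_layer(-5, g, "depth")), "positive")
})

test_that("Martin curve commutes with masking and propagates missingness", {
  g <- toy_grid()
  set.seed(1)
  e <- layer(matrix(runif(400, 1, 20), 20, 20), g, "epc100")
  d <- layer(matrix(runif(400, 50, 4000), 20, 20), g, "depth")
  full <- martin_poc(e, d)
  mask <- matrix(runif(400) < 0.2, 20, 20)
  e2 <- e; e2$values[mask] <- NA
  masked_after <- full; masked_after$values[mask] <- NA
  expect_equal(martin_poc(e2, d)$values, masked_after$values)
})

test_that("saturation state is the concentration ratio with a horizon", {
  g <- toy_grid()
  expect_equal(saturation_state(const_layer(0.1, g, "co3"),
                                const_layer(0.1, g, "co3_sat_ar"))$values,
               matrix(1, 20, 20))
  expect_equal(saturation_state(const_layer(0.2, g, "co3"),
                                const_layer(0.1, g, "co3_sat_ar"))$values[7],
               2.0)
  expect_error(saturation_state(const_layer(0.2, g, "co3"),
                                const_layer(0, g, "co3_sat_ar")), "positive")
  # monotone-decreasing co3 with constant equilibrium: unique crossing,
  # deeper cells undersaturated
  depth_prof <- matrix(rep(seq(100, 4000, length.out = 20), each = 20), 20, 20)
  co3 <- layer(0.2 * exp(-depth_prof / 1500), g, "co3")
  om <- saturation_state(co3, const_layer(0.2 * exp(-1), g, "co3_sat_ar"))
  row1 <- om$values[1, ]
  crossings <- sum(diff(sign(row1 - 1)) != 0)
  expect_equal(crossings, 1)
  expect_true(all(row1[depth_prof[1, ] > 1500 + 150] < 1))
})

test_that("slope matches the closed form for a plane and ignores offsets", {
  g <- toy_grid()
  expect_equal(slope(const_layer(1000, g, "depth"))$values,
               matrix(0, 20, 20))
  # plane dipping 30 m per 3000-m cell across columns
  plane <- matrix(rep(seq(0, by = 30, length.out = 20), each = 20), 20, 20)
  sl <- slope(layer(plane, g, "depth"))
  interior <- sl$values[5:15, 5:15]
  expect_equal(as.vector(interior),
               rep(0.5729386976834859, length(interior)), tolerance = 1e-9)
  sl2 <- slope(layer(plane + 500, g, "depth"))
  expect_equal(sl$values, sl2$values)
  expect_true(all(sl$values >= 0 & sl$values < 90))
})

test_that("BPI standardizes to mean 0, sd 1 and flags flat fields", {
  g <- toy_grid(40, 40)
  expect_error(bpi(const_layer(2000, g, "depth"), terrain_params(2, 6)),
               "zero variance")
  set.seed(2)
  d <- layer(matrix(2000 + rnorm(1600, sd = 100), 40, 40), g, "depth")
  b <- bpi(d, terrain_params(2, 6))
  v <- b$values[!is.na(b$values)]
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sd(v) - 1), 1e-6)
  expect_error(bpi(d, terrain_params(3, 30)), "outer radius")
})

test_that("an isolated seamount has the maximum standardized BPI", {
  g <- toy_grid(40, 40)
  d <- matrix(3000, 40, 40)
  d[20, 20] <- 1000 # shallow peak in a flat abyss
  b <- bpi(layer(d, g, "depth"), terrain_params(2, 6))
  expect_equal(which.max(b$values), 20L + 19L * 40L)
  # direct annulus computation at the peak: elevation minus annulus mean
  offs <- expand.grid(dr = -6:6, dc = -6:6)
  r <- sqrt(offs$dr^2 + offs$dc^2)
  ann <- offs[r <= 6 & r > 2, ]
  ann_mean <- mean(-d[cbind(20 + ann$dr, 20 + ann$dc)])
  raw_peak <- -d[20, 20] - ann_mean
  expect_gt(raw_peak, 0) # crest convention: elevated cell is positive
})

test_that("kriging downscale reproduces depth-driven fields and constants", {
  fxw <- fx_world_mid()
  depth <- fxw$world$depth
  g <- depth$grid
  ocean_cells <- which(!is.na(depth$values))
  set.seed(3)
  samp <- sample(ocean_cells, 60)
  xy <- bathyniche:::cell_xy(g, samp)

  # affine function of depth: inside the drift model class
  coarse <- data.frame(x = xy$x, y = xy$y,
                       value = 2 + 0.003 * depth$values[samp])
  fine <- downscale(coarse, depth)
  truth <- 2 + 0.003 * depth$values
  ok <- !is.na(truth)
  rmse <- sqrt(mean((fine$values[ok] - truth[ok])^2))
  expect_lt(rmse, 0.01 * diff(range(truth[ok])))
  # exact interpolator at the sample cells
  expect_lt(max(abs(fine$values[samp] - coarse$value)), 1e-6)

  # constant coarse field stays constant
  coarse_c <- data.frame(x = xy$x, y = xy$y, value = 7)
  fine_c <- downscale(coarse_c, depth)
  expect_equal(fine_c$values[ok], rep(7, sum(ok)), tolerance = 1e-8)

  expect_error(downscale(coarse[1:5, ], depth), "at least 10")
})

test_that("dropping the depth drift degrades held-out accuracy on a depth-driven field", {
  fxw <- fx_world_mid()
  depth <- fxw$world$depth
  g <- depth$grid
  ocean_cells <- which(!is.na(depth$values))
  set.seed(4)
  samp <- sample(ocean_cells, 80)
  xy <- bathyniche:::cell_xy(g, samp)
  value <- 5 + 0.002 * depth$values[samp] + rnorm(80, sd = 0.2)
  coarse <- data.frame(x = xy$x, y = xy$y, value = value)
  hold <- setdiff(sample(ocean_cells, 500), samp)
  truth <- 5 + 0.002 * depth$values[hold]
  with_drift <- downscale(coarse, depth, use_drift = TRUE)
  without <- downscale(coarse, depth, use_drift = FALSE)
  rmse_with <- sqrt(mean((with_drift$values[hold] - truth)^2))
  rmse_without <- sqrt(mean((without$values[hold] - truth)^2))
  expect_lt(rmse_with, rmse_without)
})

test_that("layer validation returns R and RMSE with exact edge cases", {
  x <- c(1, 2, 3, 4, 5)
  v <- validate_layer(x, x)
  expect_equal(v$adjusted_R, 1, tolerance = 1e-9)
  expect_equal(v$RMSE, 0)
  v2 <- validate_layer(x, x + 3)
  expect_equal(v2$adjusted_R, 1, tolerance = 1e-9)
  expect_equal(v2$RMSE, 3)
  expect_error(validate_layer(x, rep(1, 5)), "zero variance")
  expect_error(validate_layer(x[1:2], x[1:2]), "at least 3")

  # known noise level recovered within 10% at n = 1000
  set.seed(6)
  m <- rnorm(1000)
  o <- m + rnorm(1000, sd = 0.5)
  v3 <- validate_layer(m, o)
  expect_equal(v3$RMSE, 0.5, tolerance = 0.1)
  v4 <- validate_layer(m, o, adjusted_r = "correlation")
  expect_equal(v4$adjusted_R, cor(m, o))
})
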