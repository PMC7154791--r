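# Spearman rank correlation computed from first principles (no ties in
# these continuous fields), independent of stats::cor's implementation.
rank_rho <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  n <- length(a)
  1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
}

test_that("world generation is deterministic in the seed and seed-sensitive", {
  g <- grid_spec(60, 60)
  w1 <- build_world(g, seed = 3)
  w2 <- build_world(g, seed = 3)
  expect_identical(w1$stack$layers$temp$values, w2$stack$layers$temp$values)
  expect_identical(w1$depth$values, w2$depth$values)

  w3 <- build_world(g, seed = 4)
  both <- !is.na(w1$depth$values) & !is.na(w3$depth$values)
  frac_diff <- mean(w1$depth$values[both] != w3$depth$values[both])
  expect_gt(frac_diff, 0.01)
})

test_that("world has depth zones, a majority ocean mask and finite layers", {
  fxw <- fx_world_small()
  d <- fxw$world$depth$values
  ocean <- !is.na(d)
  expect_gte(mean(ocean), 0.6)
  expect_true(all(d[ocean] > 0))
  expect_lt(min(d[ocean]), 200)   # shelf present
  expect_gt(max(d[ocean]), 2000)  # abyss present
  for (l in fxw$world$stack$layers)
    expect_true(all(is.finite(l$values[ocean])))
  expect_error(build_world(grid_spec(30, 10)), "too small")
})

test_that("temperature decreases and saturation states cross 1 with depth", {
  g <- grid_spec(200, 200)
  w <- build_world(g, seed = 9)
  d <- as.vector(w$depth$values)
  ok <- !is.na(d)
  t <- as.vector(w$stack$layers$temp$values)[ok]
  expect_lt(rank_rho(t, d[ok]), -0.5)
  for (nm in c("omega_ar", "omega_cal")) {
    om <- as.vector(w$stack$layers[[nm]]$values)[ok]
    expect_lt(rank_rho(om, d[ok]), -0.85)
    expect_true(any(om < 1) && any(om > 1)) # horizon inside the domain
  }
})

test_that("scenario deltas follow the additive/multiplicative contract", {
  fxw <- fx_world_small()
  st <- fxw$world$stack

  ident <- scenario_delta(list(temp = list(offset = 0, factor = 1)))
  expect_identical(apply_scenario(st, ident)$layers$temp$values,
                   st$layers$temp$values)

  plus1 <- apply_scenario(st, scenario_delta(list(temp = list(offset = 1))))
  dd <- plus1$layers$temp$values - st$layers$temp$values
  expect_equal(dd[!is.na(dd)], rep(1, sum(!is.na(dd))))
  # untouched covariates bit-identical
  expect_identical(plus1$layers$DO$values, st$layers$DO$values)

  half <- apply_scenario(st, scenario_delta(list(epc100 = list(factor = 0.5))))
  ratio <- half$layers$epc100$values / st$layers$epc100$values
  pos <- !is.na(ratio) & st$layers$epc100$values > 0
  expect_equal(ratio[pos], rep(0.5, sum(pos)))

  expect_error(apply_scenario(st, scenario_delta(list(nope = list(offset = 1)))),
               "unknown covariates")
  expect_error(scenario_delta(list(temp = list(factor = -1))), ">= 0")
})

test_that("oracle suitability follows the closed-form response product", {
  g <- grid_spec(10, 10)
  tempv <- matrix(seq(0, 12, length.out = 100), 10, 10)
  st <- layer_stack(list(temp = layer(tempv, g, "temp"),
                         DO = layer(matrix(200, 10, 10), g, "DO")))
  n1 <- niche_spec(list(list(covariate = "temp", shape = "gaussian",
                             optimum = 6, breadth = 2)),
                   max_prevalence = 0.8)
  s <- oracle_suitability(st, n1)$values
  expect_equal(max(s), 0.8 * exp(-0.5 * ((tempv[which.max(s)] - 6) / 2)^2))
  # exact value at the optimum and at optimum +/- one breadth
  at <- function(x) 0.8 * exp(-0.5 * ((x - 6) / 2)^2)
  i_opt <- which.min(abs(tempv - 6))
  expect_equal(s[i_opt], at(tempv[i_opt]))
  i_br <- which.min(abs(tempv - 8))
  expect_equal(s[i_br], at(tempv[i_br]))
  expect_equal(at(8), 0.8 * exp(-0.5), tolerance = 1e-12)

  # product identity: a response at its optimum contributes factor 1
  n2 <- niche_spec(list(
    list(covariate = "temp", shape = "gaussian", optimum = 6, breadth = 2),
    list(covariate = "DO", shape = "gaussian", optimum = 200, breadth = 30)),
    max_prevalence = 0.8)
  expect_equal(oracle_suitability(st, n2)$values, s)
  expect_error(oracle_suitability(st, niche_spec(list(
    list(covariate = "slope", shape = "gaussian", optimum = 1, breadth = 1)))),
    "absent from stack")
})

test_that("occurrence simulation tracks suitability and applies corruption", {
  fxw <- fx_world_small()
  st <- fxw$present
  niche <- fx_niche()

  occ <- simulate_occurrences(st, niche, 500, seed = 8)
  expect_equal(nrow(occ), 500)
  expect_false(any(duplicated(occ$cell_id)))
  # presences concentrate on suitable habitat: one-sided rank test
  suit <- oracle_suitability(st, niche)$values
  pres_suit <- suit[occ$cell_id]
  dom_suit <- suit[!is.na(suit)]
  wt <- wilcox.test(pres_suit, dom_suit, alternative = "greater")
  expect_lt(wt$p.value, 0.01)

  # corruption counts are exact by construction
  corr <- corruption_spec(frac_missing_depth = 0.1,
                          frac_depth_mismatch = 0.05,
                          frac_coarse_position = 0.05)
  occ2 <- simulate_occurrences(st, niche, 1000, corr, seed = 8)
  expect_equal(sum(is.na(occ2$reported_depth_m)), 100)
  expect_equal(sum(occ2$position_accuracy_m > 5000), 50)

  # zero corruption: everything passes the QC chain
  qc <- qc_occurrences(occ, fxw$world$depth)
  expect_equal(nrow(qc$rejected), 0)
  expect_equal(nrow(qc$kept), 500)

  expect_error(simulate_occurrences(st, niche, 10^7), "exceeds")
})

test_that("a flat niche samples presences like the ocean depth distribution", {
  fxw <- fx_world_mid()
  st <- fxw$present
  flat <- niche_spec(list(list(covariate = "temp", shape = "gaussian",
                               optimum = 0, breadth = 1e9)),
                     max_prevalence = 0.9)
  occ <- simulate_occurrences(st, flat, 1000, seed = 12)
  depths <- st$layers$depth$values
  ks <- suppressWarnings(
    ks.test(occ$reported_depth_m, depths[!is.na(depths)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("future suitability declines for a present-centred niche", {
  for (seed in c(21, 22, 23)) {
    g <- grid_spec(60, 60)
    w <- build_world(g, seed = seed)
    present <- prepare_layers(w$stack, terrain = terrain_params(3, 10))
    future <- prepare_layers(apply_scenario(w$stack, scenario_delta()),
                             terrain = terrain_params(3, 10))
    niche <- fx_niche()
    s_p <- oracle_suitability(present, niche)$values
    s_f <- oracle_suitability(future, niche)$values
    expect_lt(mean(s_f, na.rm = TRUE), mean(s_p, na.rm = TRUE))
  }
})

test_that("occurrence CSV round-trips", {
  fxw <- fx_world_small()
  occ <- simulate_occurrences(fxw$present, fx_niche(), 50, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_occurrences_csv(occ, path)
  back <- read_occurrences_csv(path)
  expect_equal(back$cell_id, occ$cell_id)
  expect_equal(back$reported_depth_m, occ$reported_depth_m, tolerance = 1e-9)
})
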