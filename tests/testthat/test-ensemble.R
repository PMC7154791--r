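fake_metrics <- function(auc, tss) {
  structure(list(auc = auc, tss_mss = tss), class = "bn_metrics")
}

hsi_layer <- function(v, g) layer(matrix(v, g$n_rows, g$n_cols), g, "hsi")

test_that("ensemble weights normalize the AUC/TSS means", {
  mets <- list(MAXENT = fake_metrics(1.0, 1.0),
               GAM = fake_metrics(0.5, 0.5),
               RF = fake_metrics(0.5, 0.5))
  w <- ensemble_weights(mets)
  expect_equal(w$weight, c(0.5, 0.25, 0.25)) # normalize (1, .5, .5)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_error(ensemble_weights(list(A = fake_metrics(0, 0))), "zero")
})

test_that("ensemble HSI is the weighted per-cell mean with missing propagation", {
  g <- grid_spec(10, 10)
  set.seed(61)
  a <- hsi_layer(runif(100), g); b <- hsi_layer(runif(100), g)
  c3 <- hsi_layer(runif(100), g)
  preds <- list(MAXENT = a, GAM = b, RF = c3)

  eq <- ensemble_hsi(preds, list(MAXENT = fake_metrics(0.9, 0.6),
                                 GAM = fake_metrics(0.9, 0.6),
                                 RF = fake_metrics(0.9, 0.6)))
  expect_equal(eq$hsi$values, (a$values + b$values + c3$values) / 3)

  # zero-weight family contributes nothing
  zw <- ensemble_hsi(preds, list(MAXENT = fake_metrics(0.8, 0.4),
                                 GAM = fake_metrics(0.8, 0.4),
                                 RF = fake_metrics(0, 0)))
  expect_equal(zw$hsi$values, (a$values + b$values) / 2)

  # convex combination bound and NA propagation
  w3 <- ensemble_hsi(preds, list(MAXENT = fake_metrics(0.95, 0.8),
                                 GAM = fake_metrics(0.7, 0.3),
                                 RF = fake_metrics(0.85, 0.5)))
  lo <- pmin(a$values, b$values, c3$values)
  hi <- pmax(a$values, b$values, c3$values)
  expect_true(all(w3$hsi$values >= lo - 1e-12 & w3$hsi$values <= hi + 1e-12))

  a_na <- a; a_na$values[5] <- NA
  na_out <- ensemble_hsi(list(MAXENT = a_na, GAM = b, RF = c3),
                         eq$weights)
  expect_true(is.na(na_out$hsi$values[5]))
  expect_false(anyNA(na_out$hsi$values[-5]))
})

test_that("permutation importance is 1 minus Pearson correlation, 0 when unused", {
  # hand-built single-feature model: output strictly monotone in x, so
  # permuting x decorrelates predictions almost completely
  set.seed(62)
  n <- 1000
  tab <- data.frame(x = runif(n), z = runif(n))
  meta <- bathyniche:::maxent_feature_meta(tab, "x")
  X <- bathyniche:::maxent_features(meta, tab)
  beta <- rep(0, ncol(X)); beta[1] <- 1 # linear feature only
  m <- bathyniche:::new_model("MAXENT", NULL, "x",
                              extras = list(feature_meta = meta,
                                            beta = beta, centre = 0,
                                            prevalence = 0.5))
  imp <- permutation_importance(m, tab, "x", reps = 10, seed = 1)
  expect_equal(imp$mean, 1, tolerance = 0.1)
  expect_length(imp$values, 10)
  expect_gt(imp$sd, 0)

  # a variable absent from the model has importance exactly 0
  imp0 <- permutation_importance(m, tab, "z", reps = 10, seed = 1)
  expect_identical(imp0$values, rep(0, 10))
  expect_equal(imp0$mean, 0, tolerance = 1e-12)

  # constant predictions are flagged, not crashed
  mconst <- bathyniche:::new_model("MAXENT", NULL, "x",
                                   extras = list(feature_meta = meta,
                                                 beta = rep(0, ncol(X)),
                                                 centre = 0,
                                                 prevalence = 0.5))
  impc <- permutation_importance(mconst, tab, "x", reps = 5)
  expect_true(impc$degenerate)
  expect_equal(impc$mean, 0)
  expect_error(permutation_importance(m, tab, "nope"), "not in table")
})

test_that("ensemble importance is the weight-averaged table", {
  w <- structure(data.frame(family = c("MAXENT", "GAM", "RF"),
                            auc = 1, tss = 1,
                            weight = c(0.5, 0.25, 0.25)),
                 class = c("bn_weights", "data.frame"))
  # frozen dot product: (0.5, 0.25, 0.25) . (0.4, 0.2, 0.2) = 0.30
  expect_equal(sum(w$weight * c(0.4, 0.2, 0.2)), 0.30)
})

test_that("bootstrap uncertainty is seeded, non-negative and shrinks with n", {
  fxw <- fx_world_small()
  st <- fxw$present
  niche <- fx_niche()
  occ <- simulate_occurrences(st, niche, 200, seed = 63)
  pres <- rasterize_presences(occ, fxw$grid)
  pa <- generate_pseudo_absences(pres, st, n_target = 600,
                                 strata_edges = c(-Inf, Inf), seed = 63)
  tab <- assemble_training(pres, pa, st)
  covs <- c("temp", "omega_ar")

  cv_a <- bootstrap_uncertainty("MAXENT", tab, st, covs, B = 15, seed = 9)
  cv_b <- bootstrap_uncertainty("MAXENT", tab, st, covs, B = 15, seed = 9)
  expect_identical(cv_a$values, cv_b$values)
  v <- cv_a$values[!is.na(cv_a$values)]
  expect_true(all(v >= 0))

  # smaller training sets give larger per-cell spread
  small <- tab[c(sample(which(tab$label == 1), 40),
                 sample(which(tab$label == 0), 120)), ]
  cv_small <- bootstrap_uncertainty("MAXENT", small, st, covs, B = 15,
                                    seed = 9)
  expect_lt(median(cv_a$values, na.rm = TRUE),
            median(cv_small$values, na.rm = TRUE))
})

test_that("ensemble uncertainty averages the family CV grids", {
  g <- grid_spec(10, 10)
  w <- structure(data.frame(family = c("A", "B"), auc = 1, tss = 1,
                            weight = c(0.7, 0.3)),
                 class = c("bn_weights", "data.frame"))
  cv1 <- layer(matrix(0.2, 10, 10), g, "cv")
  cv2 <- layer(matrix(0.6, 10, 10), g, "cv")
  out <- ensemble_uncertainty(list(A = cv1, B = cv2), w)
  expect_equal(out$values, matrix(0.7 * 0.2 + 0.3 * 0.6, 10, 10))
  same <- ensemble_uncertainty(list(A = cv1, B = cv1), w)
  expect_equal(same$values, cv1$values)
  w2 <- w; w2$weight <- c(1, 0)
  expect_equal(ensemble_uncertainty(list(A = cv1, B = cv2), w2)$values,
               cv1$values)
})
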