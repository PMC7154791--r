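# Shared fixtures, built once per test run and memoised. All seeds are
# fixed constants so the suite is reproducible.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_env)) {
    assign(name, force(expr), envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

# Small prepared world for cheap module tests.
fx_world_small <- function() fx("world_small", {
  g <- grid_spec(80, 80)
  w <- build_world(g, seed = 42)
  list(grid = g, world = w,
       present = prepare_layers(w$stack, terrain = terrain_params(3, 10)))
})

# Mid-size world for model-level tests.
fx_world_mid <- function() fx("world_mid", {
  g <- grid_spec(100, 100)
  w <- build_world(g, seed = 42)
  list(grid = g, world = w,
       present = prepare_layers(w$stack, terrain = terrain_params(3, 12)))
})

fx_niche <- function() bathyniche:::default_niche("scleractinian")

# The main niche-recovery run: 200 x 200 world, 1000 presence cells,
# 2000 buffered pseudo-absences (single stratum at this domain size),
# all three families fitted and block-cross-validated. Shared by the
# recovery, threshold, null-control and climate-response tests.
fx_recovery <- function() fx("recovery", {
  g <- grid_spec(200, 200)
  w <- build_world(g, seed = 101)
  present <- prepare_layers(w$stack)
  future <- prepare_layers(apply_scenario(w$stack, scenario_delta()))
  niche <- fx_niche()
  occ <- simulate_occurrences(present, niche, 1000, seed = 101)
  pres <- rasterize_presences(qc_occurrences(occ, w$depth)$kept, g)
  pa <- generate_pseudo_absences(pres, present, n_target = 2000,
                                 strata_edges = c(-Inf, Inf), seed = 101)
  table <- assemble_training(pres, pa, present)
  sel <- select_predictors(predictor_policy("scleractinian"), table)
  covs <- sel$retained
  xy <- bathyniche:::cell_xy(g, table$cell_id)
  blocks <- make_blocks(xy$x, xy$y)
  models <- list(); metrics <- list()
  for (fam in c("MAXENT", "GAM", "RF")) {
    models[[fam]] <- fit_sdm(fam, table, covs, seed = 101)
    metrics[[fam]] <- cv_run(fam, table, blocks, covs, seed = 101)
  }
  weights <- ensemble_weights(metrics)
  hsi_p <- ensemble_hsi(lapply(models, predict_hsi, stack = present),
                        weights)$hsi
  hsi_f <- ensemble_hsi(lapply(models, predict_hsi, stack = future),
                        weights)$hsi
  train_scores <- rep(0, nrow(table))
  for (i in seq_len(nrow(weights)))
    train_scores <- train_scores + weights$weight[i] *
      predict_table(models[[weights$family[i]]], table)
  list(grid = g, world = w, present = present, future = future,
       niche = niche, presences = pres, pa = pa, table = table,
       covariates = covs, blocks = blocks, models = models,
       metrics = metrics, weights = weights,
       hsi_present = hsi_p, hsi_future = hsi_f,
       train_scores = train_scores,
       oracle = oracle_suitability(present, niche))
})

# Presence set + 10,000 stratified pseudo-absences under the coral-group
# defaults on the default-scale world (the background-generation
# acceptance conditions).
fx_background_default <- function() fx("background_default", {
  g <- grid_spec(480, 480)
  w <- build_world(g, seed = 7)
  present <- prepare_layers(w$stack)
  occ <- simulate_occurrences(present, fx_niche(), 300, seed = 7)
  pres <- rasterize_presences(qc_occurrences(occ, w$depth)$kept, g)
  pa <- generate_pseudo_absences(pres, present, n_target = 10000, seed = 7)
  list(grid = g, world = w, present = present, presences = pres, pa = pa)
})

# Simple labelled table with a known single-covariate signal.
fx_separable_table <- function(n = 600, seed = 5) {
  set.seed(seed)
  x <- runif(n)
  data.frame(cell_id = seq_len(n), x = x, label = as.integer(x > 0.5))
}
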