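#' Default run configuration
#'
#' Nested configuration for a full pipeline run, with group presets
#' carrying the standard parameter values: pseudo-absence counts of
#' 10,000 (corals) or 100,000 (fishes), a 6 km presence buffer, 10
#' blocked-CV iterations at an 80% subsample, 10 permutation-importance
#' replicates, 100 bootstrap replicates, both binarization thresholds,
#' Spearman 0.85 / VIF 10 collinearity cut-offs and 4-knot smooths
#' (3 for temperature and saturation states in coral models).
#'
#' @param group Species-group preset: `"scleractinian"`, `"octocoral"`
#'   or `"fish"`.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory (NULL = no files written).
#' @return Nested list of class `bn_config`.
#' @export
default_config <- function(group = "scleractinian", seed = 1,
                           out_dir = NULL) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    world = list(n_rows = 480, n_cols = 480, cell_size = 3000,
                 noise_sigma_cells = 6,
                 bpi_inner = 3, bpi_outer = 25),
    species = list(group = group, name = paste0("synthetic_", group),
                   n_occurrences = 300,
                   niche = NULL, # NULL = group default niche
                   corruption = list(frac_missing_depth = 0,
                                     frac_depth_mismatch = 0,
                                     frac_coarse_position = 0)),
    background = list(
      n = if (group == "fish") 100000 else 10000,
      buffer_m = 6000, strata_width_m = 250, strata_edges = NULL),
    predictors = list(rho_threshold = 0.85, vif_threshold = 10),
    model = list(families = c("MAXENT", "GAM", "RF"),
                 rf_ntree = 500, gam_default_k = 4),
    evaluation = list(iterations = 10, subsample = 0.80),
    ensemble = list(importance_reps = 10, bootstrap_B = 100,
                    uncertainty = FALSE),
    projection = list(thresholds = c("P10", "MSS"))),
    class = "bn_config")
}

config_schema <- function() {
  list(seed = NULL, out_dir = NULL,
       world = c("n_rows", "n_cols", "cell_size", "noise_sigma_cells",
                 "bpi_inner", "bpi_outer"),
       species = c("group", "name", "n_occurrences", "niche", "corruption"),
       background = c("n", "buffer_m", "strata_width_m", "strata_edges"),
       predictors = c("rho_threshold", "vif_threshold"),
       model = c("families", "rf_ntree", "gam_default_k"),
       evaluation = c("iterations", "subsample"),
       ensemble = c("importance_reps", "bootstrap_B", "uncertainty"),
       projection = c("thresholds"))
}

#' Validate a run configuration
#'
#' Rejects unknown keys before any stage runs.
#'
#' @param config A config list (e.g. from [default_config()] or
#'   [read_config()]).
#' @return The config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(schema)) {
    if (is.null(schema[[blk]]) || is.null(config[[blk]])) next
    bad <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(bad))
      stop("unknown config key(s) in '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' Read a YAML run configuration
#'
#' Values present in the file override the group-preset defaults.
#'
#' @param path YAML file.
#' @return Validated `bn_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n:` mapping key as boolean FALSE; restore it
  fix_keys <- function(x) {
    if (!is.list(x)) return(x)
    names(x)[names(x) == "FALSE"] <- "n"
    lapply(x, fix_keys)
  }
  user <- fix_keys(user)
  base <- default_config(group = user$species$group %||% "scleractinian",
                         seed = user$seed %||% 1)
  merge2 <- function(a, b) {
    for (k in names(b))
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
        merge2(a[[k]], b[[k]]) else b[[k]]
    a
  }
  cfg <- merge2(base, user)
  class(cfg) <- "bn_config"
  validate_config(cfg)
  cfg
}

# Group-default synthetic niche: a cold-water, mid-slope taxon centred
# on present-day conditions.
default_niche <- function(group) {
  switch(group,
    scleractinian = niche_spec(list(
      list(covariate = "temp", shape = "gaussian", optimum = 6, breadth = 1.5),
      list(covariate = "omega_ar", shape = "increasing-sigmoid",
           optimum = 1.1, breadth = 0.25),
      list(covariate = "poc_seafloor", shape = "increasing-sigmoid",
           optimum = 1.0, breadth = 0.8)),
      max_prevalence = 0.9),
    octocoral = niche_spec(list(
      list(covariate = "temp", shape = "gaussian", optimum = 5, breadth = 1.5),
      list(covariate = "omega_cal", shape = "increasing-sigmoid",
           optimum = 1.3, breadth = 0.3)),
      max_prevalence = 0.9),
    fish = niche_spec(list(
      list(covariate = "temp", shape = "gaussian", optimum = 6, breadth = 2),
      list(covariate = "depth", shape = "gaussian", optimum = 900,
           breadth = 400),
      list(covariate = "DO", shape = "increasing-sigmoid", optimum = 180,
           breadth = 25)),
      max_prevalence = 0.9))
}

#' Run the full pipeline
#'
#' Orchestrates simulate, prepare-layers, QC, background generation,
#' predictor selection, the three family fits, blocked cross-validation,
#' ensembling, optional bootstrap uncertainty, dual-threshold
#' binarization of present and future maps, and loss/gain/refugia
#' summaries. Every stochastic stage draws from a stage-scoped stream
#' derived from the master seed, so identical configs reproduce
#' identical results. When `out_dir` is set, intermediate artifacts are
#' written (ASCII grids, CSVs, JSON) and a manifest with their MD5
#' digests is returned.
#'
#' @param config A `bn_config`.
#' @return List with all stage outputs (world, stacks, training table,
#'   models, metrics, weights, ensemble HSI present/future, thresholds,
#'   binary/change maps, summaries) plus a `manifest`.
#' @export
run_all <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # --- simulate -----------------------------------------------------------
  g <- grid_spec(config$world$n_rows, config$world$n_cols,
                 cell_size = config$world$cell_size)
  world <- build_world(g, seed,
                       noise_sigma_cells = config$world$noise_sigma_cells)
  terrain <- terrain_params(config$world$bpi_inner, config$world$bpi_outer)
  present <- prepare_layers(world$stack, terrain = terrain)
  future <- prepare_layers(apply_scenario(world$stack, scenario_delta()),
                           terrain = terrain)
  log_stage("simulate", "world %dx%d, %d ocean cells", g$n_rows, g$n_cols,
            sum(!is.na(world$depth$values)))

  niche <- config$species$niche %||% default_niche(config$species$group)
  corr <- do.call(corruption_spec, config$species$corruption)
  occ <- simulate_occurrences(present, niche, config$species$n_occurrences,
                              corr, seed = seed,
                              species = config$species$name)

  # --- qc -----------------------------------------------------------------
  qc <- qc_occurrences(occ, world$depth)
  presences <- rasterize_presences(qc$kept, g)
  log_stage("qc", "%d records kept, %d rejected, %d presence cells",
            nrow(qc$kept), nrow(qc$rejected), presences$n_cells)

  # --- background ---------------------------------------------------------
  pa <- generate_pseudo_absences(
    presences, present, n_target = config$background$n,
    buffer_m = config$background$buffer_m,
    strata_edges = config$background$strata_edges,
    strata_width = config$background$strata_width_m, seed = seed)
  training <- assemble_training(presences, pa, present)
  log_stage("background", "%d pseudo-absences, %d training rows",
            length(pa), nrow(training))

  # --- predictor selection ------------------------------------------------
  policy <- predictor_policy(config$species$group,
                             rho_threshold = config$predictors$rho_threshold,
                             vif_threshold = config$predictors$vif_threshold)
  sel <- select_predictors(policy, training)
  covariates <- sel$retained
  log_stage("predictors", "retained: %s", paste(covariates, collapse = ", "))

  # --- fit + evaluate -----------------------------------------------------
  xy <- cell_xy(g, training$cell_id)
  blocks <- make_blocks(xy$x, xy$y)
  smooths <- smooth_spec(default_k = config$model$gam_default_k)
  fit_args_for <- function(fam) switch(fam,
    RF = list(ntree = config$model$rf_ntree),
    GAM = list(smooths = smooths),
    list())
  models <- list(); metrics <- list()
  for (fam in config$model$families) {
    models[[fam]] <- do.call(fit_sdm,
      c(list(fam, training, covariates, seed = seed), fit_args_for(fam)))
    metrics[[fam]] <- cv_run(fam, training, blocks, covariates,
                             iterations = config$evaluation$iterations,
                             subsample = config$evaluation$subsample,
                             seed = seed, fit_args = fit_args_for(fam))
    log_stage("evaluate", "%s: AUC %.3f, TSS(MSS) %.3f [%s]", fam,
              metrics[[fam]]$auc, metrics[[fam]]$tss_mss,
              accuracy_class(metrics[[fam]]$auc, metrics[[fam]]$tss_mss))
  }
  weights <- ensemble_weights(metrics)

  # --- ensemble -----------------------------------------------------------
  pred_present <- lapply(models, predict_hsi, stack = present)
  pred_future <- lapply(models, predict_hsi, stack = future)
  ens_present <- ensemble_hsi(pred_present, weights)$hsi
  ens_future <- ensemble_hsi(pred_future, weights)$hsi
  importance <- ensemble_importance(models, training, weights,
                                    reps = config$ensemble$importance_reps,
                                    seed = seed)
  uncertainty <- NULL
  if (isTRUE(config$ensemble$uncertainty)) {
    cvs <- lapply(stats::setNames(nm = config$model$families), function(fam)
      bootstrap_uncertainty(fam, training, present, covariates,
                            B = config$ensemble$bootstrap_B, seed = seed,
                            fit_args = fit_args_for(fam)))
    uncertainty <- ensemble_uncertainty(cvs, weights)
  }

  # --- project ------------------------------------------------------------
  train_scores <- rep(0, nrow(training))
  for (i in seq_len(nrow(weights)))
    train_scores <- train_scores + weights$weight[i] *
      predict_table(models[[weights$family[i]]], training)
  thresholds <- list(
    P10 = threshold_p10(train_scores[training$label == 1]),
    MSS = threshold_mss(training$label, train_scores))
  projections <- list()
  for (rule in config$projection$thresholds) {
    thr <- thresholds[[rule]]
    bp <- binarize(ens_present, thr, "present")
    bf <- binarize(ens_future, thr, "future")
    projections[[rule]] <- list(
      present = bp, future = bf,
      change = change_map(bp, bf),
      summary = summarize_habitat(bp, bf, world$depth))
    s <- projections[[rule]]$summary
    log_stage("project", "%s: area %+.1f%%, refugia %.1f%%", rule,
              s$percent_change, s$refugia_percent_of_present)
  }

  result <- list(config = config, grid = g, world = world,
                 present = present, future = future, niche = niche,
                 occurrences = occ, qc = qc, presences = presences,
                 pseudo_absences = pa, training = training,
                 predictor_selection = sel, blocks = blocks,
                 models = models, metrics = metrics, weights = weights,
                 hsi_present = ens_present, hsi_future = ens_future,
                 importance = importance, uncertainty = uncertainty,
                 thresholds = thresholds, projections = projections)
  result$manifest <- write_run_artifacts(result, config$out_dir)
  result
}

# Write the run's artifacts and return a manifest of MD5 digests. With
# out_dir = NULL a digest of the key numerical outputs is still computed
# (via a canonical JSON serialisation) so reruns can be compared.
write_run_artifacts <- function(result, out_dir) {
  summaries <- lapply(result$projections, function(p) unclass(p$summary))
  key <- list(
    weights = result$weights$weight,
    auc = vapply(result$metrics, function(m) m$auc, numeric(1)),
    thresholds = lapply(result$thresholds, function(t) t$value),
    summaries = summaries,
    n_training = nrow(result$training))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(key, tmp, auto_unbox = TRUE, digits = 12)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(seed = result$config$seed, digest = digest,
                   files = character(0))
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_layer_asc(result$world$depth, fp("depth.asc"))
  write_layer_asc(result$hsi_present, fp("hsi_present.asc"))
  write_layer_asc(result$hsi_future, fp("hsi_future.asc"))
  if (!is.null(result$uncertainty))
    write_layer_asc(result$uncertainty, fp("uncertainty_cv.asc"))
  write_occurrences_csv(result$occurrences, fp("occurrences.csv"))
  utils::write.csv(result$training, fp("training.csv"), row.names = FALSE)
  utils::write.csv(result$importance, fp("importance.csv"),
                   row.names = FALSE)
  for (rule in names(result$projections)) {
    write_change_asc(result$projections[[rule]]$change,
                     fp(sprintf("change_%s.asc", rule)))
  }
  jsonlite::write_json(
    c(list(seed = result$config$seed,
           weights = stats::setNames(as.list(result$weights$weight),
                                     result$weights$family),
           thresholds = lapply(result$thresholds, function(t) t$value)),
      list(summaries = summaries)),
    fp("summary.json"), auto_unbox = TRUE, digits = 10)
  files <- list.files(out_dir, full.names = TRUE)
  manifest$files <- stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))
  manifest
}
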