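#' Metric-based ensemble weights
#'
#' One weight per model family, proportional to the mean of its blocked
#' cross-validation AUC and TSS (TSS taken at the
#' maximum-sensitivity-plus-specificity threshold), normalised to sum
#' to 1.
#'
#' @param metrics Named list of `bn_metrics` (one per family).
#' @return Object of class `bn_weights`: data.frame with family, auc,
#'   tss, weight.
#' @export
ensemble_weights <- function(metrics) {
  fam <- names(metrics)
  a <- vapply(metrics, function(m) m$auc, numeric(1))
  t <- vapply(metrics, function(m) m$tss_mss, numeric(1))
  raw <- pmax((a + t) / 2, 0)
  if (sum(raw) <= 0) stop("all ensemble weights are zero")
  structure(data.frame(family = fam, auc = a, tss = t,
                       weight = raw / sum(raw), row.names = NULL),
            class = c("bn_weights", "data.frame"))
}

#' Weighted ensemble habitat-suitability layer
#'
#' Per-cell weighted mean of the family HSI layers; a cell missing in
#' any family is missing in the ensemble. The ensemble is a convex
#' combination, so each cell lies between the per-family minimum and
#' maximum.
#'
#' @param predictions Named list of `bn_layer` HSI maps (one per
#'   family).
#' @param weights A `bn_weights` (or a list of `bn_metrics`, converted
#'   internally).
#' @return List with `hsi` (`bn_layer`) and `weights`.
#' @export
ensemble_hsi <- function(predictions, weights) {
  if (inherits(weights, "bn_metrics") || (is.list(weights) &&
      !inherits(weights, "bn_weights") && !is.data.frame(weights)))
    weights <- ensemble_weights(weights)
  stopifnot(setequal(names(predictions), weights$family))
  g <- check_aligned(predictions[[1]], predictions[[length(predictions)]])
  do.call(check_aligned, unname(predictions))
  acc <- matrix(0, g$n_rows, g$n_cols)
  miss <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(weights))) {
    v <- predictions[[weights$family[i]]]$values
    miss <- miss | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + weights$weight[i] * v
  }
  acc[miss] <- NA
  list(hsi = layer(acc, g, "hsi"), weights = weights)
}

#' Permutation importance of one covariate
#'
#' Repeatedly permutes the covariate's column in the training table,
#' re-predicts, and reports `1 - Pearson correlation` between original
#' and permuted predictions (mean and sd over `reps` permutations).
#' High values mean high importance; a covariate the model does not use
#' yields exactly 0. Constant original predictions are reported as
#' importance 0 with a flag.
#'
#' @param model A `bn_model`.
#' @param table Training table containing `variable`.
#' @param variable Covariate to permute.
#' @param reps Number of permutations (default 10).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `values` (length `reps`) and
#'   `degenerate` flag.
#' @export
permutation_importance <- function(model, table, variable, reps = 10,
                                   seed = 1) {
  if (!variable %in% names(table)) stop("variable not in table: ", variable)
  orig <- predict_table(model, table)
  if (stats::sd(orig) < 1e-12)
    return(list(mean = 0, sd = 0, values = rep(0, reps), degenerate = TRUE))
  vals <- with_seed(stage_seed(seed, paste0("perm-", variable)), {
    vapply(seq_len(reps), function(r) {
      tab <- table
      tab[[variable]] <- sample(tab[[variable]])
      perm <- predict_table(model, tab)
      if (stats::sd(perm) < 1e-12) return(1)
      1 - stats::cor(orig, perm)
    }, numeric(1))
  })
  # identical predictions (unused covariate) must come out exactly 0
  vals[abs(vals) < 1e-14] <- 0
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       degenerate = FALSE)
}

#' Per-family and ensemble variable importance table
#'
#' Runs [permutation_importance()] for every (variable, family) pair and
#' weight-averages across families.
#'
#' @param models Named list of `bn_model` (by family).
#' @param table Training table.
#' @param weights A `bn_weights`.
#' @param variables Variables to score (default: union of model
#'   covariates).
#' @param reps Permutations per pair (default 10).
#' @param seed Integer seed.
#' @return `data.frame`: variable, one mean/sd column pair per family,
#'   and `ensemble` (weighted mean).
#' @export
ensemble_importance <- function(models, table, weights,
                                variables = NULL, reps = 10, seed = 1) {
  if (is.null(variables))
    variables <- Reduce(union, lapply(models, `[[`, "covariates"))
  out <- data.frame(variable = variables)
  ens <- rep(0, length(variables))
  for (fam in names(models)) {
    mns <- numeric(length(variables)); sds <- numeric(length(variables))
    for (i in seq_along(variables)) {
      v <- variables[i]
      if (v %in% models[[fam]]$covariates) {
        imp <- permutation_importance(models[[fam]], table, v, reps,
                                      seed = seed + i)
        mns[i] <- imp$mean; sds[i] <- imp$sd
      } else {
        mns[i] <- 0; sds[i] <- 0 # family does not use the variable
      }
    }
    out[[paste0(fam, "_mean")]] <- mns
    out[[paste0(fam, "_sd")]] <- sds
    w <- weights$weight[weights$family == fam]
    ens <- ens + w * mns
  }
  out$ensemble <- ens
  out
}

#' Bootstrap per-cell uncertainty for one family
#'
#' Refits the family on `B` label-stratified row resamples (with
#' replacement, preserving prevalence), predicts each refit over the
#' stack, and reports the per-cell coefficient of variation
#' (sd / mean) of the `B` HSI estimates. Cells whose bootstrap mean is
#' below `mean_floor` are reported missing.
#'
#' @param family Model family.
#' @param table Training table.
#' @param stack Prediction `bn_stack`.
#' @param covariates Covariates to fit.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param mean_floor Mean-HSI floor below which CV is undefined.
#' @param max_fail_frac Abort if more than this fraction of refits fail.
#' @param fit_args Extra family arguments.
#' @return `bn_layer` of kind `cv`.
#' @export
bootstrap_uncertainty <- function(family, table, stack,
                                  covariates = training_covariates(table),
                                  B = 100, seed = 1, mean_floor = 1e-6,
                                  max_fail_frac = 0.10, fit_args = list()) {
  check_two_labels(table)
  g <- stack$grid
  i1 <- which(table$label == 1); i0 <- which(table$label == 0)
  sum_x <- rep(0, n_cells(g)); sum_x2 <- rep(0, n_cells(g))
  n_ok <- 0L; n_fail <- 0L
  with_seed(stage_seed(seed, paste0("boot-", family)), {
    for (b in seq_len(B)) {
      rows <- c(sample(i1, length(i1), replace = TRUE),
                sample(i0, length(i0), replace = TRUE))
      fit <- try(do.call(fit_sdm, c(list(family, table[rows, , drop = FALSE],
                                         covariates,
                                         seed = sample.int(2^30, 1)),
                                    fit_args)), silent = TRUE)
      if (inherits(fit, "try-error")) { n_fail <- n_fail + 1L; next }
      v <- layer_values(predict_hsi(fit, stack))
      v[is.na(v)] <- 0
      sum_x <- sum_x + v; sum_x2 <- sum_x2 + v^2
      n_ok <- n_ok + 1L
    }
  })
  if (n_fail > max_fail_frac * B)
    stop(sprintf("bootstrap_uncertainty: %d of %d refits failed", n_fail, B))
  mu <- sum_x / n_ok
  varr <- pmax(sum_x2 / n_ok - mu^2, 0) * n_ok / max(1, n_ok - 1)
  cv <- sqrt(varr) / mu
  cv[mu < mean_floor] <- NA
  mask <- is.na(stack$layers[[1]]$values)
  for (l in stack$layers) mask <- mask | is.na(l$values)
  cv[as.vector(mask)] <- NA
  layer(cv, g, "cv")
}

#' Weighted ensemble of per-family uncertainty grids
#'
#' Per-cell weighted mean of the family coefficient-of-variation layers.
#'
#' @param cv_grids Named list of `bn_layer` (kind `cv`) by family.
#' @param weights A `bn_weights`.
#' @return `bn_layer` of kind `cv`.
#' @export
ensemble_uncertainty <- function(cv_grids, weights) {
  stopifnot(setequal(names(cv_grids), weights$family))
  do.call(check_aligned, unname(cv_grids))
  g <- cv_grids[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  miss <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(weights))) {
    v <- cv_grids[[weights$family[i]]]$values
    miss <- miss | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + weights$weight[i] * v
  }
  acc[miss] <- NA
  layer(acc, g, "cv")
}
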