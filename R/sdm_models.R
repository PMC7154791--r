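#' Smooth specification for GAM fits
#'
#' Basis dimension per covariate smooth. The default of 4 knots guards
#' against overfitting; coral models conventionally use 3 for
#' temperature and the saturation states.
#'
#' @param default_k Default basis dimension (>= 3).
#' @param overrides Named list/vector of per-covariate basis dimensions.
#' @return Object of class `bn_smooths`.
#' @export
smooth_spec <- function(default_k = 4,
                        overrides = c(temp = 3, omega_ar = 3, omega_cal = 3)) {
  if (default_k < 3 || any(unlist(overrides) < 3))
    stop("basis dimension must be at least 3")
  structure(list(default_k = default_k, overrides = as.list(overrides)),
            class = "bn_smooths")
}

basis_k <- function(smooths, var) {
  smooths$overrides[[var]] %||% smooths$default_k
}

new_model <- function(family, fit, covariates, extras = list(),
                      table = NULL, seed = NA_integer_) {
  summ <- if (!is.null(table))
    list(n_presence = sum(table$label == 1),
         n_absence = sum(table$label == 0),
         prevalence = sum(table$label == 1) / max(1, sum(table$label == 0)))
  else list()
  structure(c(list(family = family, fit = fit, covariates = covariates,
                   seed = seed, training_summary = summ), extras),
            class = "bn_model")
}

#' @exportS3Method base::print
print.bn_model <- function(x, ...) {
  cat(sprintf("<bn_model:%s> covariates: %s (n1=%s, n0=%s)\n", x$family,
              paste(x$covariates, collapse = ", "),
              x$training_summary$n_presence %||% "?",
              x$training_summary$n_absence %||% "?"))
  invisible(x)
}

check_two_labels <- function(table) {
  if (length(unique(table$label)) < 2)
    stop("training table must contain both presences and pseudo-absences")
}

# -- Maxent-style presence-background model ---------------------------------

maxent_feature_meta <- function(table, covariates, n_hinge = 4) {
  lapply(stats::setNames(covariates, covariates), function(v) {
    x <- table[[v]]
    list(min = min(x), max = max(x), mean = mean(x),
         sd = max(stats::sd(x), 1e-12),
         knots = unique(stats::quantile(x, seq_len(n_hinge) / (n_hinge + 1),
                                        names = FALSE)))
  })
}

maxent_features <- function(meta, table) {
  cols <- list()
  for (v in names(meta)) {
    m <- meta[[v]]
    x <- pmin(pmax(table[[v]], m$min), m$max) # clamp to training range
    z <- (x - m$mean) / m$sd
    cols[[paste0(v, "_lin")]] <- z
    cols[[paste0(v, "_sq")]] <- z^2
    for (i in seq_along(m$knots)) {
      k <- m$knots[i]
      if (m$max > k)
        cols[[paste0(v, "_hf", i)]] <- pmax(0, x - k) / (m$max - k)
      if (k > m$min)
        cols[[paste0(v, "_hr", i)]] <- pmax(0, k - x) / (k - m$min)
    }
  }
  do.call(cbind, cols)
}

#' Fit a maximum-entropy presence-background model
#'
#' An L1-regularised presence-vs-background model over linear, quadratic
#' and hinge transforms of the covariates (lasso path, penalty chosen by
#' internal cross-validation), with the logistic output transform
#' evaluated at the stated prevalence: the habitat suitability index is
#' `tau * exp(eta) / (1 - tau + tau * exp(eta))` with `eta` the fitted
#' feature score centred on the training presences and `tau` the
#' prevalence (by default the ratio of presences to pseudo-absences).
#' Covariates are clamped to their training range at prediction time.
#'
#' @param table Training table with `label` and covariate columns.
#' @param covariates Covariate names (default: every stack covariate in
#'   the table).
#' @param prevalence Logistic prevalence `tau`; default
#'   `n_presence / n_pseudo_absence`, capped at 0.99.
#' @param seed Integer seed (controls the internal lambda selection).
#' @return A `bn_model` (family `"MAXENT"`).
#' @export
fit_maxent <- function(table, covariates = training_covariates(table),
                       prevalence = NULL, seed = 1) {
  check_two_labels(table)
  if (is.null(prevalence))
    prevalence <- sum(table$label == 1) / sum(table$label == 0)
  prevalence <- min(max(prevalence, 1e-6), 0.99)
  meta <- maxent_feature_meta(table, covariates)
  X <- maxent_features(meta, table)
  with_seed(stage_seed(seed, "maxent"), {
    cv <- glmnet::cv.glmnet(X, table$label, family = "binomial",
                            alpha = 1, nfolds = 5)
  })
  beta <- as.vector(stats::coef(cv, s = "lambda.1se"))[-1]
  eta <- as.vector(X %*% beta)
  centre <- mean(eta[table$label == 1])
  new_model("MAXENT", cv, covariates,
            extras = list(feature_meta = meta, beta = beta, centre = centre,
                          prevalence = prevalence),
            table = table, seed = seed)
}

predict_maxent <- function(model, newdata) {
  X <- maxent_features(model$feature_meta, newdata)
  eta <- as.vector(X %*% model$beta) - model$centre
  tau <- model$prevalence
  tau * exp(eta) / (1 - tau + tau * exp(eta))
}

# -- binomial GAM -----------------------------------------------------------

gam_formula <- function(vars, smooths) {
  if (!length(vars)) return(stats::as.formula("label ~ 1"))
  terms <- vapply(vars, function(v)
    sprintf("s(%s, k = %d)", v, basis_k(smooths, v)), "")
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

#' Fit a binomial GAM habitat model
#'
#' Generalized additive model with binomial errors and logit link; one
#' thin-plate smooth per covariate at the basis dimension given by the
#' smooth spec. The covariate subset is chosen by AIC: exhaustively over
#' all subsets (including intercept-only) when there are at most
#' `exhaustive_limit` candidates, otherwise by stepwise
#' forward-backward search.
#'
#' @param table Training table.
#' @param covariates Candidate covariates.
#' @param smooths A `bn_smooths`.
#' @param select Run AIC subset selection (default TRUE); when FALSE all
#'   candidates enter the model.
#' @param exhaustive_limit Max candidates for exhaustive search
#'   (default 8).
#' @param seed Integer seed (kept for contract symmetry; the fit is
#'   deterministic).
#' @return A `bn_model` (family `"GAM"`) with `selected` covariates
#'   recorded.
#' @export
fit_gam <- function(table, covariates = training_covariates(table),
                    smooths = smooth_spec(), select = TRUE,
                    exhaustive_limit = 8, seed = 1) {
  check_two_labels(table)
  dat <- as.data.frame(table)
  fit_subset <- function(vars) {
    mgcv::gam(gam_formula(vars, smooths), family = stats::binomial(),
              data = dat, method = "GCV.Cp")
  }
  if (!select) {
    chosen <- covariates
  } else if (length(covariates) <= exhaustive_limit) {
    subsets <- c(list(character(0)),
                 unlist(lapply(seq_along(covariates), function(k)
                   utils::combn(covariates, k, simplify = FALSE)),
                   recursive = FALSE))
    # candidate fits may be badly mis-specified; their fitting warnings
    # are part of the search, not of the selected model
    aics <- vapply(subsets, function(v)
      suppressWarnings(stats::AIC(fit_subset(v))), numeric(1))
    chosen <- subsets[[which.min(aics)]]
  } else {
    # forward-backward AIC
    chosen <- character(0)
    best <- suppressWarnings(stats::AIC(fit_subset(chosen)))
    repeat {
      moves <- c(lapply(setdiff(covariates, chosen),
                        function(v) union(chosen, v)),
                 lapply(chosen, function(v) setdiff(chosen, v)))
      if (!length(moves)) break
      a <- vapply(moves, function(v)
        suppressWarnings(stats::AIC(fit_subset(v))), numeric(1))
      if (min(a) < best - 1e-9) {
        best <- min(a); chosen <- moves[[which.min(a)]]
      } else break
    }
  }
  fit <- fit_subset(chosen)
  if (!fit$converged) stop("GAM did not converge; inspect the training data")
  new_model("GAM", fit, covariates,
            extras = list(selected = chosen, smooths = smooths),
            table = table, seed = seed)
}

predict_gam <- function(model, newdata) {
  as.vector(stats::predict(model$fit, newdata = as.data.frame(newdata),
                           type = "response"))
}

# -- random forest ----------------------------------------------------------

#' Fit a random-forest habitat model
#'
#' Classification forest on presence vs pseudo-absence; the habitat
#' suitability index is the presence-class vote fraction. Defaults: 500
#' trees, `mtry = floor(sqrt(p))`, no class weighting.
#'
#' @param table Training table.
#' @param covariates Covariate names.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed; the same seed yields identical forests.
#' @return A `bn_model` (family `"RF"`).
#' @export
fit_rf <- function(table, covariates = training_covariates(table),
                   ntree = 500, seed = 1) {
  check_two_labels(table)
  x <- as.data.frame(table[, covariates, drop = FALSE])
  y <- factor(table$label, levels = c(0, 1))
  with_seed(stage_seed(seed, "rf"), {
    fit <- randomForest::randomForest(x, y, ntree = ntree,
                                      mtry = max(1, floor(sqrt(length(covariates)))))
  })
  new_model("RF", fit, covariates, table = table, seed = seed)
}

predict_rf <- function(model, newdata) {
  p <- stats::predict(model$fit,
                      newdata = as.data.frame(newdata[, model$covariates,
                                                      drop = FALSE]),
                      type = "prob")
  as.vector(p[, "1"])
}

#' Fit one of the three model families
#'
#' Uniform dispatcher used by cross-validation, bootstrapping and the
#' pipeline: all families share the `(table, covariates, seed)`
#' contract and return a `bn_model`.
#'
#' @param family `"MAXENT"`, `"GAM"` or `"RF"`.
#' @param table Training table.
#' @param covariates Covariate names.
#' @param seed Integer seed.
#' @param ... Family-specific arguments passed through.
#' @return A `bn_model`.
#' @export
fit_sdm <- function(family, table, covariates = training_covariates(table),
                    seed = 1, ...) {
  switch(toupper(family),
         MAXENT = fit_maxent(table, covariates, seed = seed, ...),
         GAM = fit_gam(table, covariates, seed = seed, ...),
         RF = fit_rf(table, covariates, seed = seed, ...),
         stop("unknown model family: ", family))
}

# covariates available in a training table (everything that is a stack
# covariate, i.e. not bookkeeping columns)
training_covariates <- function(table) {
  setdiff(names(table), c("cell_id", "label", "latitude"))
}

#' Predict habitat suitability for table rows
#'
#' @param model A `bn_model`.
#' @param newdata Data frame holding the model covariates.
#' @return Numeric HSI vector in `[0, 1]`.
#' @export
predict_table <- function(model, newdata) {
  missing <- setdiff(model$covariates, names(newdata))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  out <- switch(model$family,
                MAXENT = predict_maxent(model, newdata),
                GAM = predict_gam(model, newdata),
                RF = predict_rf(model, newdata))
  pmin(pmax(out, 0), 1)
}

#' Predict a habitat-suitability layer over a stack
#'
#' Applies a fitted model to every cell of a layer stack (present-day
#' prediction or future projection: the same operation on the future
#' layers). Cells missing any model covariate get a missing HSI.
#'
#' @param model A `bn_model`.
#' @param stack A `bn_stack` holding all model covariates.
#' @return `bn_layer` of kind `hsi`.
#' @export
predict_hsi <- function(model, stack) {
  missing <- setdiff(model$covariates, names(stack$layers))
  if (length(missing))
    stop("stack lacks covariate layer(s): ", paste(missing, collapse = ", "))
  g <- stack$grid
  cells <- seq_len(n_cells(g))
  tab <- extract_cells(stack, cells, model$covariates)
  ok <- stats::complete.cases(tab[, model$covariates, drop = FALSE])
  out <- rep(NA_real_, n_cells(g))
  if (any(ok))
    out[ok] <- predict_table(model, tab[ok, , drop = FALSE])
  layer(out, g, "hsi")
}

#' Save a fitted model with a JSON metadata sidecar
#'
#' @param model A `bn_model`.
#' @param path Destination file; a `<path>.json` sidecar records family,
#'   covariates, seed and training summary.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(family = model$family, covariates = model$covariates,
               seed = model$seed, training_summary = model$training_summary)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted model saved by [save_model()]
#' @param path Model file path.
#' @return A `bn_model` predicting identically to the saved one.
#' @export
load_model <- function(path) readRDS(path)
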