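#' Environmental-profiling background mask
#'
#' Delimits the region available for pseudo-absence generation by
#' profiling the presence environments: a per-covariate quantile box
#' (default the central 95%, i.e. the 2.5th-97.5th percentiles of
#' presence covariate values) describes the environmental envelope of
#' the presences, standing in for a one-class support estimate of the
#' presence environmental domain.
#'
#' In the default `mode = "exclude"` the eligible region is the ocean
#' *outside* that envelope — cells environmentally dissimilar to the
#' presences, where artificial absences are defensible. `mode =
#' "include"` restricts eligibility to the envelope instead (background
#' environmentally matched to the presences); in that mode the presence
#' cells themselves are always eligible, so the mask covers the presence
#' environments in full.
#'
#' @param presences A `bn_presences` (>= 20 presence cells).
#' @param stack A `bn_stack` of candidate covariates.
#' @param vars Covariates defining the profile (default: all non-depth
#'   stack layers present).
#' @param probs Lower/upper quantile bounds of the envelope box.
#' @param mode `"exclude"` (default; eligible = outside the presence
#'   envelope) or `"include"` (eligible = inside it).
#' @return Object of class `bn_bgmask`: list with `grid`, logical
#'   `eligible` matrix, the profile `bounds`, and `mode`.
#' @export
env_profile_mask <- function(presences, stack,
                             vars = setdiff(names(stack$layers), "depth"),
                             probs = c(0.025, 0.975),
                             mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  if (presences$n_cells < 20)
    stop("environmental profiling needs at least 20 presence cells")
  g <- stack$grid
  ocean <- stack_mask(stack)
  inside <- ocean
  bounds <- list()
  for (v in vars) {
    vals <- stack$layers[[v]]$values
    pv <- vals[presences$cells]
    q <- stats::quantile(pv, probs, na.rm = TRUE, names = FALSE)
    bounds[[v]] <- q
    inside <- inside & !is.na(vals) & vals >= q[1] & vals <= q[2]
  }
  if (mode == "include") {
    eligible <- inside
    eligible[presences$cells] <- TRUE
  } else {
    eligible <- ocean & !inside
  }
  structure(list(grid = g, eligible = eligible, bounds = bounds,
                 mode = mode),
            class = "bn_bgmask")
}

#' Sample background candidate cells
#'
#' Draws `n` distinct cells uniformly from the profile mask, excluding
#' every cell whose centre lies within `buffer_m` (planar distance) of a
#' presence cell centre.
#'
#' @param mask A `bn_bgmask`.
#' @param presences A `bn_presences`.
#' @param n Number of cells to draw; `NULL` returns the whole eligible
#'   (post-buffer) set.
#' @param buffer_m Exclusion buffer around presences in metres
#'   (default 6000).
#' @param seed Integer seed.
#' @return Integer vector of `n` distinct cell ids.
#' @export
sample_background <- function(mask, presences, n = NULL, buffer_m = 6000,
                              seed = 1) {
  g <- mask$grid
  eligible <- mask$eligible
  # knock out the buffer: all cells within ceil(buffer/cell) rings whose
  # centre distance is within buffer_m
  reach <- ceiling(buffer_m / g$cell_size)
  offs <- expand.grid(dr = -reach:reach, dc = -reach:reach)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * g$cell_size <= buffer_m, ]
  p <- cell_xy(g, presences$cells)
  for (k in seq_len(nrow(offs))) {
    rr <- p$row + offs$dr[k]; cc <- p$col + offs$dc[k]
    okk <- rr >= 1 & rr <= g$n_rows & cc >= 1 & cc <= g$n_cols
    eligible[cbind(rr[okk], cc[okk])] <- FALSE
  }
  pool <- which(eligible)
  if (is.null(n)) return(pool)
  if (length(pool) < n)
    stop(sprintf("only %d eligible background cells after buffering; %d requested (shortfall %d)",
                 length(pool), n, n - length(pool)))
  with_seed(stage_seed(seed, "background"), {
    if (length(pool) == n) pool else sort(sample(pool, n))
  })
}

#' Depth-stratified subsampling of background candidates
#'
#' Subsamples candidate cells so that their depth distribution matches
#' the presence depth distribution across strata: per-stratum targets
#' are `n_target` times the presence proportion, integerised by the
#' largest-remainder rule so the total is exact; sampling within a
#' stratum is uniform without replacement.
#'
#' @param candidates Integer cell ids (from [sample_background()]).
#' @param candidate_depths Depth (m) per candidate cell.
#' @param presence_depths Depths of the presence cells.
#' @param strata_edges Stratum boundaries in metres; default 250-m bins
#'   spanning the occupied range.
#' @param n_target Total pseudo-absences wanted (coral default 10000,
#'   fish 100000).
#' @param seed Integer seed.
#' @return Integer vector of `n_target` cell ids.
#' @export
depth_stratified_subsample <- function(candidates, candidate_depths,
                                       presence_depths,
                                       strata_edges = NULL,
                                       n_target, strata_width = 250,
                                       seed = 1) {
  if (is.null(strata_edges)) {
    # 250-m bins over the central occupied range, with open tails so the
    # rare shallowest/deepest presences share a stratum with candidates
    qd <- stats::quantile(presence_depths, c(0.10, 0.90), names = FALSE)
    lo <- floor(qd[1] / strata_width) * strata_width
    hi <- ceiling(qd[2] / strata_width) * strata_width
    if (hi <= lo) hi <- lo + strata_width
    strata_edges <- c(-Inf, seq(lo, hi, by = strata_width), Inf)
  }
  pres_bin <- cut(presence_depths, strata_edges, include.lowest = TRUE)
  cand_bin <- cut(candidate_depths, strata_edges, include.lowest = TRUE)
  prop <- as.vector(table(pres_bin)) / length(presence_depths)
  # largest-remainder integerisation
  raw <- n_target * prop
  base <- floor(raw)
  rem <- n_target - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  avail <- as.vector(table(cand_bin))
  short <- which(base > avail)
  if (length(short))
    stop("insufficient background candidates in depth strata: ",
         paste(sprintf("%s (need %d, have %d)",
                       levels(pres_bin)[short], base[short], avail[short]),
               collapse = "; "))
  with_seed(stage_seed(seed, "strata"), {
    out <- integer(0)
    for (s in seq_along(base)) {
      if (base[s] == 0) next
      pool <- candidates[which(as.integer(cand_bin) == s)]
      out <- c(out, if (length(pool) == base[s]) pool
               else sample(pool, base[s]))
    }
    sort(out)
  })
}

#' Generate pseudo-absences for a presence set
#'
#' Full chain: environmental profiling, buffered background sampling and
#' depth-stratified subsampling. The candidate draw is oversampled
#' (bounded by the eligible pool) so each stratum can be filled.
#'
#' @param presences A `bn_presences`.
#' @param stack Predictor `bn_stack` (must include depth).
#' @param n_target Pseudo-absence count (coral default 10000).
#' @param buffer_m Presence exclusion buffer (m).
#' @param strata_edges Optional depth stratum boundaries (m).
#' @param strata_width Stratum width (m) for the default boundaries.
#' @param profile_mode Profile semantics passed to [env_profile_mask()]
#'   (default "exclude").
#' @param profile_vars Covariates defining the environmental profile
#'   (default: the candidate predictors, i.e. all stack layers except
#'   depth and the raw carbonate-chemistry intermediates).
#' @param oversample Candidate pool multiplier before stratification
#'   (default: use the whole eligible pool).
#' @param seed Integer seed.
#' @return Integer vector of pseudo-absence cell ids.
#' @export
generate_pseudo_absences <- function(presences, stack, n_target = 10000,
                                     buffer_m = 6000, strata_edges = NULL,
                                     strata_width = 250,
                                     profile_vars = NULL,
                                     profile_mode = "exclude",
                                     oversample = Inf, seed = 1) {
  if (is.null(profile_vars))
    profile_vars <- setdiff(names(stack$layers),
                            c("depth", "co3", "co3_sat_ar", "co3_sat_cal"))
  mask <- env_profile_mask(presences, stack, vars = profile_vars,
                           mode = profile_mode)
  pool <- sample_background(mask, presences, n = NULL,
                            buffer_m = buffer_m, seed = seed)
  if (length(pool) < n_target)
    stop(sprintf("only %d eligible background cells after buffering; %d requested (shortfall %d)",
                 length(pool), n_target, n_target - length(pool)))
  n_cand <- min(length(pool), ceiling(oversample * n_target))
  cand <- sample_background(mask, presences, n = n_cand,
                            buffer_m = buffer_m, seed = seed)
  depth_v <- stack$layers$depth$values
  depth_stratified_subsample(cand, depth_v[cand], depth_v[presences$cells],
                             strata_edges, n_target,
                             strata_width = strata_width, seed = seed)
}

#' Assemble the model training table
#'
#' One row per presence (label 1) and pseudo-absence (label 0) cell with
#' extracted covariate values, depth and latitude. Rows with any missing
#' covariate are dropped with a message reporting the count.
#'
#' @param presences A `bn_presences`.
#' @param pseudo_absences Integer cell ids, disjoint from the presences.
#' @param stack Predictor `bn_stack`.
#' @param vars Covariates to extract (default all layers).
#' @return `data.frame` with columns cell_id, label, the covariates,
#'   and latitude (class `bn_training` prepended).
#' @export
assemble_training <- function(presences, pseudo_absences, stack,
                              vars = names(stack$layers)) {
  if (length(intersect(presences$cells, pseudo_absences)))
    stop("presence and pseudo-absence cells overlap")
  g <- stack$grid
  cells <- c(presences$cells, pseudo_absences)
  tab <- extract_cells(stack, cells, vars)
  tab$label <- rep(c(1L, 0L), c(presences$n_cells, length(pseudo_absences)))
  tab$latitude <- row_latitude(g, cell_xy(g, cells)$row)
  complete <- stats::complete.cases(tab[, vars, drop = FALSE])
  if (any(!complete))
    message(sprintf("assemble_training: dropped %d rows with missing covariates",
                    sum(!complete)))
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bn_training", class(out))
  out
}
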