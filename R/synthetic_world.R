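#' Niche specification
#'
#' Ground-truth environmental response of a simulated species: a product
#' of per-covariate response functions scaled by a maximum prevalence.
#' Supported shapes are `gaussian` (optimum + breadth = one standard
#' deviation), `increasing-sigmoid` and `decreasing-sigmoid` (inflection
#' point + breadth = logistic scale parameter).
#'
#' @param responses List of lists with fields `covariate`, `shape`,
#'   `optimum` (or inflection), `breadth` (> 0).
#' @param max_prevalence Suitability at the joint optimum, in (0, 1].
#' @return Object of class `bn_niche`.
#' @export
niche_spec <- function(responses, max_prevalence = 0.9) {
  if (length(responses) < 1) stop("at least one response is required")
  shapes <- c("gaussian", "increasing-sigmoid", "decreasing-sigmoid")
  for (r in responses) {
    stopifnot(!is.null(r$covariate), !is.null(r$optimum), !is.null(r$breadth))
    if (!(r$shape %in% shapes)) stop("unknown response shape: ", r$shape)
    if (r$breadth <= 0) stop("breadth must be positive")
  }
  if (max_prevalence <= 0 || max_prevalence > 1)
    stop("max_prevalence must lie in (0, 1]")
  structure(list(responses = responses, max_prevalence = max_prevalence),
            class = "bn_niche")
}

#' Future-scenario covariate transform
#'
#' Per-covariate affine transform `new = value * factor + offset` applied
#' to ocean cells only. The default emulates a high-emissions end-of-century
#' signal at the seafloor: warming, carbonate-ion (hence saturation-state)
#' decline that shoals the saturation horizons, a decline in export
#' production of about half, and deoxygenation.
#'
#' @param deltas Named list (by covariate) of lists with `offset` and/or
#'   `factor`; `offset` may be a function of depth (m) for depth-dependent
#'   change.
#' @return Object of class `bn_scenario`.
#' @export
scenario_delta <- function(deltas = default_rcp85_delta()) {
  for (d in deltas) {
    if (!is.null(d$factor) && any(d$factor < 0))
      stop("multiplicative factors must be >= 0")
  }
  structure(list(deltas = deltas), class = "bn_scenario")
}

#' Default high-emissions scenario delta
#'
#' Seafloor warming of +2 degC tapering with depth, a 25% drop in
#' carbonate ion concentration (shoaling both saturation horizons), a 45%
#' decline in export POC (midpoint of the 40%-55% range projected for
#' business-as-usual forcing), and a 15 umol/kg oxygen decline.
#'
#' @return Named list of per-covariate transforms.
#' @export
default_rcp85_delta <- function() {
  list(
    temp = list(offset = function(depth) 2.0 * exp(-depth / 1500)),
    co3 = list(factor = 0.75),
    omega_ar = list(factor = 0.75),
    omega_cal = list(factor = 0.75),
    epc100 = list(factor = 0.55),
    DO = list(offset = -15)
  )
}

#' Occurrence-corruption specification
#'
#' Rates and magnitudes of the data-quality defects injected into
#' simulated occurrence records so that the quality-control filters have
#' realistic targets: records with missing depth, records whose reported
#' depth disagrees with the bathymetry, and coarse-position records.
#' The three corrupted subsets are disjoint, so the fractions must sum
#' to less than 1.
#'
#' @param frac_missing_depth,frac_depth_mismatch,frac_coarse_position
#'   Fractions of records in `[0, 1)`.
#' @param mismatch_rel,mismatch_abs Relative and absolute magnitude of
#'   injected depth errors (both applied, so errors exceed both QC
#'   tolerances).
#' @param coarse_accuracy_m Position accuracy (m of error) assigned to
#'   coarse records.
#' @return Object of class `bn_corruption`.
#' @export
corruption_spec <- function(frac_missing_depth = 0,
                            frac_depth_mismatch = 0,
                            frac_coarse_position = 0,
                            mismatch_rel = 0.5, mismatch_abs = 100,
                            coarse_accuracy_m = 10000) {
  f <- c(frac_missing_depth, frac_depth_mismatch, frac_coarse_position)
  if (any(f < 0) || any(f >= 1) || sum(f) >= 1)
    stop("corruption fractions must lie in [0, 1) and sum below 1")
  structure(list(frac_missing_depth = frac_missing_depth,
                 frac_depth_mismatch = frac_depth_mismatch,
                 frac_coarse_position = frac_coarse_position,
                 mismatch_rel = mismatch_rel, mismatch_abs = mismatch_abs,
                 coarse_accuracy_m = coarse_accuracy_m),
            class = "bn_corruption")
}

#' Generate a synthetic ocean
#'
#' Builds a seeded bathymetry with shelf, slope and abyssal structure and
#' a stack of spatially autocorrelated seafloor covariates coupled to
#' depth: bottom temperature (decreasing with depth), export POC flux at
#' 100 m, carbonate ion concentration and the derived aragonite/calcite
#' saturation states (each crossing 1 inside the domain), and dissolved
#' oxygen with a mid-depth minimum. A coastal strip of land cells gives
#' the grid a mask; all covariates are `NA` on land.
#'
#' Couplings are parametric in depth with additive smooth-field noise, so
#' collinearity screening downstream sees realistic structure (depth and
#' the saturation states are strongly rank-correlated by construction).
#'
#' @param grid A `bn_grid`.
#' @param seed Integer seed; output is a pure function of (grid, seed).
#' @param noise_sigma_cells Gaussian kernel width (cells) of the random
#'   fields.
#' @return List with elements `depth` (a `bn_layer`) and `stack`
#'   (a `bn_stack` holding depth, temp, epc100, co3, co3_sat_ar,
#'   co3_sat_cal, omega_ar, omega_cal, DO).
#' @export
build_world <- function(grid, seed, noise_sigma_cells = 6) {
  stopifnot(inherits(grid, "bn_grid"))
  nr <- grid$n_rows; nc <- grid$n_cols
  if (nc < 20)
    stop("grid too small to contain shelf, slope and abyss depth zones")
  with_seed(stage_seed(seed, "world"), {
    # Margin profile across columns: land strip, shelf (<200 m),
    # slope, abyssal plain (>2000 m).
    frac <- (seq_len(nc) - 0.5) / nc
    base <- ifelse(frac < 0.05, -50,                       # land
            ifelse(frac < 0.20, 30 + (frac - 0.05) / 0.15 * 170,   # shelf
            ifelse(frac < 0.50, 200 + (frac - 0.20) / 0.30 * 2300, # slope
                   2500 + (frac - 0.50) / 0.50 * 1800)))   # abyss
    depth_m <- matrix(rep(base, each = nr), nr, nc)
    relief <- smooth_field(nr, nc, noise_sigma_cells)
    depth_m <- depth_m * (1 + 0.12 * relief) + 120 * smooth_field(nr, nc, 2)
    land <- depth_m < 10
    if (mean(!land) < 0.6)
      stop("grid too small: ocean mask below 60% of cells")
    depth_m[land] <- NA
    d <- depth_m
    lat <- matrix(rep(row_latitude(grid), nc), nr, nc)

    latfrac <- (lat - grid$lat_min) /
      max(1e-9, abs(grid$lat_max - grid$lat_min))

    # Bottom temperature: warm shallow water, cold abyss, poleward
    # cooling. The latitudinal gradient and mesoscale noise give real
    # within-depth-band variation (as water masses do), keeping the
    # depth coupling moderate rather than deterministic.
    temp <- 13 * exp(-d / 900) + 2 - 6 * latfrac +
      1.8 * smooth_field(nr, nc, noise_sigma_cells)

    # Export POC flux at 100 m: productivity higher over the shelf and
    # at high latitude, with strong regional patchiness; positive.
    epc100 <- exp(log(15) - d / 6000 + 0.8 * latfrac +
                    0.7 * smooth_field(nr, nc, noise_sigma_cells))

    # Saturation states decline with depth; aragonite horizon ~1500 m,
    # calcite ~3000 m. Carbonate ion is reconstructed from omega and an
    # equilibrium concentration increasing with pressure.
    om_noise <- 0.05 * smooth_field(nr, nc, noise_sigma_cells)
    omega_ar <- pmax(0.05, 3.2 * exp(-d / 1300) * (1 + om_noise))
    omega_cal <- pmax(0.08, 4.8 * exp(-d / 1900) * (1 + om_noise))
    co3_sat_ar <- 0.066 * (1 + d / 4000)   # mol m-3, equilibrium with aragonite
    co3_sat_cal <- co3_sat_ar * omega_ar / omega_cal
    co3 <- omega_ar * co3_sat_ar

    # Dissolved oxygen: ventilated surface and deep water with an oxygen
    # minimum zone centred near 800 m; better-ventilated high latitudes.
    DO <- 290 - 150 * exp(-((d - 800) / 700)^2) + 25 * latfrac +
      15 * smooth_field(nr, nc, noise_sigma_cells)

    mk <- function(v, kind) {
      v[land] <- NA
      layer(v, grid, kind)
    }
    depth_layer <- mk(depth_m, "depth")
    stack <- layer_stack(list(
      depth = depth_layer,
      temp = mk(temp, "temp"),
      epc100 = mk(epc100, "epc100"),
      co3 = mk(co3, "co3"),
      co3_sat_ar = mk(co3_sat_ar, "co3_sat_ar"),
      co3_sat_cal = mk(co3_sat_cal, "co3_sat_cal"),
      omega_ar = mk(omega_ar, "omega_ar"),
      omega_cal = mk(omega_cal, "omega_cal"),
      DO = mk(DO, "DO")))
    ocean <- !is.na(depth_m)
    dd <- depth_m[ocean]
    if (min(dd) >= 200 || max(dd) <= 2000)
      stop("grid too small to contain shelf, slope and abyss depth zones")
    list(depth = depth_layer, stack = stack)
  })
}

#' Apply a future scenario to a layer stack
#'
#' Transforms each named covariate by `value * factor + offset` on ocean
#' cells; land/masked cells and covariates without a delta are untouched
#' (bit-identical). Depth-dependent offsets receive the stack's depth
#' layer.
#'
#' @param stack A `bn_stack` containing a `depth` layer.
#' @param delta A `bn_scenario`.
#' @return The future `bn_stack` on the same grid.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "bn_stack"), inherits(delta, "bn_scenario"))
  unknown <- setdiff(names(delta$deltas), names(stack$layers))
  if (length(unknown))
    stop("scenario names unknown covariates: ", paste(unknown, collapse = ", "))
  depth_v <- stack$layers$depth$values
  for (nm in names(delta$deltas)) {
    d <- delta$deltas[[nm]]
    lyr <- stack$layers[[nm]]
    v <- lyr$values
    ocean <- !is.na(v)
    fac <- d$factor %||% 1
    off <- d$offset %||% 0
    if (is.function(off)) off <- off(depth_v[ocean]) else off <- rep(off, sum(ocean))
    v[ocean] <- v[ocean] * fac + off
    lyr$values <- v
    stack$layers[[nm]] <- lyr
  }
  stack
}

eval_response <- function(r, x) {
  switch(r$shape,
         "gaussian" = exp(-0.5 * ((x - r$optimum) / r$breadth)^2),
         "increasing-sigmoid" = stats::plogis((x - r$optimum) / r$breadth),
         "decreasing-sigmoid" = stats::plogis(-(x - r$optimum) / r$breadth))
}

#' Ground-truth suitability of a niche over a stack
#'
#' Product of the per-covariate response functions times the maximum
#' prevalence; the recovery oracle for all downstream model testing.
#'
#' @param stack A `bn_stack`.
#' @param niche A `bn_niche` whose covariates are all present in `stack`.
#' @return `bn_layer` of kind `hsi` with values in `[0, max_prevalence]`.
#' @export
oracle_suitability <- function(stack, niche) {
  stopifnot(inherits(niche, "bn_niche"))
  covs <- vapply(niche$responses, `[[`, "", "covariate")
  missing <- setdiff(covs, names(stack$layers))
  if (length(missing))
    stop("niche covariates absent from stack: ",
         paste(missing, collapse = ", "))
  g <- stack$grid
  suit <- matrix(niche$max_prevalence, g$n_rows, g$n_cols)
  for (r in niche$responses)
    suit <- suit * eval_response(r, stack$layers[[r$covariate]]$values)
  layer(suit, g, "hsi")
}

#' Simulate occurrence records from a known niche
#'
#' Samples `n_target` distinct presence cells with probability
#' proportional to the oracle suitability (one presence per cell), then
#' emits occurrence records with planar and geographic coordinates,
#' reported depth, position accuracy and a source tag, applying the
#' corruption spec: `round(frac * n)` records each get a missing depth
#' (source forced to OBIS), a depth error exceeding both QC tolerances
#' (source OBIS/NOAA), or a coarse position (source ICES_VME). Clean
#' records draw sources from institutional/OBIS/NOAA/ICES with accurate
#' values.
#'
#' @param stack Present-day `bn_stack` (must include depth).
#' @param niche A `bn_niche`.
#' @param n_target Number of presence cells (>= 1).
#' @param corruption A `bn_corruption`.
#' @param seed Integer seed.
#' @param species Species identifier attached to every record.
#' @return `data.frame` with columns species, cell_id, x, y, lon, lat,
#'   reported_depth_m, position_accuracy_m, source.
#' @export
simulate_occurrences <- function(stack, niche, n_target,
                                 corruption = corruption_spec(),
                                 seed = 1, species = "synthetic_taxon") {
  stopifnot(n_target >= 1)
  suit <- oracle_suitability(stack, niche)$values
  cells <- which(!is.na(suit) & suit > 0)
  if (length(cells) < n_target)
    stop(sprintf("n_target (%d) exceeds the %d cells with positive suitability",
                 n_target, length(cells)))
  g <- stack$grid
  with_seed(stage_seed(seed, "occurrences"), {
    take <- sample(cells, n_target, prob = suit[cells])
    xy <- cell_xy(g, take)
    depth_true <- stack$layers$depth$values[take]
    n <- n_target
    rec <- data.frame(
      species = species, cell_id = take,
      x = xy$x + stats::runif(n, -0.3, 0.3) * g$cell_size,
      y = xy$y + stats::runif(n, -0.3, 0.3) * g$cell_size,
      lon = -60 + xy$x / 1e5,
      lat = row_latitude(g, xy$row),
      reported_depth_m = depth_true * (1 + stats::rnorm(n, 0, 0.02)),
      position_accuracy_m = stats::runif(n, 50, 3000),
      source = sample(c("institutional", "OBIS", "NOAA", "ICES_VME"),
                      n, replace = TRUE),
      stringsAsFactors = FALSE)

    n_miss <- round(corruption$frac_missing_depth * n)
    n_bad <- round(corruption$frac_depth_mismatch * n)
    n_coarse <- round(corruption$frac_coarse_position * n)
    idx <- sample.int(n, n_miss + n_bad + n_coarse)
    i_miss <- idx[seq_len(n_miss)]
    i_bad <- idx[n_miss + seq_len(n_bad)]
    i_coarse <- idx[n_miss + n_bad + seq_len(n_coarse)]
    if (n_miss) {
      rec$reported_depth_m[i_miss] <- NA
      rec$source[i_miss] <- "OBIS"
    }
    if (n_bad) {
      err <- pmax(corruption$mismatch_rel * depth_true[i_bad],
                  corruption$mismatch_abs) + 1
      rec$reported_depth_m[i_bad] <- depth_true[i_bad] +
        sample(c(-1, 1), n_bad, replace = TRUE) * err
      rec$source[i_bad] <- sample(c("OBIS", "NOAA"), n_bad, replace = TRUE)
    }
    if (n_coarse) {
      rec$position_accuracy_m[i_coarse] <- corruption$coarse_accuracy_m
      rec$source[i_coarse] <- "ICES_VME"
    }
    # uncorrupted ICES records stay within the accuracy bound
    clean_ices <- setdiff(which(rec$source == "ICES_VME"), i_coarse)
    rec$position_accuracy_m[clean_ices] <-
      pmin(rec$position_accuracy_m[clean_ices], 4500)
    rec
  })
}

#' Write occurrence records as CSV
#'
#' @param records Data frame from [simulate_occurrences()] (or the QC
#'   filters).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV
#' @param path CSV with the occurrence column layout.
#' @return `data.frame` of records.
#' @export
read_occurrences_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
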