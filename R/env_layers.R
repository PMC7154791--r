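#' Martin-curve parameters
#'
#' @param export_depth Export depth in metres (> 0), default 100.
#' @param exponent Attenuation exponent, default -0.858.
#' @return Object of class `bn_martin`.
#' @export
martin_params <- function(export_depth = 100, exponent = -0.858) {
  if (export_depth <= 0) stop("export_depth must be positive")
  structure(list(export_depth = export_depth, exponent = exponent),
            class = "bn_martin")
}

#' Terrain (BPI) parameters
#'
#' @param bpi_inner_radius,bpi_outer_radius Annulus radii in cells,
#'   defaults 3 and 25; `0 < inner < outer`.
#' @return Object of class `bn_terrain`.
#' @export
terrain_params <- function(bpi_inner_radius = 3, bpi_outer_radius = 25) {
  if (!(bpi_inner_radius > 0 && bpi_inner_radius < bpi_outer_radius))
    stop("require 0 < inner radius < outer radius")
  structure(list(inner = as.integer(bpi_inner_radius),
                 outer = as.integer(bpi_outer_radius)),
            class = "bn_terrain")
}

#' POC flux at the seafloor via the Martin curve
#'
#' Attenuates export POC flux at the export depth down to the seafloor:
#' `poc = epc100 * (depth / export_depth) ^ exponent`. Cells shallower
#' than the export depth are evaluated by the same power law (flux above
#' the export value); missing cells propagate.
#'
#' @param epc100 Export-POC layer (mg C m-2 day-1).
#' @param depth Bathymetry layer (m, positive down).
#' @param params A `bn_martin`.
#' @return `bn_layer` of kind `poc_seafloor`.
#' @export
martin_poc <- function(epc100, depth, params = martin_params()) {
  check_aligned(epc100, depth)
  d <- depth$values; e <- epc100$values
  mask <- !is.na(d) & !is.na(e)
  if (any(d[mask] <= 0))
    stop("depth must be positive on the ocean mask")
  out <- e * (d / params$export_depth)^params$exponent
  out[!mask] <- NA
  layer(out, depth$grid, "poc_seafloor", units = epc100$units)
}

#' Carbonate saturation state
#'
#' Ratio of the bottom-water carbonate ion concentration to the
#' concentration at equilibrium with the mineral phase; `omega = 1`
#' marks the saturation horizon and `omega < 1` is corrosive.
#'
#' @param co3 Carbonate ion concentration layer (mol m-3).
#' @param co3_eq Equilibrium concentration layer (mol m-3, > 0).
#' @param kind Output kind, `omega_ar` or `omega_cal`.
#' @return `bn_layer` of the requested kind.
#' @export
saturation_state <- function(co3, co3_eq, kind = "omega_ar") {
  check_aligned(co3, co3_eq)
  mask <- !is.na(co3$values) & !is.na(co3_eq$values)
  if (any(co3_eq$values[mask] <= 0))
    stop("equilibrium carbonate concentration must be positive")
  out <- co3$values / co3_eq$values
  out[!mask] <- NA
  layer(out, co3$grid, kind)
}

#' Seafloor slope in degrees
#'
#' Horn 3x3 finite-difference gradient of the bathymetry, the standard
#' GIS stencil. Edge cells use replicated-edge padding. Adding a
#' constant to the depth field leaves slope unchanged.
#'
#' @param depth Bathymetry layer (m).
#' @return `bn_layer` of kind `slope` with values in `[0, 90)`.
#' @export
slope <- function(depth) {
  g <- depth$grid
  z <- depth$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad so border cells get a defined (one-sided) gradient
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  # fill NA in the pad with the centre value so coastal cells don't
  # inherit land as missing; their slope uses available neighbours only
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  sh <- function(dr, dc) {
    m <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    ifelse(is.na(m), ctr, m)
  }
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  e <- sh(0, 1)
  f <- sh(1, -1);  gg <- sh(1, 0); h <- sh(1, 1)
  dzdx <- ((cc + 2 * e + h) - (a + 2 * d + f)) / (8 * g$cell_size)
  dzdy <- ((f + 2 * gg + h) - (a + 2 * b + cc)) / (8 * g$cell_size)
  sl <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  sl[is.na(z)] <- NA
  layer(sl, g, "slope")
}

#' Standardized bathymetric position index
#'
#' Raw BPI is the elevation (-depth) of a cell minus the mean elevation
#' over a surrounding annulus between the inner and outer radius
#' (positive = crest, negative = depression, Benthic Terrain Modeler
#' convention); the result is z-scored over the ocean mask. Edge cells
#' use the annulus truncated at the grid border.
#'
#' @param depth Bathymetry layer (m).
#' @param params A `bn_terrain`.
#' @return `bn_layer` of kind `bpi` (mean 0, sd 1 on the mask).
#' @export
bpi <- function(depth, params = terrain_params()) {
  g <- depth$grid
  if (params$outer >= min(g$n_rows, g$n_cols) / 2)
    stop("outer radius must be below half the smaller grid dimension")
  elev <- -depth$values
  nr <- nrow(elev); nc <- ncol(elev)
  # annulus mean via two box/disc sums over an NA-aware summed-area table
  disc_sum <- function(m, r) {
    ok <- !is.na(m)
    mv <- m; mv[!ok] <- 0
    # offsets of the disc of radius r (chebyshev-euclidean hybrid: use
    # euclidean distance in cells, the BTM convention)
    offs <- expand.grid(dr = -r:r, dc = -r:r)
    offs <- offs[sqrt(offs$dr^2 + offs$dc^2) <= r + 1e-9, ]
    s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]; dc <- offs$dc[k]
      rs <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      s[rs, cs] <- s[rs, cs] + mv[rs + dr, cs + dc]
      cnt[rs, cs] <- cnt[rs, cs] + ok[rs + dr, cs + dc]
    }
    list(sum = s, count = cnt)
  }
  outer_d <- disc_sum(elev, params$outer)
  inner_d <- disc_sum(elev, params$inner)
  ann_sum <- outer_d$sum - inner_d$sum
  ann_cnt <- outer_d$count - inner_d$count
  raw <- elev - ann_sum / pmax(ann_cnt, 1)
  raw[is.na(elev) | ann_cnt == 0] <- NA
  v <- raw[!is.na(raw)]
  if (stats::sd(v) < 1e-12)
    stop("raw BPI has zero variance; cannot standardize a flat field")
  std <- (raw - mean(v)) / stats::sd(v)
  layer(std, g, "bpi")
}

# -- downscaling ------------------------------------------------------------

fit_exp_variogram <- function(h, gamma) {
  # exponential model gamma(h) = sill * (1 - exp(-h / range)), nugget 0
  init <- c(sill = max(gamma), range = max(h) / 3)
  fit <- try(stats::optim(
    log(init),
    function(p) {
      s <- exp(p[1]); r <- exp(p[2])
      sum((gamma - s * (1 - exp(-h / r)))^2)
    }), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  list(sill = exp(fit$par[1]), range = exp(fit$par[2]))
}

#' Downscale a coarse field to the model grid
#'
#' Universal-kriging-style downscaling: a linear drift on depth is fitted
#' to the coarse samples, and the residuals are interpolated by ordinary
#' kriging with an exponential variogram (nugget 0), making the result an
#' exact interpolator at the sample locations. If the variogram fit
#' fails or is degenerate, the residuals fall back to inverse-distance
#' weighting (logged via a message).
#'
#' @param coarse `data.frame` with columns `x`, `y` (m, in the fine
#'   grid's frame) and `value`; at least 10 samples.
#' @param depth Fine-grid bathymetry layer, the drift covariate.
#' @param kind Output layer kind.
#' @param use_drift Include the depth drift (default TRUE).
#' @param seed Unused randomness hook kept for interface stability.
#' @return `bn_layer` on `depth`'s grid.
#' @export
downscale <- function(coarse, depth, kind = "other", use_drift = TRUE,
                      seed = 1) {
  stopifnot(all(c("x", "y", "value") %in% names(coarse)))
  if (nrow(coarse) < 10) stop("need at least 10 coarse samples")
  g <- depth$grid
  cells <- xy_cell(g, coarse$x, coarse$y)
  if (anyNA(cells)) stop("coarse samples must fall inside the fine grid extent")
  dsamp <- depth$values[cells]
  keep <- !is.na(dsamp)
  coarse <- coarse[keep, ]; cells <- cells[keep]; dsamp <- dsamp[keep]
  if (nrow(coarse) < 10) stop("need at least 10 coarse samples on the ocean mask")

  if (use_drift) {
    drift <- stats::lm(value ~ depth_m, data.frame(value = coarse$value,
                                                   depth_m = dsamp))
    resid <- stats::residuals(drift)
  } else {
    drift <- NULL
    resid <- coarse$value - mean(coarse$value)
  }

  xs <- coarse$x; ys <- coarse$y
  n <- length(resid)
  D <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)

  # empirical semivariogram of the residuals
  iu <- which(upper.tri(D), arr.ind = TRUE)
  hh <- D[iu]
  gg <- 0.5 * (resid[iu[, 1]] - resid[iu[, 2]])^2
  brks <- seq(0, max(hh), length.out = 16)
  bin <- cut(hh, brks, include.lowest = TRUE)
  emp_h <- tapply(hh, bin, mean)
  emp_g <- tapply(gg, bin, mean)
  okb <- is.finite(emp_h) & is.finite(emp_g)
  vg <- if (sum(okb) >= 4 && stats::var(resid) > 1e-12)
    fit_exp_variogram(emp_h[okb], emp_g[okb]) else NULL

  mask_cells <- which(!is.na(depth$values))
  xy <- cell_xy(g, mask_cells)
  pred_resid <- rep(0, length(mask_cells))

  if (!is.null(vg) && vg$sill > 1e-12) {
    covf <- function(h) vg$sill * exp(-h / vg$range)
    K <- covf(D)
    A <- rbind(cbind(K, 1), c(rep(1, n), 0)) # ordinary kriging system
    Ainv <- try(solve(A), silent = TRUE)
    if (!inherits(Ainv, "try-error")) {
      k0 <- covf(sqrt(outer(xy$x, xs, "-")^2 + outer(xy$y, ys, "-")^2))
      W <- cbind(k0, 1) %*% t(Ainv)     # weights incl. Lagrange column
      pred_resid <- as.vector(W[, seq_len(n)] %*% resid)
    } else vg <- NULL
  }
  if (is.null(vg) || vg$sill <= 1e-12) {
    if (stats::var(resid) > 1e-12) {
      message("downscale: variogram fit unavailable; falling back to ",
              "inverse-distance weighting of residuals")
      d0 <- sqrt(outer(xy$x, xs, "-")^2 + outer(xy$y, ys, "-")^2)
      w <- 1 / pmax(d0, g$cell_size / 10)^2
      pred_resid <- as.vector((w %*% resid) / rowSums(w))
    }
  }

  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  base <- if (use_drift)
    stats::predict(drift, data.frame(depth_m = depth$values[mask_cells]))
  else mean(coarse$value)
  out[mask_cells] <- base + pred_resid
  # exact at sample cells (nugget 0): overwrite with observed values
  out[cells] <- coarse$value
  layer(out, g, kind)
}

#' Validate a modelled layer against observations
#'
#' Compares modelled values with field observations at paired sample
#' points, returning an adjusted correlation (by default the square root
#' of the adjusted R-squared of the linear fit of observed on modelled)
#' and the root-mean-square error.
#'
#' @param modeled,observed Paired numeric vectors (>= 3 points, neither
#'   constant).
#' @param adjusted_r How to compute the correlation summary:
#'   `"sqrt_adj_r2"` (default) or plain Pearson `"correlation"`.
#' @return List with `adjusted_R` and `RMSE`.
#' @export
validate_layer <- function(modeled, observed,
                           adjusted_r = c("sqrt_adj_r2", "correlation")) {
  adjusted_r <- match.arg(adjusted_r)
  ok <- is.finite(modeled) & is.finite(observed)
  modeled <- modeled[ok]; observed <- observed[ok]
  if (length(modeled) < 3) stop("need at least 3 paired points")
  if (stats::sd(modeled) == 0 || stats::sd(observed) == 0)
    stop("zero variance in modelled or observed values")
  rmse <- sqrt(mean((observed - modeled)^2))
  if (adjusted_r == "correlation") {
    r <- stats::cor(modeled, observed)
  } else {
    fit <- stats::lm(observed ~ modeled)
    # a perfect fit is a legitimate input here (R = 1, RMSE = |offset|)
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    r <- sign(stats::coef(fit)[2]) * sqrt(max(ar2, 0))
  }
  list(adjusted_R = unname(r), RMSE = rmse)
}

#' Derive the full predictor stack from a raw world
#'
#' Convenience wrapper adding slope, standardized BPI and seafloor POC
#' flux to a stack that already carries depth, epc100 and carbonate
#' fields.
#'
#' @param stack A `bn_stack` from [build_world()] (present or future).
#' @param martin A `bn_martin`.
#' @param terrain A `bn_terrain`.
#' @return The augmented `bn_stack` (adds slope, bpi, poc_seafloor).
#' @export
prepare_layers <- function(stack, martin = martin_params(),
                           terrain = terrain_params()) {
  depth <- stack$layers$depth
  stack <- stack_set(stack, "slope", slope(depth))
  stack <- stack_set(stack, "bpi", bpi(depth, terrain))
  stack <- stack_set(stack, "poc_seafloor",
                     martin_poc(stack$layers$epc100, depth, martin))
  stack
}
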