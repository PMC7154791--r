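#' Binarize an HSI layer at a threshold
#'
#' A cell is suitable iff `HSI >= threshold`; the map is defined only
#' where the HSI is defined.
#'
#' @param hsi `bn_layer` of kind `hsi`.
#' @param threshold A `bn_threshold` (or bare number in `[0, 1]`, taken
#'   as an anonymous rule).
#' @param period `"present"` or `"future"`.
#' @return Object of class `bn_binary`: list with logical `suitable`
#'   matrix (NA where HSI missing), `threshold`, `period`, `grid`.
#' @export
binarize <- function(hsi, threshold, period = c("present", "future")) {
  period <- match.arg(period)
  if (is.numeric(threshold))
    threshold <- structure(list(rule = "fixed", value = threshold),
                           class = "bn_threshold")
  stopifnot(threshold$value >= 0, threshold$value <= 1 + 1e-12)
  suitable <- hsi$values >= threshold$value
  structure(list(suitable = suitable, threshold = threshold,
                 period = period, grid = hsi$grid),
            class = "bn_binary")
}

#' Present/future change categories
#'
#' Partition of the defined cells into `refugia` (suitable in both
#' periods), `loss` (present only), `gain` (future only) and `never`.
#'
#' @param present,future `bn_binary` maps on the same grid, built with
#'   the same threshold rule.
#' @return Object of class `bn_change`: integer matrix `category`
#'   (0 never, 1 loss, 2 gain, 3 refugia; NA undefined) plus the grid
#'   and threshold rule.
#' @export
change_map <- function(present, future) {
  stopifnot(inherits(present, "bn_binary"), inherits(future, "bn_binary"))
  if (!same_grid(present$grid, future$grid))
    stop("present and future maps are on different grids")
  if (!identical(present$threshold$rule, future$threshold$rule))
    stop("present and future maps use different threshold rules")
  p <- present$suitable; f <- future$suitable
  cat_m <- matrix(0L, nrow(p), ncol(p))
  cat_m[p & !f] <- 1L
  cat_m[!p & f] <- 2L
  cat_m[p & f] <- 3L
  cat_m[is.na(p) | is.na(f)] <- NA_integer_
  structure(list(category = cat_m, grid = present$grid,
                 rule = present$threshold$rule),
            class = "bn_change")
}

#' Habitat areas, change, refugia and positional medians
#'
#' Suitable-habitat area per period (cell count times cell area, km^2),
#' percent change, the share of present-day habitat acting as climate
#' refugia, and the median latitude and depth of the suitable cells in
#' each period.
#'
#' @param present,future `bn_binary` maps (same grid and rule).
#' @param depth Bathymetry `bn_layer`.
#' @return Object of class `bn_summary`: list with areas (km^2),
#'   percent_change, refugia_percent_of_present, per-period
#'   median_latitude and median_depth, and the threshold rule.
#' @export
summarize_habitat <- function(present, future, depth) {
  g <- present$grid
  cm <- change_map(present, future)$category
  n_loss <- sum(cm == 1L, na.rm = TRUE)
  n_gain <- sum(cm == 2L, na.rm = TRUE)
  n_ref <- sum(cm == 3L, na.rm = TRUE)
  n_p <- n_loss + n_ref
  n_f <- n_gain + n_ref
  if (n_p == 0) stop("empty present-day suitable set")
  cell_km2 <- (g$cell_size / 1000)^2
  med <- function(bin) {
    cells <- which(bin$suitable)
    if (!length(cells)) return(list(lat = NA_real_, depth = NA_real_))
    list(lat = stats::median(row_latitude(g, cell_xy(g, cells)$row)),
         depth = stats::median(depth$values[cells], na.rm = TRUE))
  }
  mp <- med(present); mf <- med(future)
  structure(list(
    rule = present$threshold$rule,
    area_present_km2 = n_p * cell_km2,
    area_future_km2 = n_f * cell_km2,
    area_loss_km2 = n_loss * cell_km2,
    area_gain_km2 = n_gain * cell_km2,
    area_refugia_km2 = n_ref * cell_km2,
    percent_change = 100 * (n_f - n_p) / n_p,
    refugia_percent_of_present = 100 * n_ref / n_p,
    median_latitude_present = mp$lat, median_latitude_future = mf$lat,
    median_depth_present = mp$depth, median_depth_future = mf$depth),
    class = "bn_summary")
}

#' @exportS3Method base::print
print.bn_summary <- function(x, ...) {
  cat(sprintf(
    "<bn_summary:%s> area %.0f -> %.0f km2 (%+.1f%%), refugia %.1f%% of present\n",
    x$rule, x$area_present_km2, x$area_future_km2, x$percent_change,
    x$refugia_percent_of_present))
  cat(sprintf("  median latitude %.2f -> %.2f deg; median depth %.0f -> %.0f m\n",
              x$median_latitude_present, x$median_latitude_future,
              x$median_depth_present, x$median_depth_future))
  invisible(x)
}

#' Write a change map as a categorical ASCII grid
#'
#' Codes: 0 never, 1 loss, 2 gain, 3 refugia.
#'
#' @param cm A `bn_change`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_change_asc <- function(cm, path) {
  lyr <- layer(cm$category + 0, cm$grid, "other", units = "category")
  write_layer_asc(lyr, path)
}
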