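#' Depth-consistency filter for occurrence records
#'
#' Compares the reported depth of OBIS and NOAA records against the
#' bathymetry raster, rejecting records with no depth information or
#' whose depth differs by more than `rel_tol` (relative to the raster
#' depth) AND more than `abs_tol` metres (both conditions must hold for
#' rejection). Institutional and ICES records are considered accurate
#' and pass unchanged. Records falling outside the grid extent are
#' rejected with reason `out_of_extent`.
#'
#' @param records Occurrence `data.frame` (columns x, y, reported_depth_m,
#'   source at minimum).
#' @param depth Bathymetry `bn_layer`.
#' @param rel_tol Relative tolerance (default 0.30).
#' @param abs_tol Absolute tolerance in metres (default 50).
#' @return List with `kept` and `rejected` data frames; `rejected`
#'   carries a `reject_reason` column (`missing_depth`, `depth_mismatch`,
#'   `out_of_extent`). The two frames partition the input.
#' @export
depth_consistency_filter <- function(records, depth,
                                     rel_tol = 0.30, abs_tol = 50) {
  g <- depth$grid
  cells <- xy_cell(g, records$x, records$y)
  out_ext <- is.na(cells)
  raster_depth <- rep(NA_real_, nrow(records))
  raster_depth[!out_ext] <- depth$values[cells[!out_ext]]
  out_ext <- out_ext | is.na(raster_depth) # land cells count as outside

  in_scope <- records$source %in% c("OBIS", "NOAA") & !out_ext
  missing <- in_scope & is.na(records$reported_depth_m)
  diff <- abs(records$reported_depth_m - raster_depth)
  mismatch <- in_scope & !is.na(records$reported_depth_m) &
    diff > rel_tol * abs(raster_depth) & diff > abs_tol

  reason <- rep(NA_character_, nrow(records))
  reason[out_ext] <- "out_of_extent"
  reason[missing] <- "missing_depth"
  reason[mismatch] <- "depth_mismatch"

  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reject_reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Position-accuracy filter for occurrence records
#'
#' Excludes ICES VME records whose positional error exceeds `max_error`
#' metres (or whose accuracy is unreported). Other sources are out of
#' scope and pass unchanged.
#'
#' @param records Occurrence `data.frame`.
#' @param max_error Maximum tolerated positional error in metres
#'   (default 5000).
#' @return List with `kept` and `rejected` (with `reject_reason` =
#'   `coarse_position`); a partition of the input.
#' @export
position_accuracy_filter <- function(records, max_error = 5000) {
  in_scope <- records$source == "ICES_VME"
  bad <- in_scope & (is.na(records$position_accuracy_m) |
                       records$position_accuracy_m > max_error)
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- "coarse_position"
  else rejected$reject_reason <- character(0)
  list(kept = records[!bad, , drop = FALSE], rejected = rejected)
}

#' Run the full occurrence QC chain
#'
#' Applies the depth-consistency filter then the position-accuracy
#' filter (the two have disjoint source scopes, so order does not change
#' the result).
#'
#' @inheritParams depth_consistency_filter
#' @inheritParams position_accuracy_filter
#' @return List with `kept` and `rejected` (with reasons).
#' @export
qc_occurrences <- function(records, depth, rel_tol = 0.30, abs_tol = 50,
                           max_error = 5000) {
  a <- depth_consistency_filter(records, depth, rel_tol, abs_tol)
  b <- position_accuracy_filter(a$kept, max_error)
  rej <- rbind(a$rejected, b$rejected)
  list(kept = b$kept, rejected = rej)
}

#' Collapse QC-passed records to one presence per grid cell
#'
#' Duplicate records in a cell are collapsed to a single presence; when
#' duplicates span sources, provenance is retained by the priority order
#' institutional > NOAA > OBIS > ICES_VME.
#'
#' @param records QC-passed occurrence `data.frame`.
#' @param grid A `bn_grid`.
#' @param species Optional species id (defaults to the records' single
#'   species value).
#' @return Object of class `bn_presences`: list with `species`, `cells`
#'   (sorted integer cell ids), `n_cells`, and `provenance` (source per
#'   cell).
#' @export
rasterize_presences <- function(records, grid, species = NULL) {
  cells <- if ("cell_id" %in% names(records) && !anyNA(records$cell_id))
    records$cell_id else xy_cell(grid, records$x, records$y)
  ok <- !is.na(cells)
  records <- records[ok, , drop = FALSE]; cells <- cells[ok]
  if (nrow(records) == 0)
    stop("no occurrence records survive QC; species cannot be modelled")
  prio <- c(institutional = 1, NOAA = 2, OBIS = 3, ICES_VME = 4)
  ord <- order(cells, prio[records$source])
  first <- !duplicated(cells[ord])
  cell_ids <- cells[ord][first]
  src <- records$source[ord][first]
  if (is.null(species))
    species <- unique(records$species)[1] %||% "unknown"
  structure(list(species = species,
                 cells = sort(cell_ids),
                 n_cells = length(cell_ids),
                 provenance = src[order(cell_ids)]),
            class = "bn_presences")
}

#' @exportS3Method base::print
print.bn_presences <- function(x, ...) {
  cat(sprintf("<bn_presences> %s: %d occupied cells\n", x$species, x$n_cells))
  invisible(x)
}
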