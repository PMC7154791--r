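#' Equal-area grid specification
#'
#' Defines the planar equal-area frame every raster layer in a run shares:
#' cell size in metres, number of rows and columns, a planar origin, and an
#' affine row-to-latitude mapping used for latitudinal summaries. Row 1 is
#' the southernmost row; latitude is strictly monotone in the row index.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 8).
#' @param cell_size Cell edge length in metres (default 3000, i.e. a
#'   3 x 3 km grid).
#' @param origin_x,origin_y Planar coordinates (m) of the lower-left corner.
#' @param lat_min,lat_max Latitudes (degrees) of the centres of the first
#'   and last row; must differ.
#' @param projection_id Free-text label for the planar frame.
#' @return An object of class `bn_grid`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 3000,
                      origin_x = 0, origin_y = 0,
                      lat_min = 30, lat_max = 65,
                      projection_id = "synthetic-equal-area") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L)
    stop("grid must be at least 8 x 8 cells")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (lat_min == lat_max) stop("latitude must be strictly monotone in row")
  structure(
    list(projection_id = projection_id,
         origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size,
         n_rows = n_rows, n_cols = n_cols,
         lat_min = lat_min, lat_max = lat_max),
    class = "bn_grid")
}

#' @exportS3Method base::print
print.bn_grid <- function(x, ...) {
  cat(sprintf("<bn_grid> %d x %d cells, %g m resolution [%s]\n",
              x$n_rows, x$n_cols, x$cell_size, x$projection_id))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Latitude of grid rows
#'
#' Affine mapping from row index to degrees latitude (cell centres).
#'
#' @param grid A `bn_grid`.
#' @param row Row indices (default all rows).
#' @return Numeric vector of latitudes.
#' @export
row_latitude <- function(grid, row = seq_len(grid$n_rows)) {
  grid$lat_min + (row - 1) * (grid$lat_max - grid$lat_min) /
    (grid$n_rows - 1)
}

#' Planar centre coordinates of grid cells
#'
#' Cells are numbered column-major (R matrix order):
#' `cell = row + (col - 1) * n_rows`.
#'
#' @param grid A `bn_grid`.
#' @param cells Integer cell indices.
#' @return `data.frame` with columns x, y (m), row, col.
#' @export
cell_centres <- function(grid, cells) {
  as.data.frame(cell_xy(grid, cells))
}

# Planar centre coordinates of cells. Cells are numbered column-major
# (R matrix order): cell = row + (col - 1) * n_rows.
cell_xy <- function(grid, cell) {
  row <- (cell - 1L) %% grid$n_rows + 1L
  col <- (cell - 1L) %/% grid$n_rows + 1L
  list(x = grid$origin_x + (col - 0.5) * grid$cell_size,
       y = grid$origin_y + (row - 0.5) * grid$cell_size,
       row = row, col = col)
}

# Cell index from planar coordinates; NA outside the grid extent.
xy_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  ok <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(row[ok] + (col[ok] - 1) * grid$n_rows)
  out
}

#' Construct a raster layer
#'
#' A layer is a numeric matrix (rows x cols of its grid) plus metadata:
#' the grid, a `kind` tag identifying the covariate, and units. `NA`
#' marks land / missing cells.
#'
#' @param values Numeric matrix of dimension `n_rows x n_cols`, or a
#'   vector of length `n_rows * n_cols` (column-major).
#' @param grid A `bn_grid`.
#' @param kind Covariate tag, one of the recognised layer kinds (depth,
#'   slope, bpi, temp, epc100, poc_seafloor, co3, co3_sat_ar, co3_sat_cal,
#'   omega_ar, omega_cal, DO, pH, hsi, cv).
#' @param units Unit string; defaults to the conventional unit for `kind`.
#' @return An object of class `bn_layer`.
#' @export
layer <- function(values, grid, kind, units = default_units(kind)) {
  kinds <- c("depth", "slope", "bpi", "temp", "epc100", "poc_seafloor",
             "co3", "co3_sat_ar", "co3_sat_cal", "omega_ar", "omega_cal",
             "DO", "pH", "hsi", "cv", "other")
  kind <- match.arg(kind, kinds)
  if (!is.matrix(values))
    values <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (kind == "hsi") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("hsi layer values must lie in [0, 1]")
  }
  structure(list(values = values, grid = grid, kind = kind, units = units),
            class = "bn_layer")
}

default_units <- function(kind) {
  switch(kind,
         depth = "m", slope = "degrees", bpi = "sd units",
         temp = "degC", epc100 = "mg C m-2 day-1",
         poc_seafloor = "mg C m-2 day-1",
         co3 = "mol m-3", co3_sat_ar = "mol m-3", co3_sat_cal = "mol m-3",
         omega_ar = "dimensionless", omega_cal = "dimensionless",
         DO = "umol kg-1", pH = "pH units", hsi = "dimensionless",
         cv = "dimensionless", "unknown")
}

#' @exportS3Method base::print
print.bn_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<bn_layer:%s> %d x %d [%s], %d ocean cells, range %.4g..%.4g\n",
              x$kind, x$grid$n_rows, x$grid$n_cols, x$units, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

layer_values <- function(lyr) as.vector(lyr$values)

same_grid <- function(a, b) {
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

check_aligned <- function(...) {
  lys <- list(...)
  g <- lys[[1]]$grid
  for (l in lys[-1])
    if (!same_grid(g, l$grid)) stop("layers are not grid-aligned")
  invisible(g)
}

#' Construct a layer stack
#'
#' A named collection of grid-aligned layers sharing one `bn_grid`.
#'
#' @param layers Named list of `bn_layer` objects on the same grid.
#' @return An object of class `bn_stack`.
#' @export
layer_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  g <- layers[[1]]$grid
  for (l in layers) {
    stopifnot(inherits(l, "bn_layer"))
    if (!same_grid(g, l$grid)) stop("all layers must share one grid")
  }
  structure(list(grid = g, layers = layers), class = "bn_stack")
}

#' @exportS3Method base::print
print.bn_stack <- function(x, ...) {
  cat(sprintf("<bn_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
`[[.bn_stack` <- function(x, name) x$layers[[name]]

#' @export
names.bn_stack <- function(x) names(x$layers)

stack_set <- function(stack, name, lyr) {
  stack$layers[[name]] <- lyr
  stack
}

# Ocean mask: cells where every layer in the stack is defined.
stack_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) m <- m & !is.na(l$values)
  m
}

# Covariate data.frame for a cell vector (column-major indices).
extract_cells <- function(stack, cells, vars = names(stack$layers)) {
  out <- data.frame(cell_id = cells)
  for (v in vars) out[[v]] <- stack$layers[[v]]$values[cells]
  out
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#' Row 1 of the file is the northernmost (last) grid row.
#'
#' @param lyr A `bn_layer`.
#' @param path Output file path (conventionally `.asc`).
#' @param na_value NODATA sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_layer_asc <- function(lyr, path, na_value = -9999) {
  g <- lyr$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.6f", g$origin_x),
           sprintf("yllcorner %.6f", g$origin_y),
           sprintf("cellsize %.6f", g$cell_size),
           sprintf("NODATA_value %g", na_value))
  v <- lyr$values
  v[is.na(v)] <- na_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (r in seq(g$n_rows, 1)) # north to south
    writeLines(paste(format(v[r, ], trim = TRUE, scientific = FALSE,
                            digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a layer
#'
#' @param path File written by [write_layer_asc()] or any conforming
#'   ASCII grid.
#' @param kind,units Layer metadata to attach (the format carries none).
#' @param grid Optional `bn_grid` supplying latitude metadata; must match
#'   the file's header.
#' @return A `bn_layer`.
#' @export
read_layer_asc <- function(path, kind = "other", units = default_units(kind),
                           grid = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  na_value <- val("NODATA_value")
  rows <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  m <- m[seq(nr, 1), , drop = FALSE] # back to south-first
  m[m == na_value] <- NA
  if (is.null(grid))
    grid <- grid_spec(nr, nc, cell_size = val("cellsize"),
                      origin_x = val("xllcorner"), origin_y = val("yllcorner"))
  else
    stopifnot(grid$n_rows == nr, grid$n_cols == nc)
  layer(m, grid, kind, units)
}
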