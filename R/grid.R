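# Grid-aligned raster data model shared by every stage.
#
# Conventions: row 1 is the northernmost row, cells are addressed (row, col),
# a point falls in the cell whose half-open x/y interval [x, x + cell_size)
# contains it, and every grid is an equal-area projected grid with a constant
# per-cell area in km2. Nodata is encoded as NA and propagates pessimistically:
# any derived cell is NA wherever any input is NA.

#' Define a raster grid
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param origin_x,origin_y map coordinates of the lower-left corner.
#' @param cell_size cell edge length in map units (square cells). The default
#'   convention takes map units to be kilometres.
#' @param crs_label free-text label for the coordinate system.
#' @param cell_area_km2 area of one cell in km2; defaults to `cell_size^2`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = 0, cell_size = 1,
                      crs_label = "synthetic-equal-area-km",
                      cell_area_km2 = cell_size^2) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, cell_area_km2 > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, crs_label = crs_label,
                 cell_area_km2 = cell_area_km2),
            class = "grid_spec")
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$cell_area_km2 - b$cell_area_km2) < tol
}

#' Create a raster layer
#'
#' @param grid a [grid_spec()].
#' @param name layer name.
#' @param values numeric (or integer-coded categorical) matrix of dimension
#'   `n_rows x n_cols`; `NA` marks nodata.
#' @param categories optional character vector mapping integer codes
#'   `1..length(categories)` to category labels.
#' @return An `ec_layer` object.
#' @export
new_layer <- function(grid, name, values, categories = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("layer '", name, "': values must be ", grid$n_rows, "x", grid$n_cols)
  if (!is.null(categories)) {
    codes <- values[!is.na(values)]
    if (length(codes) && (any(codes < 1) || any(codes > length(categories))))
      stop("layer '", name, "': categorical codes outside category dictionary")
  }
  structure(list(grid = grid, name = name, values = values,
                 categories = categories),
            class = "ec_layer")
}

#' @export
print.ec_layer <- function(x, ...) {
  kind <- if (is.null(x$categories)) "continuous" else
    paste0("categorical (", length(x$categories), " classes)")
  cat("<ec_layer> '", x$name, "' ", x$grid$n_rows, "x", x$grid$n_cols, " ",
      kind, ", ", sum(is.na(x$values)), " nodata cells\n", sep = "")
  invisible(x)
}

nodata_mask <- function(layer) is.na(layer$values)

#' Align layers into an environmental stack
#'
#' All layers must share an identical grid; the union of their nodata masks is
#' propagated to every layer, so downstream stages see one common mask.
#'
#' @param layers a list of [new_layer()] objects with unique names.
#' @param source_label label for the climate source (e.g. `"current"`,
#'   `"RCP4.5/GCM2"`).
#' @return An `env_stack`: the shared grid plus a named list of value matrices.
#' @export
align_stack <- function(layers, source_label = "current") {
  stopifnot(length(layers) >= 1)
  nm <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  g <- layers[[1]]$grid
  for (l in layers) {
    if (!same_grid(g, l$grid))
      stop("alignment error: layer '", l$name, "' is on a different grid")
  }
  shared_na <- Reduce(`|`, lapply(layers, nodata_mask))
  vals <- lapply(layers, function(l) {
    v <- l$values
    v[shared_na] <- NA_real_
    v
  })
  names(vals) <- nm
  structure(list(grid = g, layers = vals, source_label = source_label),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> '", x$source_label, "': ", length(x$layers), " layers on a ",
      x$grid$n_rows, "x", x$grid$n_cols, " grid [",
      paste(utils::head(names(x$layers), 8), collapse = ", "),
      if (length(x$layers) > 8) ", ..." else "", "]\n", sep = "")
  invisible(x)
}

# Subset a stack to named layers (order preserved as given).
select_layers <- function(stack, keep, source_label = stack$source_label) {
  missing <- setdiff(keep, names(stack$layers))
  if (length(missing)) stop("unknown layers: ", paste(missing, collapse = ", "))
  structure(list(grid = stack$grid, layers = stack$layers[keep],
                 source_label = source_label),
            class = "env_stack")
}

# Cells x layers matrix (column-major cell order), all cells including nodata.
stack_matrix <- function(stack) {
  do.call(cbind, lapply(stack$layers, as.vector))
}

#' Total area of a boolean mask
#'
#' @param mask logical matrix or an `ec_layer` with logical/0-1 values; `NA`
#'   cells never count.
#' @param grid the [grid_spec()] the mask is aligned to.
#' @return Area in km2: number of `TRUE` non-nodata cells times the constant
#'   per-cell area.
#' @export
total_area_km2 <- function(mask, grid) {
  m <- if (inherits(mask, "ec_layer")) mask$values else mask
  m <- as.matrix(m)
  if (!all(dim(m) == c(grid$n_rows, grid$n_cols)))
    stop("mask is not aligned to the grid")
  sum(m == 1, na.rm = TRUE) * grid$cell_area_km2
}

# Point -> cell lookup under the half-open cell convention; points outside the
# grid extent map to NA.
points_to_cells <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Cell centre coordinates.
cell_centres <- function(grid, row, col) {
  data.frame(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}
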