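# Raster file I/O. Rasters are stored as single-band ESRI ASCII grids (.asc),
# a plain-text format carrying the full grid geometry and a nodata tag.
# Categorical layers write their category dictionary to a JSON sidecar
# (<path>.cat.json) so that write -> read round-trips codes and labels.

ASC_NODATA <- -9999

#' Write a raster layer to an ESRI ASCII grid
#'
#' @param layer an `ec_layer`.
#' @param path output path (conventionally `.asc`). Categorical layers also
#'   write `<path>.cat.json` with the category dictionary.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "ec_layer"))
  g <- layer$grid
  v <- layer$values
  if (any(v[!is.na(v)] == ASC_NODATA))
    stop("values collide with the nodata sentinel ", ASC_NODATA)
  v[is.na(v)] <- ASC_NODATA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", sprintf("%.10g", g$origin_x)),
    paste("yllcorner", sprintf("%.10g", g$origin_y)),
    paste("cellsize", sprintf("%.10g", g$cell_size)),
    paste("NODATA_value", ASC_NODATA)
  ), con)
  # row 1 of the matrix is the northernmost row, matching the .asc convention
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  if (!is.null(layer$categories)) {
    jsonlite::write_json(
      list(name = layer$name, categories = layer$categories),
      paste0(path, ".cat.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a raster layer from an ESRI ASCII grid
#'
#' Honours the `NODATA_value` tag; a `<path>.cat.json` sidecar, if present,
#' restores the category dictionary.
#'
#' @param path path to a single-band `.asc` file.
#' @param name layer name; defaults to the file stem.
#' @return An `ec_layer`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("unsupported raster format (expected a single-band ESRI ASCII grid): ",
         path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[(i + 1):length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("unsupported raster format: expected ", nr * nc, " cell values, got ",
         length(vals), " (multi-band input is not supported)")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% ASC_NODATA
  m[m == nodata] <- NA_real_
  g <- grid_spec(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
  categories <- NULL
  sidecar <- paste0(path, ".cat.json")
  if (is.null(name)) name <- sub("\\.asc$", "", basename(path))
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    categories <- meta$categories
    name <- meta$name %||% name
    m[] <- as.integer(m)
  }
  new_layer(g, name, m, categories = categories)
}
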