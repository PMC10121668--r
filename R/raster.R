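#' Gridded raster layer
#'
#' A `raster_grid` is the package's minimal raster container: a numeric
#' matrix of cell values (row 1 is the northern edge, column 1 the western
#' edge), a logical nodata mask of identical shape, and the side length of
#' the square cells in kilometres. Cells are treated as equal-area squares;
#' no geodesic correction is applied. Masked cells hold `NA` in `values`
#' and are excluded from every statistic, training extraction and area
#' count downstream.
#'
#' @param values Numeric matrix of cell values.
#' @param mask Logical matrix, `TRUE` where the cell is nodata. Defaults to
#'   `is.na(values)`.
#' @param cell_size_km Positive scalar, cell side length in km.
#' @param name Layer name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, mask = NULL, cell_size_km = 1, name = "layer") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ensdm("raster_grid: `values` must be a numeric matrix",
               class = "ensdm_validation_error")
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop_ensdm("raster_grid: `mask` must be a logical matrix with the same ",
               "shape as `values`", class = "ensdm_validation_error")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0)
    stop_ensdm("raster_grid: `cell_size_km` must be a positive scalar",
               class = "ensdm_validation_error")
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (any(!is.finite(values[!mask])))
    stop_ensdm("raster_grid: non-masked values must be finite (layer '",
               name, "')", class = "ensdm_validation_error")
  structure(
    list(values = values, mask = mask,
         cell_size_km = as.numeric(cell_size_km), name = as.character(name)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid '%s'> %d x %d cells (%.4g km), %d masked\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size_km,
              sum(x$mask)))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Environmental predictor stack
#'
#' Bundle aligned [raster_grid] layers into an `env_stack`. All layers must
#' share shape and cell size; the union of the individual nodata masks
#' becomes the shared mask so no layer's nodata leaks into another layer's
#' statistics.
#'
#' @param grids List of [raster_grid] objects with unique names.
#' @param label Scenario identifier, e.g. `"current"`.
#' @return An object of class `env_stack` with fields `layers` (named list
#'   of `raster_grid`, all carrying the shared mask), `label`,
#'   `cell_size_km`.
#' @export
assemble_stack <- function(grids, label = "current") {
  if (length(grids) < 1)
    stop_ensdm("assemble_stack: need at least one layer",
               class = "ensdm_validation_error")
  stopifnot(all(vapply(grids, is_raster_grid, logical(1))))
  nms <- vapply(grids, function(g) g$name, character(1))
  if (anyDuplicated(nms))
    stop_ensdm("assemble_stack: duplicate layer names: ",
               paste(unique(nms[duplicated(nms)]), collapse = ", "),
               class = "ensdm_validation_error")
  ref <- grids[[1]]
  bad_shape <- nms[!vapply(grids, function(g)
    identical(dim(g$values), dim(ref$values)), logical(1))]
  bad_cell <- nms[!vapply(grids, function(g)
    isTRUE(all.equal(g$cell_size_km, ref$cell_size_km)), logical(1))]
  if (length(bad_shape) || length(bad_cell))
    stop_ensdm("assemble_stack: layers not aligned with '", ref$name, "': ",
               paste(unique(c(bad_shape, bad_cell)), collapse = ", "),
               class = "ensdm_alignment_error")
  shared <- Reduce(`|`, lapply(grids, function(g) g$mask))
  layers <- lapply(grids, function(g)
    raster_grid(g$values, shared, g$cell_size_km, g$name))
  names(layers) <- nms
  structure(list(layers = layers, label = as.character(label),
                 cell_size_km = ref$cell_size_km),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack '%s'> %d layers, %d x %d cells: %s\n",
              x$label, length(x$layers),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$layers[[1]]$values)
stack_mask <- function(stack) stack$layers[[1]]$mask
layer_names <- function(stack) names(stack$layers)

#' Suitability map
#'
#' Wrap a [raster_grid] of occurrence probabilities in `[0, 1]` together
#' with the identifier of the model that produced it.
#'
#' @param grid [raster_grid] with all non-masked values in `[0, 1]`.
#' @param source Ensemble or learner identifier.
#' @return Object of class `suitability_map`.
#' @export
suitability_map <- function(grid, source = "ensemble") {
  stopifnot(is_raster_grid(grid))
  v <- grid$values[!grid$mask]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop_ensdm("suitability_map: probabilities must lie in [0, 1]",
               class = "ensdm_validation_error")
  structure(list(probability = grid, source = as.character(source)),
            class = "suitability_map")
}

#' Area of a cell count in square kilometres
#'
#' @param n_cells Non-negative cell count.
#' @param cell_size_km Cell side length in km.
#' @return `n_cells * cell_size_km^2`.
#' @export
area_km2 <- function(n_cells, cell_size_km) {
  stopifnot(n_cells >= 0, cell_size_km > 0)
  n_cells * cell_size_km^2
}

# -- file I/O -----------------------------------------------------------

KM_PER_DEGREE <- 111.32  # equatorial degree length used for CELLSIZE-in-degrees

ascii_header_fields <- c("ncols", "nrows", "xllcorner", "yllcorner",
                         "cellsize", "nodata_value")

#' Read a raster layer from disk
#'
#' Supports the ESRI ASCII grid dialect (full fidelity, including nodata)
#' and single-band GeoTIFF. The GeoTIFF branch uses the `tiff` package,
#' which stores 32-bit float samples and round-trips only values in
#' `[0, 1]`; it is intended for suitability and binary maps, carries no
#' georeferencing keys, and takes its cell size from the `cell_size_km`
#' argument.
#'
#' @param path File path.
#' @param format `"ascii_grid"` or `"geotiff"`; `"auto"` picks by
#'   extension (`.asc` vs `.tif`/`.tiff`).
#' @param name Layer name; defaults to the file stem.
#' @param cellsize_unit For ASCII grids, how to interpret the CELLSIZE
#'   header: `"km"` (planar kilometres) or `"degrees"` (converted at
#'   1 degree = 111.32 km, the equatorial value).
#' @param cell_size_km Cell size for GeoTIFF input (no geokeys are read).
#' @return A [raster_grid].
#' @export
read_raster <- function(path, format = c("auto", "ascii_grid", "geotiff"),
                        name = NULL,
                        cellsize_unit = c("km", "degrees"),
                        cell_size_km = 1) {
  format <- match.arg(format)
  cellsize_unit <- match.arg(cellsize_unit)
  if (!file.exists(path))
    stop_ensdm("read_raster: no such file: ", path, class = "ensdm_io_error")
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "geotiff" else "ascii_grid"
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "ascii_grid")
    read_ascii_grid(path, name, cellsize_unit)
  else
    read_geotiff(path, name, cell_size_km)
}

read_ascii_grid <- function(path, name, cellsize_unit) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7)
    stop_ensdm("read_raster: '", path, "' is too short to hold an ASCII ",
               "grid header plus data", class = "ensdm_format_error")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop_ensdm("read_raster: malformed header line ", i, " ('",
                 lines[i], "') in ", path, class = "ensdm_format_error")
    hdr[[tolower(parts[1])]] <- parts[2]
  }
  missing <- setdiff(ascii_header_fields, names(hdr))
  if (length(missing))
    stop_ensdm("read_raster: ASCII grid header missing field(s): ",
               paste(toupper(missing), collapse = ", "),
               class = "ensdm_format_error")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize); nodata <- as.numeric(hdr$nodata_value)
  if (any(is.na(c(nc, nr, cs, nodata))) || nc < 1 || nr < 1 || cs <= 0)
    stop_ensdm("read_raster: non-numeric or invalid ASCII grid header in ",
               path, class = "ensdm_format_error")
  toks <- unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop_ensdm("read_raster: non-numeric cell value(s) in ", path,
               class = "ensdm_format_error")
  if (length(vals) != nr * nc)
    stop_ensdm("read_raster: expected ", nr * nc, " cells but found ",
               length(vals), " in ", path, class = "ensdm_format_error")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == nodata
  m[mask] <- NA_real_
  if (cellsize_unit == "degrees") cs <- cs * KM_PER_DEGREE
  raster_grid(m, mask, cs, name)
}

read_geotiff <- function(path, name, cell_size_km) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) != 2)
    stop_ensdm("read_raster: only single-band GeoTIFFs are supported (",
               path, ")", class = "ensdm_format_error")
  raster_grid(m, cell_size_km = cell_size_km, name = name)
}

#' Write a raster layer to disk
#'
#' The ASCII grid dialect preserves values to full double precision and
#' masked cells as NODATA; the GeoTIFF dialect (via the `tiff` package)
#' accepts only fully-unmasked grids with values in `[0, 1]`.
#'
#' @param grid A [raster_grid].
#' @inheritParams read_raster
#' @param nodata NODATA sentinel written to ASCII grids.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("auto", "ascii_grid", "geotiff"),
                         nodata = -9999) {
  stopifnot(is_raster_grid(grid))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "geotiff" else "ascii_grid"
  if (format == "ascii_grid") {
    m <- grid$values
    m[grid$mask] <- nodata
    hdr <- c(paste("NCOLS", ncol(m)), paste("NROWS", nrow(m)),
             "XLLCORNER 0", "YLLCORNER 0",
             paste("CELLSIZE", format(grid$cell_size_km, digits = 17)),
             paste("NODATA_value", format(nodata, digits = 17)))
    body <- apply(m, 1, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = " "))
    ok <- tryCatch({
      writeLines(c(hdr, body), path); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop_ensdm("write_raster: failed writing '", path, "': ",
                 conditionMessage(ok), class = "ensdm_io_error")
  } else {
    if (any(grid$mask))
      stop_ensdm("write_raster: the GeoTIFF dialect cannot encode masked ",
                 "cells; use the ASCII grid dialect",
                 class = "ensdm_format_error")
    v <- grid$values
    if (min(v) < 0 || max(v) > 1)
      stop_ensdm("write_raster: the GeoTIFF dialect stores [0, 1] samples ",
                 "only; use the ASCII grid dialect",
                 class = "ensdm_format_error")
    tiff::writeTIFF(v, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read or write a whole stack as one file per layer
#'
#' Layers are stored as `<dir>/<layer>.asc`; a `stack.json` sidecar keeps
#' the layer order and label.
#'
#' @param stack An [assemble_stack()] result.
#' @param dir Directory to create/read.
#' @return `write_stack`: `dir` invisibly. `read_stack`: an `env_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in layer_names(stack))
    write_raster(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                 "ascii_grid")
  jsonlite::write_json(
    list(label = stack$label, layers = layer_names(stack)),
    file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @param cellsize_unit Passed to [read_raster()].
#' @export
read_stack <- function(dir, cellsize_unit = c("km", "degrees")) {
  meta_path <- file.path(dir, "stack.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    files <- file.path(dir, paste0(meta$layers, ".asc"))
    label <- meta$label
  } else {
    files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
    label <- basename(dir)
  }
  grids <- lapply(files, read_raster, format = "ascii_grid",
                  cellsize_unit = match.arg(cellsize_unit))
  assemble_stack(grids, label)
}
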