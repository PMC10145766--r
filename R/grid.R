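#' Georeferenced raster grid
#'
#' A minimal single-band raster carrier: a numeric matrix of cell values
#' (`NA` = nodata), a geotransform (upper-left corner origin plus square cell
#' size in decimal degrees), and a CRS identifier. Rows run north to south,
#' columns west to east, matching the usual raster layout.
#'
#' @param values Numeric matrix; `NA` marks nodata cells.
#' @param origin_lon,origin_lat Longitude/latitude (degrees) of the *upper
#'   left corner* of cell (1, 1).
#' @param cell_size Cell edge length in decimal degrees (> 0).
#' @param crs CRS identifier; only geographic lat/lon grids are supported.
#' @return An object of class `sdm_grid`.
#' @export
grid_new <- function(values, origin_lon, origin_lat, cell_size,
                     crs = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(cell_size > 0, is.finite(origin_lon), is.finite(origin_lat))
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, crs = crs),
    class = "sdm_grid"
  )
}

#' @export
dim.sdm_grid <- function(x) dim(x$values)

#' @export
print.sdm_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<sdm_grid> %d x %d cells, %.6g deg resolution, origin (%.4f, %.4f), %s\n",
    d[1], d[2], x$cell_size, x$origin_lon, x$origin_lat, x$crs))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  valid cells: %d (range %.4g .. %.4g)\n",
                length(v), min(v), max(v)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' Test whether a grid object is valid
#' @param x Object.
#' @return Logical.
#' @export
is_grid <- function(x) inherits(x, "sdm_grid")

#' Do two grids share shape, geotransform and CRS?
#' @param a,b `sdm_grid` objects.
#' @param tol Numeric tolerance on the transform.
#' @return Logical.
#' @export
grid_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    identical(a$crs, b$crs)
}

#' Cell-center coordinates
#'
#' @param grid An `sdm_grid`.
#' @param rows,cols Optional integer vectors (recycled together); default all
#'   cells in row-major order.
#' @return Tibble with `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  d <- dim(grid$values)
  if (is.null(rows)) {
    rows <- rep(seq_len(d[1]), times = d[2])
    cols <- rep(seq_len(d[2]), each = d[1])
  }
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    lon = grid$origin_lon + (cols - 0.5) * grid$cell_size,
    lat = grid$origin_lat - (rows - 0.5) * grid$cell_size
  )
}

#' Locate the cell containing lon/lat points
#'
#' Points outside the grid extent get `NA` row/col.
#'
#' @param grid An `sdm_grid`.
#' @param lon,lat Coordinate vectors in degrees.
#' @return Tibble with `row`, `col`.
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  d <- dim(grid$values)
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1L
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1L
  bad <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Convert a grid to a long cell table
#'
#' @param x An `sdm_grid`.
#' @param ... Unused.
#' @param drop_na Drop nodata cells (default `TRUE`).
#' @return Tibble with `row`, `col`, `lon`, `lat`, `value`.
#' @export
as_tibble.sdm_grid <- function(x, ..., drop_na = TRUE) {
  out <- cell_centers(x)
  out$value <- as.vector(x$values)
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster interchange (`.asc`): six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values from north to south.
#'
#' @param path File path.
#' @param crs CRS identifier to attach on read.
#' @return `read_asc()` returns an `sdm_grid`; `write_asc()` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed .asc header in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_new(m,
           origin_lon = hdr$xllcorner,
           origin_lat = hdr$yllcorner + hdr$nrows * hdr$cellsize,
           cell_size = hdr$cellsize, crs = crs)
}

#' @rdname read_asc
#' @param grid An `sdm_grid` to write.
#' @param nodata Sentinel value written for nodata cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin_lon),
    sprintf("yllcorner %.10g", grid$origin_lat - d[1] * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  m <- grid$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Raster heat map of a grid
#'
#' @param object An `sdm_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdm_grid <- function(object, ...) {
  df <- as_tibble.sdm_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

# ---- predictor stacks -------------------------------------------------------

#' Bundle aligned grids into a named predictor stack
#'
#' @param layers Named list of `sdm_grid` objects, mutually aligned.
#' @return A `predictor_stack` (named list of grids).
#' @export
predictor_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names")
  ok <- vapply(layers, is_grid, logical(1))
  if (!all(ok)) stop("all layers must be sdm_grid objects")
  tmpl <- layers[[1]]
  for (i in seq_along(layers)) {
    if (!grid_aligned(layers[[i]], tmpl))
      stop("layer '", nm[i], "' is not aligned to the first layer")
  }
  structure(layers, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  d <- dim(x[[1]]$values)
  cat(sprintf("<predictor_stack> %d layers on a %d x %d grid: %s\n",
              length(x), d[1], d[2], paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Layer names of a stack
#' @param stack A `predictor_stack`.
#' @return Character vector.
#' @export
stack_layers <- function(stack) names(stack)

#' Extract predictor values at cells
#'
#' @param stack A `predictor_stack`.
#' @param rows,cols Cell indices (equal length).
#' @param layers Layer subset; default all.
#' @return Tibble, one column per layer, one row per cell.
#' @export
stack_extract <- function(stack, rows, cols, layers = names(stack)) {
  d <- dim(stack[[1]]$values)
  idx <- cbind(rows, cols)
  out <- lapply(stack[layers], function(g) g$values[idx])
  tibble::as_tibble(out)
}

#' Convert a stack to a wide cell table
#'
#' @param stack A `predictor_stack`.
#' @param drop_na Drop cells where any layer is nodata (default `TRUE`).
#' @return Tibble with `row`, `col`, `lon`, `lat` and one column per layer.
#' @export
stack_as_tibble <- function(stack, drop_na = TRUE) {
  base <- cell_centers(stack[[1]])
  vals <- lapply(stack, function(g) as.vector(g$values))
  out <- dplyr::bind_cols(base, tibble::as_tibble(vals))
  if (drop_na) {
    keep <- stats::complete.cases(out[names(stack)])
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Apply a function to every layer's values, preserving geometry
#' @param stack A `predictor_stack`.
#' @param f Function matrix -> matrix.
#' @return A `predictor_stack`.
#' @keywords internal
stack_map <- function(stack, f) {
  out <- lapply(stack, function(g) { g$values <- f(g$values); g })
  structure(out, class = "predictor_stack")
}

#' Write / read a stack as a directory of `.asc` files
#'
#' @param stack A `predictor_stack`.
#' @param dir Directory path (created if missing).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` a
#'   `predictor_stack` with layer names taken from file names.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack))
    write_asc(stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers found in ", dir)
  layers <- lapply(files, read_asc)
  names(layers) <- sub("\\.asc$", "", basename(files))
  predictor_stack(layers)
}
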